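# Individual-level Dice overlap between a subject's top-weighted (or
# treatment-altered) edges and a factor's significant connectivity profile.

new_edge_set <- function(edges, provenance) {
  structure(list(edges = sort(unique(as.integer(edges))),
                 provenance = provenance),
            class = "edge_set")
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("edge_set (%s): %d edges\n", x$provenance, length(x$edges)))
  invisible(x)
}

#' Top-fraction edge set of a subject's profile
#'
#' The `ceiling(fraction * E)` edges of largest connection strength.
#' "Largest" means largest absolute value by default (hyper- and
#' hypo-connectivity both count, consistent with signed profiles);
#' `mode = "positive"` ranks raw values instead. Ties at the cutoff are
#' broken by edge index.
#'
#' @param v length-E edge or deviation vector.
#' @param fraction fraction in (0, 1] (default 0.10).
#' @param mode "absolute" (default) or "positive".
#' @return an `edge_set`.
#' @export
top_fraction_edges <- function(v, fraction = 0.10,
                               mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  check_scalar(fraction, "fraction", lower = 0, upper = 1, open_lower = TRUE)
  E <- length(v)
  m <- ceiling(fraction * E)
  key <- if (mode == "absolute") -abs(v) else -v
  idx <- order(key, seq_len(E))[seq_len(m)]
  new_edge_set(idx, "top-fraction")
}

#' Edges significantly altered between paired scans
#'
#' Per-edge paired t-test on post - pre with Benjamini-Hochberg adjustment
#' across all E edges; the set holds edges with q below `alpha`. Edges
#' with exactly zero change in every subject are never flagged.
#'
#' @param pre,post n x E matrices of paired edge (or deviation) vectors.
#' @param alpha FDR threshold (default 0.05).
#' @return an `edge_set` with attributes `t`, `p`, `q`.
#' @export
paired_altered_edges <- function(pre, post, alpha = 0.05) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!all(dim(pre) == dim(post))) stopf("pre/post dimensions differ")
  n <- nrow(pre)
  if (n < 3L) stopf("need at least 3 paired subjects")
  d <- post - pre
  mu <- colMeans(d)
  sdv <- apply(d, 2L, sd)
  tstat <- mu / (sdv / sqrt(n))
  tstat[sdv == 0 & mu == 0] <- 0
  tstat[sdv == 0 & mu != 0] <- Inf * sign(mu[sdv == 0 & mu != 0])
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  q <- fdr_adjust(p)
  es <- new_edge_set(which(q < alpha), "paired-altered")
  attr(es, "t") <- tstat; attr(es, "p") <- p; attr(es, "q") <- q
  es
}

#' Significant-profile edge set of one factor
#'
#' The edges flagged by the bootstrap significance mask of
#' [bootstrap_profiles()] for the given factor.
#'
#' @param ci a `factor_profile_ci`.
#' @param factor factor index.
#' @return an `edge_set`.
#' @export
factor_profile_set <- function(ci, factor) {
  if (!inherits(ci, "factor_profile_ci"))
    stopf("'ci' must come from bootstrap_profiles()")
  if (factor < 1 || factor > nrow(ci$mask)) stopf("factor index out of range")
  new_edge_set(which(ci$mask[factor, ]), "factor-profile")
}

#' Dice coefficient of two edge sets
#'
#' 2|A∩B| / (|A| + |B|), the cardinality form. Empty operands are an
#' error: the coefficient is undefined, not zero.
#'
#' @param a,b `edge_set`s (or plain integer vectors of edge indices).
#' @return a `dice_result`: list with `coefficient`, `size_a`, `size_b`,
#'   `size_intersection`.
#' @export
dice <- function(a, b) {
  ea <- if (inherits(a, "edge_set")) a$edges else sort(unique(as.integer(a)))
  eb <- if (inherits(b, "edge_set")) b$edges else sort(unique(as.integer(b)))
  if (length(ea) == 0L || length(eb) == 0L)
    stopf("Dice coefficient undefined for an empty edge set")
  ni <- length(intersect(ea, eb))
  structure(list(coefficient = 2 * ni / (length(ea) + length(eb)),
                 size_a = length(ea), size_b = length(eb),
                 size_intersection = ni),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("Dice = %.1f%%  (|A| = %d, |B| = %d, |A∩B| = %d)\n",
              100 * x$coefficient, x$size_a, x$size_b,
              x$size_intersection))
  invisible(x)
}

#' Rank regions by their contribution to an edge set
#'
#' Region score = number of incident edges in the set (count mode) or the
#' sum of |weight| over incident edges when `weights` is supplied.
#' Regions are ranked by descending score with ties broken by region
#' order.
#'
#' @param s an `edge_set`.
#' @param parcellation a [parcellation()].
#' @param weights optional length-E edge weights.
#' @return data frame: `region_id`, `network`, `score`, sorted.
#' @export
top_contributing_regions <- function(s, parcellation, weights = NULL) {
  edges <- if (inherits(s, "edge_set")) s$edges else as.integer(s)
  R <- n_regions(parcellation)
  ep <- edge_pairs(R)
  score <- numeric(R)
  w <- if (is.null(weights)) rep(1, n_edges(parcellation)) else abs(weights)
  for (e in edges) {
    score[ep[e, 1L]] <- score[ep[e, 1L]] + w[e]
    score[ep[e, 2L]] <- score[ep[e, 2L]] + w[e]
  }
  out <- data.frame(region_id = parcellation$region_id,
                    network = parcellation$network,
                    score = score)
  out[order(-out$score, seq_len(R)), , drop = FALSE]
}

#' Per-subject Dice table against expressed factor profiles
#'
#' For each subject, compares the top-fraction edge set of the subject's
#' deviation vector with the significant profile of the subject's
#' dominant factor (argmax loading), or of a fixed `factor` if given.
#'
#' @param deviations N x E deviation matrix.
#' @param expressions N x K loading matrix.
#' @param ci a `factor_profile_ci`.
#' @param fraction top fraction (default 0.10).
#' @param factor optional fixed factor index for all subjects.
#' @return data frame: subject, factor, size_top, size_profile,
#'   size_intersection, dice_pct.
#' @export
dice_by_subject <- function(deviations, expressions, ci, fraction = 0.10,
                            factor = NULL) {
  dev <- as.matrix(deviations)
  L <- as.matrix(expressions)
  rows <- lapply(seq_len(nrow(dev)), function(i) {
    k <- factor %||% which.max(L[i, ])
    dd <- dice(top_fraction_edges(dev[i, ], fraction),
               factor_profile_set(ci, k))
    data.frame(subject = i, factor = k, size_top = dd$size_a,
               size_profile = dd$size_b,
               size_intersection = dd$size_intersection,
               dice_pct = 100 * dd$coefficient)
  })
  do.call(rbind, rows)
}
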
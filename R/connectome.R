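#' Pearson functional connectivity from ROI time series
#'
#' @param timeseries a T x R numeric matrix (T timepoints, R regions).
#'   Column names, if present, are kept as region labels.
#' @return an R x R symmetric correlation matrix with unit diagonal.
#' @export
compute_fc <- function(timeseries) {
  ts <- as.matrix(timeseries)
  if (nrow(ts) < 3L)
    stopf("need at least 3 timepoints, got %d", nrow(ts))
  v <- apply(ts, 2L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    nm <- colnames(ts)[bad] %||% as.character(bad)
    stopf("zero-variance region(s): %s", paste(nm, collapse = ", "))
  }
  M <- stats::cor(ts)
  diag(M) <- 1
  M
}

# symmetry check shared by vectorize() and the validators
assert_fc <- function(M, tol = 1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stopf("connectivity matrix must be square")
  if (max(abs(M - t(M))) > tol)
    stopf("connectivity matrix is asymmetric beyond tolerance %g", tol)
  invisible(M)
}

#' Half-vectorize a symmetric connectivity matrix
#'
#' Extracts the strict upper triangle in row-major order (1,2), (1,3), ...,
#' (R-1,R); see [edge_pairs()] for the edge index convention.
#'
#' @param M an R x R symmetric matrix.
#' @param tol symmetry tolerance.
#' @return numeric vector of length E = R(R-1)/2.
#' @export
vectorize <- function(M, tol = 1e-10) {
  assert_fc(M, tol)
  # column-major lower triangle of a symmetric matrix == row-major upper
  M[lower.tri(M)]
}

#' Rebuild a symmetric unit-diagonal matrix from an edge vector
#' @param v length-E numeric vector in [edge_pairs()] order.
#' @param diag_value diagonal to restore (1 for correlation matrices).
#' @return an R x R symmetric matrix.
#' @export
unvectorize <- function(v, diag_value = 1) {
  E <- length(v)
  R <- (1 + sqrt(1 + 8 * E)) / 2
  if (R != round(R))
    stopf("length %d is not R(R-1)/2 for any integer R", E)
  R <- as.integer(R)
  M <- matrix(0, R, R)
  M[lower.tri(M)] <- v
  M <- M + t(M)
  diag(M) <- diag_value
  M
}

#' Fit a normative reference from control subjects
#'
#' Per edge, ordinary least squares of the edge value on the supplied
#' covariates (with intercept); with no covariates this reduces to the
#' per-edge control mean and standard deviation. The residual SD is the
#' scale for later deviation (w-) scoring.
#'
#' @param control_vectors n x E matrix of control edge vectors (rows =
#'   subjects), or a list of length-E vectors.
#' @param control_covariates optional n x C numeric matrix / data frame.
#' @return an `fc_reference` object with per-edge `coef` ((C+1) x E) and
#'   `resid_sd` (length E).
#' @export
fit_reference <- function(control_vectors, control_covariates = NULL) {
  Y <- if (is.list(control_vectors)) do.call(rbind, control_vectors)
       else as.matrix(control_vectors)
  n <- nrow(Y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(control_covariates)) {
    C <- as.matrix(control_covariates)
    if (nrow(C) != n) stopf("covariate rows must match control rows")
    colnames(C) <- colnames(C) %||% paste0("cov", seq_len(ncol(C)))
    X <- cbind(X, C)
  }
  p <- ncol(X)
  if (n <= p + 1L)
    stopf("reference unidentifiable: %d controls for %d coefficients", n, p)
  qx <- qr(X)
  if (qx$rank < p)
    stopf("collinear covariates in reference fit")
  coefs <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  resid_sd <- sqrt(colSums(res^2) / (n - p))
  if (any(resid_sd < 1e-8))
    stopf("degenerate reference: %d edge(s) with residual sd < 1e-8",
          sum(resid_sd < 1e-8))
  structure(list(coef = coefs, resid_sd = resid_sd,
                 covariates = setdiff(colnames(X), "(Intercept)"),
                 n = n),
            class = "fc_reference")
}

#' Deviation (w-) score of one subject against the control reference
#'
#' Per edge: (observed - predicted from covariates) / residual SD, i.e. a
#' covariate-adjusted z-score relative to the control population.
#'
#' @param v length-E edge vector for the subject.
#' @param covariates the subject's covariate values (length C, same order
#'   as in [fit_reference()]); NULL for an intercept-only reference.
#' @param reference an `fc_reference`.
#' @return length-E numeric deviation vector (z units).
#' @export
deviation_score <- function(v, covariates = NULL, reference) {
  if (!inherits(reference, "fc_reference"))
    stopf("'reference' must come from fit_reference()")
  p <- nrow(reference$coef)
  x <- c(1, if (is.null(covariates)) numeric(0) else as.numeric(covariates))
  if (length(x) != p)
    stopf("expected %d covariate value(s), got %d", p - 1L, length(x) - 1L)
  pred <- drop(x %*% reference$coef)
  (v - pred) / reference$resid_sd
}

#' Encode a deviation vector as signed edge counts
#'
#' Bridges continuous deviation scores to the count likelihood required by
#' the topic model. The vocabulary has 2E words: `edge_k+` (hyper-
#' connectivity) followed by `edge_k-` (hypo-connectivity). Each deviation
#' is clipped to `[-clip, clip]` and contributes `round(scale * |z|)`
#' tokens of the word matching its sign.
#'
#' @param d length-E deviation vector.
#' @param scale tokens per z unit (default 10).
#' @param clip absolute z cap (default 3).
#' @return a `count_document`: list with integer `ids` (1-based positions
#'   in the 2E vocabulary), `counts`, `total`, and vocabulary size `V`.
#' @export
encode_counts <- function(d, scale = 10, clip = 3) {
  check_scalar(scale, "scale", lower = 0, open_lower = TRUE)
  check_scalar(clip, "clip", lower = 0, open_lower = TRUE)
  E <- length(d)
  z <- pmin(pmax(d, -clip), clip)
  cnt <- round(scale * abs(z))
  keep <- cnt > 0
  if (!any(keep))
    stopf("all counts are zero; increase 'scale' (deviations too small)")
  idx <- which(keep)
  ids <- ifelse(z[idx] > 0, idx, E + idx)
  o <- order(ids)
  structure(list(ids = as.integer(ids[o]), counts = as.numeric(cnt[idx][o]),
                 total = sum(cnt), V = 2L * E),
            class = "count_document")
}

#' Signed edge vocabulary labels for a parcellation
#' @param parc a [parcellation()].
#' @return character vector of length 2E: `edge+` labels then `edge-`.
#' @export
edge_vocabulary <- function(parc) {
  lab <- edge_labels(parc)
  c(paste0(lab, "+"), paste0(lab, "-"))
}

#' Network-block summary of an edge vector
#'
#' Averages edge values within each unordered pair of networks, yielding a
#' symmetric networks x networks block matrix (diagonal = within-network).
#'
#' @param values length-E numeric vector (edge or deviation values).
#' @param parc a [parcellation()].
#' @return a symmetric B x B matrix (B = number of networks); blocks with
#'   no edges are NA.
#' @export
network_block_summary <- function(values, parc) {
  E <- n_edges(parc)
  if (length(values) != E)
    stopf("expected %d edge values, got %d", E, length(values))
  lev <- network_levels(parc)
  en <- edge_networks(parc)
  a <- factor(en[, 1L], levels = lev)
  b <- factor(en[, 2L], levels = lev)
  B <- length(lev)
  sums <- matrix(0, B, B, dimnames = list(lev, lev))
  cnts <- matrix(0, B, B, dimnames = list(lev, lev))
  ia <- as.integer(a); ib <- as.integer(b)
  for (e in seq_len(E)) {
    sums[ia[e], ib[e]] <- sums[ia[e], ib[e]] + values[e]
    cnts[ia[e], ib[e]] <- cnts[ia[e], ib[e]] + 1
  }
  sums <- sums + t(sums * (row(sums) != col(sums)))
  cnts <- cnts + t(cnts * (row(cnts) != col(cnts)))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Radar-style network distribution of a block summary
#'
#' Row sums of absolute block means, min-max scaled to [0, 1]; used to
#' display how a factor's connectivity profile distributes over networks.
#'
#' @param block a block matrix from [network_block_summary()].
#' @return named numeric vector in [0, 1].
#' @export
network_distribution <- function(block) {
  s <- rowSums(abs(block), na.rm = TRUE)
  rng <- range(s)
  if (diff(rng) == 0) return(setNames(rep(0, length(s)), names(s)))
  (s - rng[1]) / diff(rng)
}
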
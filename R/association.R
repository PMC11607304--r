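# Factor-symptom association layer: covariate residualization, one CCA
# per (factor, clinical scale) pair with site-aware permutation, FDR
# control, group and longitudinal comparisons.

# design matrix: intercept + numeric covariates + one-hot site (reference
# level dropped). `covariates` may be NULL, a matrix, or a data frame
# (factors/characters are expanded via model.matrix).
build_design <- function(n, covariates = NULL, site = NULL) {
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    if (nrow(cv) != n) stopf("covariates must have %d rows", n)
    mm <- stats::model.matrix(~ ., data = cv)
    X <- cbind(X, mm[, -1L, drop = FALSE])
  }
  if (!is.null(site)) {
    s <- factor(site)
    if (nlevels(s) > 1L) {
      mm <- stats::model.matrix(~ s)
      colnames(mm) <- sub("^s", "site", colnames(mm))
      X <- cbind(X, mm[, -1L, drop = FALSE])
    }
  }
  X
}

#' Residualize columns on covariates
#'
#' Per column, ordinary least squares residuals on the covariates plus an
#' intercept; site labels, if given, enter as one-hot indicators with the
#' reference level dropped.
#'
#' @param values n x m numeric matrix (or vector).
#' @param covariates n x C matrix / data frame, or NULL (centering only).
#' @param site optional site labels.
#' @return residual matrix (or vector) of the same shape.
#' @export
residualize <- function(values, covariates = NULL, site = NULL) {
  vec <- is.null(dim(values))
  Y <- as.matrix(values)
  X <- build_design(nrow(Y), covariates, site)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stopf("rank-deficient covariates; collinear column(s): %s",
          paste(drop_cols, collapse = ", "))
  }
  res <- qr.resid(qx, Y)
  if (vec) drop(res) else res
}

#' Canonical correlation between one factor's expression and a scale
#'
#' With a scalar factor side, the first canonical pair reduces to the
#' multiple-correlation solution: the clinical weights are the regression
#' coefficients of the loading on the (residualized) items, the canonical
#' correlation is the multiple correlation, and each item's structural
#' coefficient is its correlation with the fitted clinical variate. The
#' clinical variate is oriented to correlate positively with the loading.
#'
#' @param loading length-n factor expression vector.
#' @param items n x p matrix of item-level scores.
#' @param covariates,site optional nuisance terms; both sides are
#'   residualized on them before the CCA.
#' @return a `cca_result`: list with `r`, `weights`, `structural`, `n`,
#'   `p_items`; permutation p and FDR q are filled in by the pipeline.
#' @export
cca_factor_scale <- function(loading, items, covariates = NULL, site = NULL) {
  items <- as.matrix(items)
  n <- length(loading); p <- ncol(items)
  if (nrow(items) != n) stopf("loading and items disagree on n")
  if (p >= n)
    stopf("p = %d items >= n = %d subjects; reduce the item set (no silent regularization)", p, n)
  ncov <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (n <= p + ncov + 2)
    stopf("too few subjects (n = %d) for %d items and %d covariates",
          n, p, ncov)
  y <- residualize(loading, covariates, site)
  Z <- residualize(items, covariates, site)
  fit <- stats::lm.fit(cbind(1, Z), y)
  fitted <- y - fit$residuals
  r <- suppressWarnings(stats::cor(fitted, y))
  if (!is.finite(r)) r <- 0
  r <- max(r, 0)   # multiple correlation is nonnegative by construction
  structural <- suppressWarnings(apply(Z, 2L, stats::cor, y = fitted))
  structural[!is.finite(structural)] <- 0
  structure(list(r = r, weights = fit$coefficients[-1L],
                 structural = structural, n = n, p_items = p),
            class = "cca_result")
}

#' Site-aware permutation p-value
#'
#' Permutes the loading vector within site blocks only (subjects are
#' exchangeable within, not across, acquisition sites) and recomputes the
#' test statistic; p = (1 + #\{perm >= observed\}) / (1 + n_perm).
#'
#' By default the statistic is the canonical correlation of
#' [cca_factor_scale()] against `items`, computed by a fast QR path; a
#' custom `statistic(loading)` function may be supplied instead.
#'
#' @param loading length-n vector to be permuted.
#' @param items n x p item matrix (default statistic).
#' @param site_labels site labels; NULL = one site (free permutation).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param covariates passed to the residualization of both sides.
#' @param statistic optional function(loading) -> scalar.
#' @return list with `p`, `observed`, and the permutation null `null`.
#' @export
permutation_p <- function(loading, items = NULL, site_labels = NULL,
                          n_perm = 10000, seed = 1, covariates = NULL,
                          statistic = NULL) {
  n <- length(loading)
  s <- factor(site_labels %||% rep("all", n))
  small <- table(s) < 2L
  if (any(small))
    warnf("site(s) with < 2 subjects are fixed points in the permutation: %s",
          paste(names(which(small)), collapse = ", "))
  idx_by_site <- split(seq_len(n), s)
  perm_matrix <- with_seed(derive_seed(seed, 31), {
    P <- matrix(seq_len(n), n, n_perm)
    for (b in idx_by_site) {
      if (length(b) >= 2L)
        for (t in seq_len(n_perm)) P[b, t] <- b[sample.int(length(b))]
    }
    P
  })
  if (is.null(statistic)) {
    if (is.null(items)) stopf("supply 'items' or a 'statistic' function")
    Z <- residualize(as.matrix(items), covariates, site_labels)
    y <- residualize(loading, covariates, site_labels)
    qx <- qr(cbind(1, Z))
    Q <- qr.Q(qx)[, 2:qx$rank, drop = FALSE]
    stat_many <- function(Y) {
      Yc <- sweep(Y, 2L, colMeans(Y))
      ssr <- colSums(crossprod(Q, Yc)^2)
      sst <- colSums(Yc^2)
      sqrt(pmax(ssr, 0) / sst)
    }
    observed <- stat_many(matrix(y, ncol = 1))
    null <- stat_many(matrix(y[perm_matrix], n, n_perm))
  } else {
    observed <- statistic(loading)
    null <- apply(perm_matrix, 2L, function(ix) statistic(loading[ix]))
  }
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(p = p, observed = observed, null = null)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure with enforced monotonicity: q(i) = min over j >= i of
#' p(j) * m / j at the sorted p-values, capped at 1.
#'
#' @param pvals numeric vector of p-values.
#' @return q-values in the original order.
#' @export
fdr_adjust <- function(pvals) {
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
  q
}

#' Per-factor group comparison (two-sided Wilcoxon rank-sum)
#'
#' Exact p-values where possible (small samples, no ties), otherwise the
#' tie-corrected normal approximation; FDR across the K factors.
#'
#' @param loadings N x K expression matrix.
#' @param groups two-level group labels of length N.
#' @return data frame with `factor`, `W`, `p`, `q`.
#' @export
group_compare <- function(loadings, groups) {
  L <- as.matrix(loadings)
  g <- factor(groups)
  if (nlevels(g) != 2L) stopf("need exactly two groups")
  res <- lapply(seq_len(ncol(L)), function(k) {
    wt <- suppressWarnings(
      stats::wilcox.test(L[g == levels(g)[1L], k],
                         L[g == levels(g)[2L], k]))
    c(W = unname(wt$statistic), p = wt$p.value)
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- cbind(factor = seq_len(ncol(L)), out)
  out$q <- fdr_adjust(out$p)
  out
}

#' Pre/post change test per factor
#'
#' The default compares pre vs post with a two-sided Wilcoxon rank-sum
#' test (the convention of the reference analyses for longitudinal factor
#' expression); `method = "signedrank"` gives the paired signed-rank
#' alternative.
#'
#' @param pre,post n x K loading matrices (same subjects, same order).
#' @param method "ranksum" (default) or "signedrank".
#' @return data frame with `factor`, `statistic`, `p`, `q`.
#' @export
paired_change_test <- function(pre, post,
                               method = c("ranksum", "signedrank")) {
  method <- match.arg(method)
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!all(dim(pre) == dim(post))) stopf("pre/post dimensions differ")
  res <- lapply(seq_len(ncol(pre)), function(k) {
    wt <- suppressWarnings(
      if (method == "ranksum")
        stats::wilcox.test(pre[, k], post[, k])
      else stats::wilcox.test(pre[, k], post[, k], paired = TRUE))
    c(statistic = unname(wt$statistic), p = wt$p.value)
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- cbind(factor = seq_len(ncol(pre)), out)
  out$q <- fdr_adjust(out$p)
  out
}

#' Spearman association between loading change and symptom change
#'
#' Both deltas are residualized on the covariates (if any), then the
#' tie-aware Spearman correlation (average ranks) is computed with the
#' t-approximation for the two-sided p-value.
#'
#' @param delta_loading,delta_symptom length-n change vectors.
#' @param covariates,site optional nuisance terms.
#' @return list with `rho`, `p`, `n`.
#' @export
change_association <- function(delta_loading, delta_symptom,
                               covariates = NULL, site = NULL) {
  x <- residualize(delta_loading, covariates, site)
  y <- residualize(delta_symptom, covariates, site)
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Out-of-sample prediction-error summaries
#'
#' Pearson correlation between predicted factor expression and observed
#' scores (after residualizing both on covariates, if given), and the mean
#' square error after min-max mapping both vectors to [0, 1] (loadings and
#' clinical scores live on incommensurate scales; the mapping makes the
#' MSE well defined).
#'
#' @param predicted_loading,scores length-n vectors.
#' @param covariates,site optional nuisance terms (correlation only).
#' @return list with `mse`, `r`, `n`.
#' @export
prediction_error <- function(predicted_loading, scores,
                             covariates = NULL, site = NULL) {
  n <- length(predicted_loading)
  if (length(scores) != n) stopf("length mismatch")
  x <- residualize(predicted_loading, covariates, site)
  y <- residualize(scores, covariates, site)
  r <- stats::cor(x, y)
  minmax <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) stopf("constant vector: min-max MSE undefined")
    (v - rng[1]) / diff(rng)
  }
  mse <- mean((minmax(predicted_loading) - minmax(scores))^2)
  list(mse = mse, r = r, n = n)
}

#' CCA of every factor against every clinical scale, with permutation and FDR
#'
#' Runs [cca_factor_scale()] + [permutation_p()] for each (factor, scale)
#' pair, listwise-complete within each scale, and applies
#' Benjamini-Hochberg across all tested pairs (the FDR family is all
#' pairs).
#'
#' @param expressions N x K loading matrix.
#' @param phenotypes data frame holding item columns.
#' @param scales named list: scale name -> item column names.
#' @param covariates,site optional nuisance terms.
#' @param n_perm permutations per pair (default 10000).
#' @param seed integer seed.
#' @return list with `results` (data frame: factor, scale, r, p, q, n) and
#'   `structural` (data frame: factor, scale, item, coefficient).
#' @export
associate_factors <- function(expressions, phenotypes, scales,
                              covariates = NULL, site = NULL,
                              n_perm = 10000, seed = 1) {
  L <- as.matrix(expressions)
  K <- ncol(L)
  rows <- list(); stru <- list(); ii <- 0L
  for (k in seq_len(K)) {
    for (nm in names(scales)) {
      items <- as.matrix(phenotypes[, scales[[nm]], drop = FALSE])
      keep <- stats::complete.cases(items)
      cv <- if (is.null(covariates)) NULL
            else as.data.frame(covariates)[keep, , drop = FALSE]
      st <- if (is.null(site)) NULL else site[keep]
      cc <- cca_factor_scale(L[keep, k], items[keep, , drop = FALSE],
                             covariates = cv, site = st)
      pp <- permutation_p(L[keep, k], items[keep, , drop = FALSE],
                          site_labels = st, n_perm = n_perm,
                          seed = derive_seed(seed, 10L * k + ii),
                          covariates = cv)
      ii <- ii + 1L
      rows[[ii]] <- data.frame(factor = k, scale = nm, r = cc$r,
                               p = pp$p, n = cc$n)
      stru[[ii]] <- data.frame(factor = k, scale = nm,
                               item = scales[[nm]],
                               coefficient = cc$structural)
    }
  }
  results <- do.call(rbind, rows)
  results$q <- fdr_adjust(results$p)
  list(results = results, structural = do.call(rbind, stru))
}
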
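#' Generate sparse signed factor connectivity profiles
#'
#' Each factor's profile is a sparse signed vector over the E edges of the
#' parcellation, organized into network blocks: a small random subset of
#' within/between-network blocks is marked active and, for `block_bias > 0`,
#' nonzero edges concentrate inside active blocks. Each active block
#' carries a dominant sign (hyper- or hypo-connectivity); nonzero
#' magnitudes are drawn uniformly from `magnitude` (default 0.75-2.25
#' connectivity-deviation units, i.e. roughly 1.5-4.5 control SDs at the
#' default noise level for a fully expressed factor - the regime of
#' bootstrapped-z profile maps in case-control connectomics). The default
#' support fraction of 0.25 reflects that empirical factor profiles are
#' broad (reference analyses display their top half of connections), not
#' narrowly sparse; see the methods vignette for the calibration
#' rationale.
#'
#' @param K number of factors (>= 2).
#' @param parcellation a [parcellation()].
#' @param sparsity fraction of edges with nonzero weight per factor, in
#'   (0, 1] (default 0.25).
#' @param block_bias nonnegative concentration of support into active
#'   blocks; 0 spreads support uniformly over all edges (default 2).
#' @param seed integer seed.
#' @param magnitude length-2 range of nonzero |weights|.
#' @return a K x E signed matrix with attributes `support` (list of
#'   nonzero index vectors) and `sparsity`.
#' @export
generate_factor_profiles <- function(K, parcellation, sparsity = 0.25,
                                     block_bias = 2, seed = 1,
                                     magnitude = c(0.75, 2.25)) {
  if (!is_count(K) || K < 2) stopf("invalid parameter: K must be an integer >= 2")
  check_scalar(sparsity, "sparsity", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(block_bias, "block_bias", lower = 0)
  E <- n_edges(parcellation)
  lev <- network_levels(parcellation)
  en <- edge_networks(parcellation)
  # unordered block id per edge
  blk <- paste(pmin(en[, 1], en[, 2]), pmax(en[, 1], en[, 2]), sep = ":")
  blocks <- sort(unique(blk))
  m <- max(1L, round(sparsity * E))
  n_active <- max(2L, round(0.15 * length(blocks)))
  with_seed(seed, {
    profiles <- matrix(0, K, E)
    support <- vector("list", K)
    for (k in seq_len(K)) {
      for (try in 1:50) {
        active <- sample(blocks, n_active)
        w <- exp(block_bias * (blk %in% active))
        idx <- sample.int(E, m, prob = w / sum(w))
        # dominant sign per active block, coin-flip signs elsewhere
        sgn_blk <- setNames(sample(c(-1, 1), length(active), replace = TRUE),
                            active)
        sgn <- ifelse(blk[idx] %in% active, sgn_blk[blk[idx]],
                      sample(c(-1, 1), m, replace = TRUE))
        if (length(unique(sgn)) == 1L) sgn[1L] <- -sgn[1L]
        # keep pairwise support overlap below 50%
        ok <- TRUE
        for (kk in seq_len(k - 1L)) {
          ov <- length(intersect(idx, support[[kk]])) / m
          if (ov >= 0.5) { ok <- FALSE; break }
        }
        if (ok) break
      }
      if (!ok) stopf("could not generate factor supports with overlap < 50%%")
      profiles[k, idx] <- sgn * runif(m, magnitude[1], magnitude[2])
      support[[k]] <- sort(idx)
    }
    structure(profiles, support = support, sparsity = sparsity,
              class = c("factor_profiles", "matrix"))
  })
}

#' Bundle the generative ground truth of a synthetic study
#'
#' @param factor_profiles K x E matrix from [generate_factor_profiles()].
#' @param parcellation the [parcellation()] the profiles refer to.
#' @param n_sites number of acquisition sites.
#' @param site_effect_sd SD of additive per-edge site offsets shared within
#'   site (default 0: no site effect unless requested).
#' @param symptom_coupling optional coupling spec, see [sample_phenotypes()].
#' @param treatment_effect expected decrease in the treated factor's
#'   loading for treated subjects (used by [sample_longitudinal()]).
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(factor_profiles, parcellation, n_sites = 3,
                         site_effect_sd = 0, symptom_coupling = NULL,
                         treatment_effect = 0.2) {
  structure(list(profiles = factor_profiles, parcellation = parcellation,
                 K = nrow(factor_profiles), n_sites = n_sites,
                 site_effect_sd = site_effect_sd,
                 symptom_coupling = symptom_coupling,
                 treatment_effect = treatment_effect),
            class = "ground_truth")
}

# deviation vectors -> list of clipped symmetric correlation-like matrices
deviations_to_matrices <- function(dev) {
  lapply(seq_len(nrow(dev)), function(i)
    unvectorize(pmin(pmax(dev[i, ], -0.999), 0.999)))
}

#' Sample a patient cohort with planted factor structure
#'
#' Each subject draws a loading vector from Dirichlet(`dirichlet_alpha`);
#' the subject's edge deviation vector is the loading-weighted mixture of
#' factor profiles plus i.i.d. Gaussian noise (plus a shared per-site
#' offset when the truth declares one). Connectivity matrices are the
#' deviations clipped to (-0.999, 0.999) with unit diagonal. If
#' `n_timepoints` is given, surrogate ROI time series realizing
#' (approximately) each matrix are also returned.
#'
#' @param truth a [ground_truth()].
#' @param n_subjects cohort size.
#' @param dirichlet_alpha positive length-K Dirichlet parameter.
#' @param noise_sd positive edge noise SD.
#' @param n_timepoints optional; if supplied must be >= R + 2.
#' @param seed integer seed.
#' @param loadings optional N x K matrix of fixed loading rows (rows must
#'   lie on the simplex); overrides the Dirichlet draw.
#' @return list with `matrices` (list of R x R), `loadings` (N x K simplex
#'   rows), `deviations` (N x E, pre-clipping), `site` (factor),
#'   `covariates` (data frame: age, sex, fd), and optionally `timeseries`.
#' @export
sample_cohort <- function(truth, n_subjects, dirichlet_alpha, noise_sd,
                          n_timepoints = NULL, seed = 1, loadings = NULL) {
  if (!is_count(n_subjects)) stopf("invalid parameter: n_subjects")
  check_scalar(noise_sd, "noise_sd", lower = 0, open_lower = TRUE)
  K <- truth$K
  if (length(dirichlet_alpha) == 1L) dirichlet_alpha <- rep(dirichlet_alpha, K)
  if (length(dirichlet_alpha) != K || any(dirichlet_alpha <= 0))
    stopf("invalid parameter: dirichlet_alpha must be positive, length K")
  E <- ncol(truth$profiles)
  R <- n_regions(truth$parcellation)
  if (!is.null(n_timepoints) && n_timepoints < R + 2)
    stopf("n_timepoints must be at least R + 2 = %d", R + 2)
  if (!is.null(loadings)) {
    loadings <- as.matrix(loadings)
    if (nrow(loadings) != n_subjects || ncol(loadings) != K)
      stopf("fixed 'loadings' must be %d x %d", n_subjects, K)
    if (max(abs(rowSums(loadings) - 1)) > 1e-8 || any(loadings < 0))
      stopf("fixed 'loadings' rows must lie on the simplex")
  }
  fixed_loadings <- loadings
  with_seed(seed, {
    loadings <- fixed_loadings %||% rdirichlet(n_subjects, dirichlet_alpha)
    site <- factor(sample(paste0("site", seq_len(truth$n_sites)),
                          n_subjects, replace = TRUE))
    site_off <- matrix(rnorm(truth$n_sites * E, 0, truth$site_effect_sd),
                       truth$n_sites, E)
    dev <- loadings %*% truth$profiles +
      site_off[as.integer(site), , drop = FALSE] +
      matrix(rnorm(n_subjects * E, 0, noise_sd), n_subjects, E)
    covs <- data.frame(age = runif(n_subjects, 8, 18),
                       sex = rbinom(n_subjects, 1, 0.5),
                       fd = runif(n_subjects, 0.02, 0.2))
    out <- list(matrices = deviations_to_matrices(dev), loadings = loadings,
                deviations = dev, site = site, covariates = covs)
    if (!is.null(n_timepoints))
      out$timeseries <- lapply(out$matrices, surrogate_timeseries,
                               n_timepoints = n_timepoints)
    out
  })
}

# T x R Gaussian series whose population correlation equals the nearest
# positive-definite approximation of `M` (eigenvalue floor)
surrogate_timeseries <- function(M, n_timepoints) {
  eg <- eigen(M, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-6)
  L <- eg$vectors %*% diag(sqrt(vals))
  Z <- matrix(rnorm(n_timepoints * nrow(M)), n_timepoints)
  Z %*% t(L)
}

#' Sample a control (reference) cohort
#'
#' Controls carry zero factor signal: their edge deviations are pure
#' Gaussian noise (optionally plus planted covariate effects, useful for
#' testing covariate-adjusted reference fitting).
#'
#' @param n number of controls (>= 2).
#' @param parcellation a [parcellation()].
#' @param noise_sd positive edge noise SD.
#' @param seed integer seed.
#' @param covariates optional n x C data frame / matrix.
#' @param covariate_effects optional C x E matrix of linear effects added
#'   as `covariates %*% covariate_effects`.
#' @return list with `matrices`, `deviations`, `covariates`.
#' @export
sample_controls <- function(n, parcellation, noise_sd, seed = 1,
                            covariates = NULL, covariate_effects = NULL) {
  if (!is_count(n) || n < 2)
    stopf("invalid parameter: need n >= 2 controls")
  check_scalar(noise_sd, "noise_sd", lower = 0, open_lower = TRUE)
  E <- n_edges(parcellation)
  with_seed(seed, {
    dev <- matrix(rnorm(n * E, 0, noise_sd), n, E)
    if (!is.null(covariates) && !is.null(covariate_effects))
      dev <- dev + as.matrix(covariates) %*% covariate_effects
    list(matrices = deviations_to_matrices(dev), deviations = dev,
         covariates = covariates)
  })
}

#' Sample item-level phenotypes coupled to factor loadings
#'
#' `coupling` is a named list of clinical scales; each scale is a list with
#' `n_items`, and optionally `factor` (index), `items` (indices of coupled
#' items within the scale) and `effect` (linear slope). Coupled items are
#' `intercept + effect * loading[, factor] + noise`; uncoupled items are
#' pure noise around the intercept.
#'
#' @param loadings N x K simplex matrix.
#' @param coupling coupling spec (see above).
#' @param noise_sd positive item noise SD.
#' @param seed integer seed.
#' @param site optional site labels to attach.
#' @param covariates optional covariate data frame to attach.
#' @param intercept baseline item score (default 10).
#' @return a data frame: `subject_id`, optional `site` and covariates, and
#'   one column per item named `<scale>.item<j>`, plus an attribute
#'   `scales` mapping scale name -> item column names.
#' @export
sample_phenotypes <- function(loadings, coupling, noise_sd, seed = 1,
                              site = NULL, covariates = NULL,
                              intercept = 10) {
  check_scalar(noise_sd, "noise_sd", lower = 0, open_lower = TRUE)
  loadings <- as.matrix(loadings)
  N <- nrow(loadings); K <- ncol(loadings)
  for (sc in coupling) {
    if (!is.null(sc$factor) && (sc$factor < 1 || sc$factor > K))
      stopf("invalid parameter: coupling references factor %d with K = %d",
            sc$factor, K)
    if (!is.null(sc$items) && any(sc$items > sc$n_items))
      stopf("invalid parameter: coupled item index exceeds n_items")
  }
  with_seed(seed, {
    out <- data.frame(subject_id = sprintf("sub%04d", seq_len(N)))
    if (!is.null(site)) out$site <- site
    if (!is.null(covariates)) out <- cbind(out, covariates)
    scales <- list()
    for (nm in names(coupling)) {
      sc <- coupling[[nm]]
      items <- matrix(rnorm(N * sc$n_items, intercept, noise_sd),
                      N, sc$n_items)
      if (!is.null(sc$factor) && length(sc$items %||% integer(0)) > 0)
        items[, sc$items] <- items[, sc$items] +
          sc$effect * loadings[, sc$factor]
      cols <- sprintf("%s.item%d", nm, seq_len(sc$n_items))
      colnames(items) <- cols
      out <- cbind(out, items)
      scales[[nm]] <- cols
    }
    attr(out, "scales") <- scales
    out
  })
}

#' Sample pre/post-treatment factor expression and symptom change
#'
#' Each treated subject's loading on `treated_factor` decreases by a
#' per-subject delta ~ Normal(`mean_delta`, `noise_sd`), floored at 0, and
#' the loading row is renormalized to the simplex. Symptom change is
#' coupled to the realized decrease in expression (subjects floored at 0
#' improve less, mirroring remission tracking actual circuit change):
#' `delta_symptom = -symptom_coupling_delta * delta_applied +
#' Normal(0, noise_sd)`, negative = remission, so measured loading change
#' and symptom change are positively correlated.
#'
#' @param baseline_loadings n x K simplex matrix.
#' @param treated_factor factor index receiving the decrease.
#' @param mean_delta expected loading decrease (positive = improvement).
#' @param symptom_coupling_delta slope linking delta to symptom change.
#' @param noise_sd positive SD for both the per-subject delta spread and
#'   the symptom noise.
#' @param seed integer seed.
#' @return list with `post` (n x K simplex rows), `delta_symptom`,
#'   `delta_applied` (realized loading decreases before renormalization).
#' @export
sample_longitudinal <- function(baseline_loadings, treated_factor,
                                mean_delta, symptom_coupling_delta,
                                noise_sd, seed = 1) {
  check_scalar(noise_sd, "noise_sd", lower = 0, open_lower = TRUE)
  L <- as.matrix(baseline_loadings)
  n <- nrow(L); K <- ncol(L)
  if (treated_factor < 1 || treated_factor > K)
    stopf("invalid parameter: treated_factor")
  with_seed(seed, {
    delta <- rnorm(n, mean_delta, noise_sd)
    post <- L
    new_val <- pmax(L[, treated_factor] - delta, 0)   # clip at 0, documented
    applied <- L[, treated_factor] - new_val
    post[, treated_factor] <- new_val
    post <- post / rowSums(post)
    dsym <- -symptom_coupling_delta * applied + rnorm(n, 0, noise_sd)
    list(post = post, delta_symptom = dsym, delta_applied = applied)
  })
}
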
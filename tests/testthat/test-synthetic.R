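parc16 <- default_parcellation(16)

test_that("generate_factor_profiles obeys its contracts", {
  P <- generate_factor_profiles(4, default_parcellation(128), seed = 1)
  expect_equal(dim(P), c(4, 8128))
  # determinism
  P2 <- generate_factor_profiles(4, default_parcellation(128), seed = 1)
  expect_identical(unclass(P), unclass(P2))
  # sparsity + signs + pairwise support overlap < 50%
  sup <- attr(P, "support")
  m <- round(0.25 * 8128)
  for (k in 1:4) {
    expect_length(sup[[k]], m)
    expect_true(any(P[k, ] > 0) && any(P[k, ] < 0))
  }
  for (a in 1:3) for (b in (a + 1):4)
    expect_lt(length(intersect(sup[[a]], sup[[b]])) / m, 0.5)
  expect_error(generate_factor_profiles(1, parc16), "invalid parameter")
  expect_error(generate_factor_profiles(3, parc16, sparsity = 0),
               "sparsity")
})

test_that("block_bias = 0 spreads support uniformly over edges", {
  # chi-square goodness of fit of support counts against block sizes,
  # pooled over 20 seeds
  parc <- default_parcellation(24)
  en <- edge_networks(parc)
  blk <- factor(paste(pmin(en[, 1], en[, 2]), pmax(en[, 1], en[, 2]),
                      sep = ":"))
  expected_prop <- table(blk) / length(blk)
  counts <- 0
  for (s in 1:20) {
    P <- generate_factor_profiles(2, parc, sparsity = 0.3, block_bias = 0,
                                  seed = s)
    counts <- counts + table(blk[attr(P, "support")[[1]]])
  }
  suppressWarnings(gof <- chisq.test(counts, p = as.vector(expected_prop)))
  expect_gt(gof$p.value, 0.01)
})

test_that("sample_cohort plants the declared mixture structure", {
  P <- generate_factor_profiles(4, parc16, seed = 2)
  truth <- ground_truth(P, parc16)
  # noiseless pure-factor subject reproduces profile 1
  pure <- matrix(rep(c(1, 0, 0, 0), each = 2), 2, 4)
  coh0 <- sample_cohort(truth, 2, rep(1, 4), noise_sd = 1e-9, seed = 3,
                        loadings = pure)
  expect_lt(max(abs(coh0$deviations[1, ] - P[1, ])), 1e-8)
  # loading rows on the simplex (the 215-patient configuration)
  coh <- sample_cohort(truth, 215, rep(1, 4), noise_sd = 0.5, seed = 4)
  expect_equal(nrow(coh$loadings), 215)
  expect_true(all(abs(rowSums(coh$loadings) - 1) < 1e-12))
  expect_true(all(coh$loadings >= 0))
  # matrices are symmetric, unit diagonal, clipped
  M <- coh$matrices[[1]]
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(1, 16))
  expect_true(all(abs(M[upper.tri(M)]) <= 0.999))
  # concentrated Dirichlet gives near-uniform loadings
  cohc <- sample_cohort(truth, 500, rep(100, 4), noise_sd = 0.5, seed = 5)
  expect_true(all(abs(colMeans(cohc$loadings) - 0.25) < 0.01))
  expect_true(all(apply(cohc$loadings, 2, sd) < 0.05))
  expect_error(sample_cohort(truth, 10, rep(1, 4), noise_sd = 0),
               "noise_sd")
})

test_that("time-series mode produces matrices consistent with compute_fc", {
  P <- generate_factor_profiles(2, default_parcellation(10), seed = 6)
  truth <- ground_truth(P, default_parcellation(10))
  coh <- sample_cohort(truth, 2, rep(1, 2), noise_sd = 0.2,
                       n_timepoints = 400, seed = 7)
  fc <- compute_fc(coh$timeseries[[1]])
  # finite-T estimate of the (eigenvalue-floored) target
  expect_gt(cor(vectorize(fc), vectorize(coh$matrices[[1]])), 0.6)
  expect_error(sample_cohort(truth, 2, rep(1, 2), noise_sd = 0.2,
                             n_timepoints = 5), "R \\+ 2")
})

test_that("sample_controls carries zero signal and is seed-stable", {
  ctl <- sample_controls(173, parc16, noise_sd = 0.5, seed = 8)
  expect_length(ctl$matrices, 173)
  expect_equal(dim(ctl$matrices[[1]]), c(16, 16))
  ctl2 <- sample_controls(173, parc16, noise_sd = 0.5, seed = 8)
  expect_identical(ctl$deviations, ctl2$deviations)
  expect_error(sample_controls(1, parc16, 0.5), "n >= 2")
  # CLT check on the edge means of 500 controls
  big <- sample_controls(500, parc16, noise_sd = 0.5, seed = 9)
  mu <- colMeans(big$deviations)
  expect_gte(mean(abs(mu) < 3 * 0.5 / sqrt(500)), 0.99)
})

test_that("sample_phenotypes couples items to loadings as declared", {
  set.seed(20)
  L <- rdirich(500, rep(1, 4))
  # noiseless limit: coupled item tracks its factor
  cp <- list(anx = list(n_items = 3, factor = 3, items = 1, effect = 1))
  ph0 <- sample_phenotypes(L, cp, noise_sd = 1e-8, seed = 21)
  expect_gt(cor(ph0$anx.item1, L[, 3]), 0.999)
  # closed-form attenuation at effect 1, noise 1
  ph1 <- sample_phenotypes(L, cp, noise_sd = 1, seed = 22)
  r_pred <- 1 * sd(L[, 3]) / sqrt(var(L[, 3]) + 1)
  expect_lt(abs(cor(ph1$anx.item1, L[, 3]) - r_pred), 0.1)
  # zero-effect null: |r| < 0.1 in >= 95% of 100 seeds
  cp0 <- list(s = list(n_items = 2))
  ok <- vapply(1:100, function(s) {
    ph <- sample_phenotypes(L, cp0, noise_sd = 1, seed = s)
    abs(cor(ph$s.item1, L[, 1])) < 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  expect_error(sample_phenotypes(L, list(bad = list(n_items = 2,
                                                    factor = 9, items = 1,
                                                    effect = 1)),
                                 noise_sd = 1), "factor")
})

test_that("sample_longitudinal plants a pre/post decrease with coupled remission", {
  set.seed(23)
  pre <- rdirich(27, rep(2, 4))
  # identity at zero delta, tiny noise
  lg0 <- sample_longitudinal(pre, 1, mean_delta = 0, 1, noise_sd = 1e-10,
                             seed = 24)
  expect_equal(lg0$post, pre, tolerance = 1e-8)
  # planted decrease: paired location test rejects in >= 95% of 100 seeds
  rej <- vapply(1:100, function(s) {
    p0 <- rdirich(27, rep(2, 4))
    lg <- sample_longitudinal(p0, 1, 0.2, 1, noise_sd = 0.05, seed = s)
    expect_true(all(abs(rowSums(lg$post) - 1) < 1e-12))
    expect_true(all(lg$post >= 0))
    suppressWarnings(
      stats::wilcox.test(p0[, 1], lg$post[, 1],
                         paired = TRUE)$p.value) < 0.001
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("null worlds give uniform downstream permutation p-values", {
  # coupling effects 0: the CCA permutation p over replicate cohorts is
  # Uniform(0,1) (up to the n_perm discretization)
  pvals <- vapply(1:500, function(r) {
    set.seed(3000 + r)
    L <- rdirich(100, rep(1, 4))
    items <- matrix(rnorm(100 * 3), 100, 3)
    permutation_p(L[, 1], items, n_perm = 99, seed = r)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
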
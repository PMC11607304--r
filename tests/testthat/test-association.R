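# unit tests for the factor-symptom association layer

test_that("residualize has the OLS residual properties", {
  set.seed(1)
  n <- 100
  cov <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(n * 3), n, 3)
  R <- residualize(Y, cov)
  # orthogonal to every covariate column and centered
  expect_lt(max(abs(crossprod(cbind(1, cov$age, cov$sex), R))), 1e-6 * n)
  # exactly linear values vanish
  y_lin <- 2 + 3 * cov$age - cov$sex
  expect_lt(max(abs(residualize(y_lin, cov))), 1e-8)
  # covariates orthogonal to values: residuals = centered values
  y <- rnorm(n)
  y_orth <- residualize(y, NULL)
  expect_equal(y_orth, y - mean(y))
  # collinear covariates named in the error
  cov_bad <- data.frame(a = cov$age, b = 2 * cov$age)
  expect_error(residualize(y, cov_bad), "collinear")
})

test_that("cca_factor_scale collapses to the bivariate case for one item", {
  set.seed(2)
  n <- 80
  l <- rnorm(n)
  item <- matrix(0.6 * l + rnorm(n), ncol = 1)
  cc <- cca_factor_scale(l, item)
  expect_equal(cc$r, abs(drop(cor(l, item))), tolerance = 1e-10)
  expect_equal(abs(cc$structural), 1, tolerance = 1e-10)
  # negative association: r still reported in [0, 1], structural carries sign
  item2 <- matrix(-0.6 * l + rnorm(n), ncol = 1)
  cc2 <- cca_factor_scale(l, item2)
  expect_equal(cc2$r, abs(drop(cor(l, item2))), tolerance = 1e-10)
  expect_lt(cc2$structural, 0)
  expect_error(cca_factor_scale(l, matrix(rnorm(n * 81), n, 81)), "items")
})

test_that("multiple correlation dominates any single item", {
  set.seed(3)
  reps <- 50
  dom <- vapply(seq_len(reps), function(i) {
    n <- 150
    l <- rnorm(n)
    items <- sapply(1:4, function(j) l + rnorm(n, sd = 1.5))
    cc <- cca_factor_scale(l, items)
    cc$r >= max(abs(cor(items, l))) - 1e-10
  }, logical(1))
  expect_true(all(dom))
})

test_that("null multiple correlation is calibrated (r^2 ~ p/(n-1))", {
  set.seed(4)
  r2 <- vapply(1:500, function(i) {
    l <- rnorm(200)
    cca_factor_scale(l, matrix(rnorm(200 * 5), 200, 5))$r^2
  }, 0)
  expect_lt(abs(mean(r2) - 5 / 199), 0.2 * 5 / 199)
})

test_that("permutation_p follows the add-one rule and handles sites", {
  set.seed(5)
  n <- 60
  l <- rnorm(n)
  items <- matrix(l + rnorm(n, sd = 0.1), ncol = 1)   # overwhelming signal
  pp <- permutation_p(l, items, n_perm = 99, seed = 6)
  expect_equal(pp$p, 1 / 100)
  # single site equals explicit all-one-site labels
  pp1 <- permutation_p(l, items, site_labels = rep("x", n), n_perm = 49,
                       seed = 7)
  pp2 <- permutation_p(l, items, n_perm = 49, seed = 7)
  expect_equal(pp1$p, pp2$p)
  # a singleton site is warned about and kept fixed
  expect_warning(
    permutation_p(l, items, site_labels = c("solo", rep("a", n - 1)),
                  n_perm = 19, seed = 8),
    "fixed points")
  # custom statistic path agrees with the fast path
  Z <- matrix(rnorm(n * 3), n, 3)
  stat <- function(y) {
    f <- lm.fit(cbind(1, Z), y)
    suppressWarnings(max(cor(y - f$residuals, y), 0))
  }
  a <- permutation_p(l, Z, n_perm = 200, seed = 9)
  b <- permutation_p(l, statistic = stat, n_perm = 200, seed = 9)
  expect_equal(a$p, b$p, tolerance = 1e-8)
})

test_that("fdr_adjust matches the hand-worked example and the reference", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_adjust(0.37), 0.37)
  set.seed(10)
  for (t in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- fdr_adjust(p)
    expect_equal(q, p.adjust(p, method = "BH"))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("group_compare reproduces exact rank-sum results", {
  # completely separated samples, n = 10 vs 10: two-sided p = 2/C(20,10)
  L <- cbind(c(1:10, 101:110))
  g <- rep(c("a", "b"), each = 10)
  gc <- group_compare(L, g)
  expect_equal(gc$p, 2 / choose(20, 10), tolerance = 1e-12)
  # identical groups: p = 1
  L0 <- cbind(rep(c(1, 2, 3, 4, 5), 4))
  gc0 <- group_compare(L0, rep(c("a", "b"), 10))
  expect_gt(gc0$p, 0.95)
  # invariance to monotone transforms
  set.seed(11)
  x <- cbind(rexp(30))
  g2 <- rep(c("a", "b"), 15)
  expect_equal(group_compare(x, g2)$p, group_compare(exp(x), g2)$p)
  expect_error(group_compare(x, rep("a", 30)), "two groups")
})

test_that("paired_change_test is symmetric and supports both methods", {
  set.seed(12)
  pre <- rdirich(27, rep(2, 3))
  post <- pre
  expect_gt(paired_change_test(pre, post)$p[1], 0.95)
  lg <- sample_longitudinal(pre, 1, 0.2, 1, 0.05, seed = 13)
  a <- paired_change_test(pre, lg$post)
  b <- paired_change_test(lg$post, pre)
  expect_equal(a$p, b$p)
  expect_lt(a$p[1], 0.05)
  sr <- paired_change_test(pre, lg$post, method = "signedrank")
  expect_lt(sr$p[1], 0.001)
})

test_that("change_association is rank-based with average-rank ties", {
  # monotone relation: rho = 1
  x <- c(0.1, 0.5, 0.2, 0.9, 0.4)
  expect_equal(change_association(x, exp(3 * x))$rho, 1)
  # 5-point worked example with a tie, textbook tie-corrected value:
  # x ranks (1, 2.5, 2.5, 4, 5), y ranks (2, 1, 4, 3, 5) -> rho = Pearson
  # correlation of the average ranks
  x2 <- c(1, 2, 2, 3, 4)
  y2 <- c(10, 5, 30, 20, 40)
  expect_equal(change_association(x2, y2)$rho,
               cor(c(1, 2.5, 2.5, 4, 5), c(2, 1, 4, 3, 5)))
  # independent deltas at n = 27 stay small in >= 95% of 500 sims
  set.seed(14)
  small <- vapply(1:500, function(i)
    abs(change_association(rnorm(27), rnorm(27))$rho) < 0.5, logical(1))
  expect_gte(mean(small), 0.95)
})

test_that("prediction_error reports scale-free MSE and correlation", {
  set.seed(15)
  s <- rnorm(40)
  pred <- 3 + 2 * s
  pe <- prediction_error(pred, s)
  expect_equal(pe$r, 1)
  expect_equal(pe$mse, 0, tolerance = 1e-20)
  # symmetry of r
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(prediction_error(a, b)$r, prediction_error(b, a)$r)
  # independent uniforms: E[MSE] = 1/6 within 10%
  set.seed(16)
  mses <- vapply(1:400, function(i)
    prediction_error(runif(100), runif(100))$mse, 0)
  expect_lt(abs(mean(mses) - 1 / 6), 0.1 / 6)
  expect_error(prediction_error(rep(1, 10), rnorm(10)), "constant")
})

test_that("associate_factors ties the pieces together with an FDR family", {
  set.seed(17)
  n <- 120
  L <- rdirich(n, rep(1, 3))
  site <- sample(c("s1", "s2"), n, TRUE)
  phen <- data.frame(a.item1 = 2 * L[, 2] + rnorm(n),
                     a.item2 = rnorm(n),
                     b.item1 = rnorm(n))
  scales <- list(a = c("a.item1", "a.item2"), b = "b.item1")
  res <- associate_factors(L, phen, scales, site = site, n_perm = 199,
                           seed = 18)
  expect_equal(nrow(res$results), 6)          # 3 factors x 2 scales
  expect_true(all(res$results$p > 0 & res$results$p <= 1))
  top <- res$results[which.min(res$results$p), ]
  expect_equal(top$factor, 2)
  expect_equal(top$scale, "a")
  stru <- res$structural
  expect_true(all(abs(stru$coefficient) <= 1 + 1e-12))
})
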
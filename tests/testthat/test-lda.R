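# unit tests for the variational latent factor model

test_that("fit_lda separates a disjoint-vocabulary corpus", {
  docsA <- lapply(1:5, function(i) mkdoc(1:3, c(5, 3, 2), 6))
  docsB <- lapply(1:5, function(i) mkdoc(4:6, c(4, 4, 2), 6))
  fit <- fit_lda(c(docsA, docsB), K = 2, alpha = 0.5, eta = 0.01,
                 n_restarts = 4, max_iter = 200, seed = 1)
  b <- fit$model$beta
  expect_true(all(abs(rowSums(b) - 1) < 1e-8))
  grpA <- which.max(b[, 1] + b[, 2] + b[, 3])
  expect_gte(sum(b[grpA, 1:3]), 0.99)
  expect_gte(sum(b[-grpA, 4:6]), 0.99)
  expect_true(all(fit$expressions >= 0))
  expect_true(all(abs(rowSums(fit$expressions) - 1) < 1e-8))
  expect_error(fit_lda(list(), 2), "empty corpus")
  expect_error(fit_lda(docsA, K = 6), "exceeds")
})

test_that("K = 1 degenerates to smoothed corpus frequencies", {
  docs <- lapply(1:4, function(i) mkdoc(c(1, 3), c(i, 5 - i), 4))
  fit <- fit_lda(docs, K = 1, alpha = 1, eta = 0.05, n_restarts = 1,
                 max_iter = 50, seed = 2)
  freq <- rep(0, 4)
  for (d in docs) freq[d$ids] <- freq[d$ids] + d$counts
  expect_equal(drop(fit$model$beta), (freq + 0.05) / sum(freq + 0.05),
               tolerance = 1e-10)
  expect_equal(fit$expressions, matrix(1, 4, 1))
  # elbo equals the multinomial log-likelihood under the smoothed
  # frequencies (Dirichlet prior terms vanish at K = 1)
  closed <- sum(vapply(docs, function(d)
    sum(d$counts * log(fit$model$beta[1, d$ids])), 0))
  expect_equal(elbo(fit$model, docs), closed, tolerance = 1e-8)
})

test_that("the variational bound is certified by the enumeration oracle", {
  set.seed(3)
  for (rep in 1:5) {
    docs <- list(mkdoc(sample(3, 2), sample(3, 2, TRUE), 3),
                 mkdoc(sample(3, 2), sample(2, 2, TRUE), 3))
    for (method in c("ml", "vb")) {
      fit <- suppressWarnings(
        fit_lda(docs, K = 2, alpha = 0.7, eta = 0.1, n_restarts = 3,
                max_iter = 300, tol = 1e-8, seed = rep, method = method))
      exact <- sum(vapply(docs, exact_logevidence, 0,
                          beta = fit$model$beta, alpha = rep(0.7, 2)))
      # the point-beta bound never exceeds the exact log-evidence at the
      # reported beta, whichever way the model was fitted
      expect_lte(elbo(fit$model, docs), exact + 1e-10)
      # monotone objective within the best restart
      expect_true(all(diff(fit$model$fit_log) >=
                        -1e-6 * abs(fit$model$fit_log[-1])))
    }
  }
})

test_that("infer_expression is consistent with training and with planted docs", {
  world <- build_encoded_cohort(41, R = 16, K = 3, n = 80, n_controls = 80)
  fit <- suppressWarnings(
    fit_lda(world$docs, K = 3, alpha = 1, eta = 0.01, n_restarts = 2,
            max_iter = 200, tol = 1e-6, seed = 42))
  # training documents round-trip
  re <- infer_expression(fit$model, world$docs)
  expect_lt(max(abs(re - fit$expressions)), 0.02)
  # a document drawn exactly from factor k's beta concentrates on k
  set.seed(43)
  for (k in 1:3) {
    w <- sample(fit$model$V, 10000, replace = TRUE,
                prob = fit$model$beta[k, ])
    tab <- table(w)
    doc <- mkdoc(as.integer(names(tab)), as.numeric(tab), fit$model$V)
    expect_gte(infer_expression(fit$model, doc)[k], 0.95)
  }
  # near-empty doc: posterior mean proportional to alpha-weighted beta
  doc1 <- mkdoc(5L, 1, fit$model$V)
  e1 <- infer_expression(fit$model, doc1)
  expect_equal(sum(e1), 1, tolerance = 1e-8)
  # vocabulary mismatch refused
  expect_error(infer_expression(fit$model, mkdoc(1, 2, 10)), "mismatch")
})

test_that("match_factors recovers planted permutations and equals brute force", {
  set.seed(44)
  A <- matrix(rnorm(4 * 50), 4)
  perm <- c(3, 1, 4, 2)
  expect_equal(match_factors(A, A[perm, ]), order(perm))
  expect_equal(match_factors(A, A), 1:4)
  for (t in 1:25) {
    K <- sample(2:5, 1)
    X <- matrix(rnorm(K * 30), K)
    Y <- matrix(rnorm(K * 30), K)
    expect_equal(match_factors(X, Y), brute_match(X, Y))
  }
})

test_that("threshold_profile ranks by magnitude with deterministic ties", {
  expect_equal(threshold_profile(c(5, -4, 3, 1), 0.5), c(1, 2))
  expect_equal(threshold_profile(c(5, -4, 3, 1), 1.0), 1:4)
  # ties at the cutoff resolved by edge index
  expect_equal(threshold_profile(c(2, 2, 2, 1), 0.5), c(1, 2))
  # count contract on random profiles
  set.seed(45)
  for (t in 1:10) {
    w <- rnorm(37) * rbinom(37, 1, 0.7)
    sel <- threshold_profile(w, 0.5)
    expect_length(sel, ceiling(0.5 * sum(w != 0)))
  }
})

test_that("bootstrap_profiles flags planted edges and is reproducible", {
  world <- build_encoded_cohort(46, R = 12, K = 3, n = 60, n_controls = 80)
  ci <- suppressWarnings(
    bootstrap_profiles(world$docs, K = 3, B = 25, seed = 47,
                       n_restarts = 2, max_iter = 100, tol = 1e-5,
                       alpha = 1))
  expect_s3_class(ci, "factor_profile_ci")
  expect_true(all((ci$q < 0.05) == ci$mask))
  # strong planted edges are mostly recovered
  perm <- match_factors(world$profiles, ci$signed_profile)
  hits <- vapply(1:3, function(k) {
    strong <- which(abs(world$profiles[k, ]) > 1.5)
    mean(ci$mask[perm[k], strong])
  }, 0)
  expect_gt(mean(hits), 0.6)
  ci2 <- suppressWarnings(
    bootstrap_profiles(world$docs, K = 3, B = 25, seed = 47,
                       n_restarts = 2, max_iter = 100, tol = 1e-5,
                       alpha = 1))
  expect_identical(ci$mask, ci2$mask)
  expect_error(bootstrap_profiles(world$docs, 3, B = 10), "at least 20")
})

test_that("scan_k reports held-out likelihood tables deterministically", {
  world <- build_encoded_cohort(48, R = 10, K = 2, n = 40, n_controls = 60)
  tab <- suppressWarnings(
    scan_k(world$docs, K_range = 2, n_folds = 4, seed = 49,
           n_restarts = 1, max_iter = 80, tol = 1e-4))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$K, 2)
  tab2 <- suppressWarnings(
    scan_k(world$docs, K_range = 2, n_folds = 4, seed = 49,
           n_restarts = 1, max_iter = 80, tol = 1e-4))
  expect_identical(tab, tab2)
})

test_that("cross-validation prefers the generating K", {
  # data planted with K = 4: held-out likelihood at K = 4 should beat
  # K = 2 in most worlds (scaled-down version of the model-selection
  # simulation: 5 worlds instead of 20 to stay inside the time budget)
  wins <- 0
  for (s in 1:5) {
    world <- build_encoded_cohort(60 + s, R = 14, K = 4, n = 60,
                                  n_controls = 80)
    tab <- suppressWarnings(
      scan_k(world$docs, K_range = c(2, 4), n_folds = 3,
             seed = derive_seed(60, s), n_restarts = 1, max_iter = 80,
             tol = 1e-4, alpha = 1))
    wins <- wins + (tab$heldout_loglik[tab$K == 4] >=
                      tab$heldout_loglik[tab$K == 2])
  }
  expect_gte(wins, 4)
})

test_that("model archives round-trip through JSON", {
  world <- build_encoded_cohort(50, R = 10, K = 2, n = 30, n_controls = 60)
  fit <- suppressWarnings(
    fit_lda(world$docs, K = 2, alpha = 1, eta = 0.01, n_restarts = 1,
            max_iter = 60, seed = 51))
  f <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, f)
  m2 <- load_model(f)
  expect_equal(m2$beta, fit$model$beta, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m2$vocabulary, fit$model$vocabulary)
  expect_equal(infer_expression(m2, world$docs[[1]]),
               infer_expression(fit$model, world$docs[[1]]),
               tolerance = 1e-10)
  expect_error(load_model(system.file("DESCRIPTION", package = "connlda")))
})
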
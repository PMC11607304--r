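# Hierarchical Bayesian latent factor model: LDA over signed edge counts,
# fitted by variational EM. Subjects are documents; the 2E-word vocabulary
# holds hyper-/hypo-connectivity tokens per edge (see encode_counts()).

check_corpus <- function(docs) {
  if (length(docs) == 0L) stopf("empty corpus")
  V <- vapply(docs, function(d) d$V, numeric(1))
  if (length(unique(V)) != 1L)
    stopf("documents disagree on vocabulary size")
  tot <- vapply(docs, function(d) d$total, numeric(1))
  if (any(tot <= 0)) stopf("document(s) with zero tokens")
  as.integer(V[1L])
}

corpus_ids <- function(docs) lapply(docs, function(d) d$ids - 1L)
corpus_cnts <- function(docs) lapply(docs, function(d) d$counts)

# beta block of the variational-Bayes ELBO: E[log p(beta | eta)] -
# E[log q(beta)] for the factor-word Dirichlet posteriors lambda
beta_elbo_term <- function(lambda, elog_beta, eta) {
  V <- ncol(lambda)
  sum(lgamma(V * eta) - V * lgamma(eta) +
        rowSums((eta - lambda) * elog_beta) +
        rowSums(lgamma(lambda)) - lgamma(rowSums(lambda)))
}

# E[log beta] under the rowwise Dirichlet posterior
elog_beta_of <- function(lambda) digamma(lambda) - digamma(rowSums(lambda))

#' Fit the latent factor (LDA) model by variational EM
#'
#' Mean-field variational inference per document (Dirichlet over factor
#' proportions, multinomial responsibilities per token) alternating with a
#' variational-Bayes M-step for the factor-word matrix: each factor row
#' keeps a Dirichlet posterior (smoothing eta), and documents see its
#' expected log weights. The reported `beta` is the posterior mean. The
#' recorded objective is the full variational ELBO and is non-decreasing
#' over iterations. Several random restarts are run; the restart with the
#' best final objective is kept (ties broken by lowest restart index).
#'
#' @param docs list of `count_document`s (see [encode_counts()]).
#' @param K number of factors.
#' @param alpha Dirichlet hyperparameter on factor proportions, scalar or
#'   length-K (default 50/K, standard topic-model practice).
#' @param eta topic-word smoothing (default 0.01).
#' @param n_restarts random restarts (default 10).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param tol relative change in objective declaring convergence
#'   (default 1e-5).
#' @param seed integer seed; restart r uses `derive_seed(seed, r)`.
#' @param inner_iter,inner_tol per-document fixed-point controls (cold
#'   start).
#' @param warm_inner per-document sweeps per EM iteration once
#'   warm-started (partial E-step; coordinate ascent keeps the objective
#'   monotone at any value).
#' @param method "vb" (default): full variational Bayes over the
#'   factor-word rows, documents see the expected log weights - the
#'   better optimizer on hard corpora. "ml": classic variational EM with
#'   a point beta and smoothed M-step; its reported objective is the
#'   point-beta bound certified by [elbo()] against exact enumeration on
#'   tiny corpora.
#' @param verbose print per-restart progress.
#' @return list with `model` (a `factor_model`: `beta` K x V rows summing
#'   to 1, `alpha`, `eta`, `K`, `V`, `vocabulary`, `fit_log`,
#'   `restart_elbos`, `converged`) and `expressions` (N x K matrix of
#'   normalized variational Dirichlet means, rows on the simplex).
#' @export
fit_lda <- function(docs, K, alpha = 50 / K, eta = 0.01, n_restarts = 10,
                    max_iter = 500, tol = 1e-5, seed = 1,
                    inner_iter = 100, inner_tol = 1e-6, warm_inner = 3,
                    method = c("vb", "ml"), verbose = FALSE) {
  method <- match.arg(method)
  V <- check_corpus(docs)
  D <- length(docs)
  if (!is_count(K)) stopf("K must be a positive integer")
  if (K > D) stopf("K = %d exceeds the number of documents (%d)", K, D)
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  if (length(alpha) != K || any(alpha <= 0)) stopf("alpha must be positive")
  check_scalar(eta, "eta", lower = 0, open_lower = TRUE)

  ids <- corpus_ids(docs)
  cnts <- corpus_cnts(docs)

  best <- NULL
  restart_elbos <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    # full variational Bayes: Dirichlet posterior lambda over each
    # factor-word row; documents see E[log beta] (digamma weights).
    # Topics are seeded from small random subsets of documents (plus
    # jitter), which anchors restarts near distinct corpus modes and is
    # markedly more stable than pure random initialization.
    lambda <- with_seed(derive_seed(seed, r), {
      lam <- matrix(rgamma(K * V, shape = 100) / 100, K, V)
      nseed <- min(3L, D)
      for (k in seq_len(K)) {
        pick <- sample.int(D, nseed)
        for (d in pick)
          lam[k, ids[[d]] + 1L] <- lam[k, ids[[d]] + 1L] +
            cnts[[d]] / nseed
      }
      lam + eta
    })
    see_beta <- function(lam) {
      if (method == "vb") elog_beta_of(lam) else log(lam / rowSums(lam))
    }
    objective_of <- function(bound, lam, elb) {
      if (method == "vb") bound + beta_elbo_term(lam, elb, eta)
      # ml: penalized likelihood objective maximized exactly by the
      # smoothed M-step (eta * log beta acts as the conjugate penalty)
      else bound + eta * sum(elb)
    }
    elb <- see_beta(lambda)
    fit_log <- numeric(0)
    obj_prev <- -Inf
    converged <- FALSE
    gam <- NULL   # warm-started across EM iterations (coordinate ascent)
    for (it in seq_len(max_iter)) {
      # after the cold-start iteration a single responsibilities/gamma
      # sweep per document suffices (partial E-step; the objective is
      # still non-decreasing because every sweep is coordinate ascent)
      es <- lda_estep(ids, cnts, elb, alpha,
                      if (is.null(gam)) inner_iter else warm_inner,
                      inner_tol, compute_ss = TRUE, gamma_init = gam)
      gam <- es$gamma
      obj <- objective_of(es$bound, lambda, elb)
      fit_log <- c(fit_log, obj)
      lambda <- es$ss + eta
      elb <- see_beta(lambda)
      if (is.finite(obj_prev) &&
          abs(obj - obj_prev) <= tol * abs(obj_prev)) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
    # one final E-step so gamma and lambda are mutually consistent at the
    # reported objective
    es <- lda_estep(ids, cnts, elb, alpha, inner_iter, inner_tol,
                    compute_ss = FALSE, gamma_init = gam)
    obj <- objective_of(es$bound, lambda, elb)
    fit_log <- c(fit_log, obj)
    restart_elbos[r] <- obj
    if (verbose)
      message(sprintf("restart %d: objective %.4f (%d iterations%s)",
                      r, obj, length(fit_log),
                      if (converged) "" else ", not converged"))
    if (is.null(best) || obj > best$objective) {
      best <- list(beta = lambda / rowSums(lambda), gamma = es$gamma,
                   fit_log = fit_log, objective = obj,
                   converged = converged, restart = r)
    }
  }
  if (!best$converged)
    warnf("best restart did not converge within max_iter = %d", max_iter)

  expressions <- best$gamma / rowSums(best$gamma)
  model <- structure(list(beta = best$beta, alpha = alpha, eta = eta,
                          K = K, V = V,
                          vocabulary = attr(docs, "vocabulary"),
                          fit_log = best$fit_log,
                          restart_elbos = restart_elbos,
                          best_restart = best$restart,
                          converged = best$converged),
                     class = "factor_model")
  list(model = model, expressions = expressions)
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: K = %d factors over V = %d signed edge words\n",
              x$K, x$V))
  cat(sprintf("  best restart %d/%d, objective %.2f (%sconverged)\n",
              x$best_restart, length(x$restart_elbos),
              max(x$restart_elbos), if (x$converged) "" else "not "))
  invisible(x)
}

#' Infer factor expression for an unseen subject
#'
#' Runs per-document variational inference with the factor-word matrix
#' held fixed, starting from uniform responsibilities, so the result is
#' deterministic given the model and the document.
#'
#' @param model a `factor_model`.
#' @param doc a `count_document` (or list of them).
#' @param max_iter,tol fixed-point controls.
#' @return a length-K simplex vector (or N x K matrix for a list input).
#' @export
infer_expression <- function(model, doc, max_iter = 200, tol = 1e-8) {
  docs <- if (inherits(doc, "count_document")) list(doc) else doc
  V <- check_corpus(docs)
  if (V != model$V)
    stopf("vocabulary mismatch: document V = %d, model V = %d", V, model$V)
  es <- lda_estep(corpus_ids(docs), corpus_cnts(docs), log(model$beta),
                  model$alpha, max_iter, tol, compute_ss = FALSE)
  expr <- es$gamma / rowSums(es$gamma)
  if (inherits(doc, "count_document")) drop(expr) else expr
}

#' Evidence lower bound of the model on a corpus
#'
#' Sum over documents of the converged per-document variational bound on
#' `log p(doc | beta, alpha)` (beta treated as a point parameter; the
#' topic-smoothing prior term is not included). For tiny corpora this is
#' certified to lie at or below the exact log-evidence obtained by
#' enumerating all token-to-factor assignments.
#'
#' @param model a `factor_model`.
#' @param docs list of `count_document`s.
#' @param max_iter,tol fixed-point controls.
#' @return a scalar lower bound (nats).
#' @export
elbo <- function(model, docs, max_iter = 500, tol = 1e-10) {
  V <- check_corpus(docs)
  if (V != model$V) stopf("vocabulary mismatch")
  es <- lda_estep(corpus_ids(docs), corpus_cnts(docs), log(model$beta),
                  model$alpha, max_iter, tol, compute_ss = FALSE)
  es$bound
}

#' Signed connectivity profile of each factor
#'
#' Collapses the signed vocabulary back to edges: mass on `edge+` minus
#' mass on `edge-`, optionally renormalized per factor by the maximum
#' absolute value (display convention).
#'
#' @param model a `factor_model` (V must be even, 2E).
#' @param rescale divide each row by its max |value| (default FALSE).
#' @return K x E signed matrix.
#' @export
signed_profile <- function(model, rescale = FALSE) {
  if (model$V %% 2L != 0L) stopf("vocabulary is not a signed edge vocabulary")
  E <- model$V %/% 2L
  sp <- model$beta[, seq_len(E), drop = FALSE] -
    model$beta[, E + seq_len(E), drop = FALSE]
  if (rescale) {
    mx <- apply(abs(sp), 1L, max)
    mx[mx == 0] <- 1
    sp <- sp / mx
  }
  sp
}

#' Match factors between two fits (label-switching resolution)
#'
#' Finds the permutation of B's rows maximizing the total Pearson
#' correlation with A's rows, solved exactly as a linear assignment
#' problem (Jonker-Volgenant shortest augmenting paths).
#'
#' @param betaA,betaB K x V matrices (rows = factors).
#' @return integer permutation `perm` such that `betaB[perm[k], ]` matches
#'   `betaA[k, ]`.
#' @export
match_factors <- function(betaA, betaB) {
  if (!all(dim(betaA) == dim(betaB)))
    stopf("factor matrices must have identical dimensions")
  K <- nrow(betaA)
  cc <- suppressWarnings(stats::cor(t(betaA), t(betaB)))
  cc[!is.finite(cc)] <- 0
  solve_assignment(-cc)
}

#' Bootstrap edge-wise significance of factor profiles
#'
#' Resamples subjects (documents) with replacement B times, refits the
#' model from scratch on each resample, matches each replicate's factors
#' to the full-data fit, and forms per-factor per-edge z = mean/sd of the
#' signed profile across replicates. Two-sided normal p-values are
#' Benjamini-Hochberg adjusted across all K*E tests; the significance
#' mask is q < `fdr_alpha`.
#'
#' @param docs list of `count_document`s.
#' @param K number of factors.
#' @param B bootstrap replicates (>= 20).
#' @param seed integer seed.
#' @param fdr_alpha FDR threshold (default 0.05).
#' @param n_restarts,max_iter,tol,alpha,eta fit parameters; replicate fits
#'   default to a single restart for tractability.
#' @param boot_restarts restarts per replicate fit (default 1).
#' @return a `factor_profile_ci`: list with K x E matrices `mean`, `sd`,
#'   `z`, `p`, `q`, logical `mask`, the full-fit `signed_profile`,
#'   `model`, and `expressions`.
#' @export
bootstrap_profiles <- function(docs, K, B, seed = 1, fdr_alpha = 0.05,
                               alpha = 50 / K, eta = 0.01, n_restarts = 5,
                               max_iter = 200, tol = 1e-5,
                               boot_restarts = 1) {
  if (!is_count(B) || B < 20)
    stopf("B must be at least 20 (bootstrap sd unstable below that)")
  full <- fit_lda(docs, K, alpha = alpha, eta = eta,
                  n_restarts = n_restarts, max_iter = max_iter, tol = tol,
                  seed = derive_seed(seed, 0))
  sp_full <- signed_profile(full$model)
  E <- ncol(sp_full)
  D <- length(docs)
  acc <- array(NA_real_, dim = c(B, K, E))
  for (b in seq_len(B)) {
    idx <- with_seed(derive_seed(seed, 1000 + b),
                     sample.int(D, D, replace = TRUE))
    boot_docs <- docs[idx]
    attr(boot_docs, "vocabulary") <- attr(docs, "vocabulary")
    fb <- suppressWarnings(
      fit_lda(boot_docs, K, alpha = alpha, eta = eta,
              n_restarts = boot_restarts, max_iter = max_iter, tol = tol,
              seed = derive_seed(seed, 2000 + b)))
    perm <- match_factors(full$model$beta, fb$model$beta)
    acc[b, , ] <- signed_profile(fb$model)[perm, , drop = FALSE]
  }
  mu <- apply(acc, c(2, 3), mean)
  sdev <- apply(acc, c(2, 3), sd)
  z <- mu / sdev
  z[sdev == 0 & mu != 0] <- Inf * sign(mu[sdev == 0 & mu != 0])
  z[sdev == 0 & mu == 0] <- 0
  p <- 2 * pnorm(-abs(z))
  q <- matrix(fdr_adjust(as.vector(p)), K, E)
  structure(list(mean = mu, sd = sdev, z = z, p = p, q = q,
                 mask = q < fdr_alpha, fdr_alpha = fdr_alpha,
                 signed_profile = sp_full, model = full$model,
                 expressions = full$expressions, B = B),
            class = "factor_profile_ci")
}

#' Threshold a factor profile to its strongest edges
#'
#' Retains the `ceiling(fraction * m)` edges of largest absolute weight,
#' where m is the number of nonzero-weight edges in the supplied profile
#' (pass a significance-masked profile to threshold among significant
#' edges only). Ties at the cutoff are broken by edge index.
#'
#' @param profile length-E numeric vector of per-edge weights.
#' @param fraction fraction in (0, 1] to retain (default 0.5).
#' @return sorted integer vector of retained edge indices.
#' @export
threshold_profile <- function(profile, fraction = 0.5) {
  check_scalar(fraction, "fraction", lower = 0, upper = 1, open_lower = TRUE)
  nz <- which(profile != 0)
  if (length(nz) == 0L) return(integer(0))
  m <- ceiling(fraction * length(nz))
  o <- nz[order(-abs(profile[nz]), nz)]
  sort(o[seq_len(m)])
}

#' Cross-validated factor-count scan
#'
#' Document-level cross-validation: for each K, fit on the training folds,
#' infer factor expression for held-out documents, and score them by the
#' plug-in predictive log-likelihood sum_w c_w log(theta' beta[, w]).
#' The table is reported without automatic selection.
#'
#' @param docs list of `count_document`s.
#' @param K_range integer vector of candidate factor counts.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed (fold assignment and fits).
#' @param ... passed to [fit_lda()].
#' @return data frame with columns `K`, `heldout_loglik` (total),
#'   `per_token` (per held-out token).
#' @export
scan_k <- function(docs, K_range, n_folds = 5, seed = 1, ...) {
  D <- length(docs)
  if (n_folds < 2 || n_folds > D) stopf("invalid n_folds")
  fold <- with_seed(derive_seed(seed, 77),
                    sample(rep_len(seq_len(n_folds), D)))
  res <- lapply(K_range, function(K) {
    ll <- 0; ntok <- 0
    for (f in seq_len(n_folds)) {
      train <- docs[fold != f]; test <- docs[fold == f]
      attr(train, "vocabulary") <- attr(docs, "vocabulary")
      fit <- suppressWarnings(
        fit_lda(train, K, seed = derive_seed(seed, 100 * K + f), ...))
      theta <- infer_expression(fit$model, test)
      if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
      pw <- theta %*% fit$model$beta      # n_test x V predictive word probs
      for (i in seq_along(test)) {
        d <- test[[i]]
        ll <- ll + sum(d$counts * log(pw[i, d$ids]))
        ntok <- ntok + d$total
      }
    }
    c(K = K, heldout_loglik = ll, per_token = ll / ntok)
  })
  as.data.frame(do.call(rbind, res))
}
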
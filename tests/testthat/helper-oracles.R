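# shared fixtures and independent oracles (kept deliberately separate from
# the code paths they check)

# bare count document
mkdoc <- function(ids, counts, V) {
  structure(list(ids = as.integer(ids), counts = as.numeric(counts),
                 total = sum(counts), V = as.integer(V)),
            class = "count_document")
}

# exact log-evidence of one document under fixed beta/alpha by exhaustive
# enumeration of token-to-factor assignments (Dirichlet-multinomial prior
# over assignment counts); tractable only for a handful of tokens
exact_logevidence <- function(doc, beta, alpha) {
  toks <- rep(doc$ids, doc$counts)
  n <- length(toks)
  K <- nrow(beta)
  a0 <- sum(alpha)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- apply(grid, 1L, function(z) {
    nk <- tabulate(z, K)
    lgamma(a0) - lgamma(a0 + n) +
      sum(lgamma(alpha + nk) - lgamma(alpha)) +
      sum(log(beta[cbind(z, toks)]))
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# all permutations of 1..n (small n)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# brute-force factor matching by enumeration over all K! permutations
brute_match <- function(betaA, betaB) {
  K <- nrow(betaA)
  cc <- suppressWarnings(cor(t(betaA), t(betaB)))
  cc[!is.finite(cc)] <- 0
  pm <- all_perms(K)
  vals <- apply(pm, 1L, function(p) sum(cc[cbind(seq_len(K), p)]))
  unname(pm[which.max(vals), ])
}

# plant a K-factor world, sample + encode a cohort; returns everything a
# recovery test needs
build_encoded_cohort <- function(world_seed, R = 32, K = 4, n = 300,
                                 n_controls = 150, noise_sd = 0.5,
                                 dirichlet_alpha = 1, scale = 10,
                                 clip = 3, sparsity = 0.25) {
  parc <- default_parcellation(R)
  profiles <- generate_factor_profiles(K, parc, sparsity = sparsity,
                                       seed = world_seed)
  truth <- ground_truth(profiles, parc)
  coh <- sample_cohort(truth, n, rep(dirichlet_alpha, K), noise_sd,
                       seed = derive_seed(world_seed, 1))
  ctl <- sample_controls(n_controls, parc, noise_sd,
                         seed = derive_seed(world_seed, 2))
  ref <- fit_reference(ctl$deviations)
  docs <- lapply(seq_len(n), function(i)
    encode_counts(deviation_score(vectorize(coh$matrices[[i]]), NULL, ref),
                  scale = scale, clip = clip))
  attr(docs, "vocabulary") <- edge_vocabulary(parc)
  list(parc = parc, profiles = profiles, truth = truth, cohort = coh,
       reference = ref, docs = docs)
}

# encode additional subjects against an existing world/reference
encode_more <- function(world, n, seed, dirichlet_alpha = 1,
                        noise_sd = 0.5, scale = 10, clip = 3) {
  K <- world$truth$K
  coh <- sample_cohort(world$truth, n, rep(dirichlet_alpha, K), noise_sd,
                       seed = seed)
  docs <- lapply(seq_len(n), function(i)
    encode_counts(deviation_score(vectorize(coh$matrices[[i]]), NULL,
                                  world$reference),
                  scale = scale, clip = clip))
  attr(docs, "vocabulary") <- edge_vocabulary(world$parc)
  list(cohort = coh, docs = docs)
}

# simplex Dirichlet sampler for association-level tests
rdirich <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  x / rowSums(x)
}

# construct an edge_set directly (the exported constructors are
# provenance-specific)
new_edge_set_for_test <- function(e) {
  structure(list(edges = sort(unique(as.integer(e))), provenance = "test"),
            class = "edge_set")
}

# internal config validator (not part of the exported surface)
validate_config_for_test <- function(cfg) connlda:::validate_config(cfg)
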
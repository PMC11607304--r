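# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == round(x) && x > 0

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stopf("'%s' must be a single finite number", name)
  lo <- if (open_lower) x > lower else x >= lower
  hi <- if (open_upper) x < upper else x <= upper
  if (!lo || !hi)
    stopf("'%s' = %g is outside its valid range", name, x)
  invisible(x)
}

#' Derive a stage-specific seed from a root seed
#'
#' All pipeline randomness flows from one root seed; each stage (and each
#' restart / bootstrap replicate) uses `derive_seed(seed, k)` with a fixed
#' stage offset `k` so runs are bit-reproducible. Derived seeds stay below
#' 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param k nonnegative integer offset.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 69069 + 12345 + k) %% 2147483647)
}

# evaluate `code` under a temporary RNG state seeded by `seed`;
# the caller's RNG stream is left untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    set.seed(seed)
  }
  force(code)
}

# Dirichlet sampler (rows of the returned matrix lie on the simplex)
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  # guard against underflow at very small alpha: resample zeros from a
  # tiny positive floor rather than returning a degenerate 0/0 row
  rs <- rowSums(x)
  bad <- rs == 0
  if (any(bad)) {
    x[bad, ] <- matrix(rgamma(sum(bad) * k, shape = 1), ncol = k)
    rs[bad] <- rowSums(x[bad, , drop = FALSE])
  }
  x / rs
}
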
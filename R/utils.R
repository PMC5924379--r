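# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed_ <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# sample() without the length-1 surprise: sample_int(5, 1) draws from 1:5,
# resample(x) always treats x as the candidate set.
resample <- function(x, size = 1L, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size = size, replace = replace, prob = prob)]
}

# Canonical ordering of feature-domain tags (demographics first).
DOMAIN_TAGS <- c("demo", "l", "p", "d", "c", "s")

abort_config <- function(msg) {
  rlang::abort(msg, class = "fedsimhash_config_error")
}

abort_dim <- function(msg) {
  rlang::abort(msg, class = "fedsimhash_dim_error")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == as.integer(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
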
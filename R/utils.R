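# Internal helpers shared across modules.

# Derive a reproducible 31-bit seed from a base seed plus integer tags.
# Mixing is a small LCG-style hash; stays strictly below 2^31 so it is a
# valid R seed on all platforms.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) {
    h <- (h * 69069 + (as.numeric(t) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == as.integer(x)
}

# Digest of a numeric parameter set (order-sensitive); used for sync-event
# audit logs and result caching.
params_digest <- function(x) {
  unname(hash(lapply(x, function(m) round(unclass(m), 12))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
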
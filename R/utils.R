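# internal helpers

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a substream seed from a master seed, staying inside 32-bit range.
derive_seed <- function(seed, k) {
  (as.integer(seed) * 1000003L + as.integer(k) * 7919L) %% 2147483081L
}

clamp01 <- function(x) pmin(1, pmax(0, x))
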
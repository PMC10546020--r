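#' @keywords internal
"_PACKAGE"

# Run code with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Derive a deterministic sub-seed from a root seed; keeps values < 2^31.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 1009 + k) %% 2147483647
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
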
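# Internal helpers shared across modules.

# Run code under a fixed seed without disturbing the caller's RNG stream.
# A NULL seed leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed, staying inside 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 1009 * k) %% 2147483647
}

`%||%` <- rlang::`%||%`

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
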
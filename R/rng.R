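#' Derive a child seed from a master seed
#'
#' Deterministic seed-splitting rule used throughout the package so that
#' every afferent, neuron and trial gets its own reproducible random stream.
#' The master seed is folded with each id by a multiplicative-congruential
#' step; all intermediate values stay below 2^53 so the arithmetic is exact
#' in double precision, and the result is always a valid 32-bit seed.
#'
#' @param seed integer master seed.
#' @param ... integer ids (folded left to right), e.g. trial index, hair index.
#' @return an integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, 3, 7)
#' @export
derive_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (id in c(...)) {
    s <- (s * 69069 + as.numeric(id) + 1) %% 2147483647
  }
  as.integer(s)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's .Random.seed afterwards. If seed is NULL the
## current stream is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}
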
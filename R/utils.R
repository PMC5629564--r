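# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so no function touches global state.
# seed = NULL means: use (and advance) the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}
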
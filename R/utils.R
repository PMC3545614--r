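# Run expr under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards so package functions never perturb the global RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Deterministic sub-seed derivation; keeps results < 2^31 for set.seed().
subSeed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + offset * 104729) %% 2147483647
}
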
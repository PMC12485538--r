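# Evaluate `code` with the RNG seeded at `seed` (if non-NULL), restoring the
# caller's RNG state afterwards so library code never perturbs user
# reproducibility. With seed = NULL the current RNG stream is used (and
# advanced) as usual.
with_preserved_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
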
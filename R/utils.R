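# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library functions never clobber user randomness.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Index of the grid band nearest to a wavelength; errors outside the grid.
nearestBand <- function(grid, nm) {
  v <- if (is(grid, "WavelengthGrid")) grid@values else as.numeric(grid)
  if (nm < min(v) || nm > max(v))
    stop(sprintf("wavelength %.1f nm outside grid range [%.1f, %.1f]",
                 nm, min(v), max(v)))
  which.min(abs(v - nm))
}

# Round half-up to `digits` decimals (matching printed-percentage style).
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
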
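## Shared fixtures: reference conditions of the calibration experiments
## and small builders used across test files.

env23 <- ambientConditions(23, 20)
blood <- bloodProperties()
consts <- physicalConstants()
model0 <- calibratedModel()
tilePrior <- tileSurfacePrior()

## A mid-sized pool with the calibration-mean height (deterministic).
referenceScenario <- function(seed = 1L, ...) {
  poolScenario(5.24e-3, height = tilePrior@heightMean, seed = seed, ...)
}

## Rasterised disc mask (pixel-centre sampling).
discMask <- function(radiusPx, n = ceiling(2 * radiusPx) + 20L) {
  c0 <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n)
  (xs - c0)^2 + (t(xs) - c0)^2 <= radiusPx^2
}
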
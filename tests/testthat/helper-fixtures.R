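# Small generator presets used across tests: full statistical structure,
# coarse grid / reduced panel for speed.

smallConfig <- function(seed = 1L, ...) {
  generatorConfig(nGenotypes = 40L, nPlots = 2L, nYears = 2L,
                  wnStep = 40, seed = seed, ...)
}

noiselessConfig <- function(seed = 1L, ...) {
  smallConfig(seed = seed, noiseSd = 0, scatterMultSd = 0,
              scatterOffsetSd = 0, scatterSlopeSd = 0,
              plotEffectSd = 0, repNoiseSd = 0, ...)
}

# a SpectraSet from a plain matrix on an arbitrary uniform grid
toySpectra <- function(m, wn = seq(4000, by = 4, length.out = ncol(m)),
                       ids = sprintf("T%02d", seq_len(nrow(m))))
  SpectraSet(m, wn, ids = ids)

sampleSkewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5
}
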
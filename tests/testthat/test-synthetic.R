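test_that("pure components are smooth, positive, reproducible and full rank", {
  cfg <- smallConfig(seed = 42L)
  S1 <- simulatePureComponents(cfg)
  S2 <- simulatePureComponents(cfg)
  expect_identical(S1, S2)
  expect_true(all(S1 > 0))
  expect_equal(qr(S1)$rank, cfg@nComponents)
  expect_equal(dim(S1), c(3L, 151L))
})

test_that("a single Gaussian band peaks at its center", {
  wn <- defaultGrid()
  band <- exp(-0.5 * ((wn - 7000) / 200)^2)
  expect_equal(wn[which.max(band)], 7000)
})

test_that("panels are deterministic in the seed", {
  p1 <- simulatePanel(smallConfig(seed = 9L))
  p2 <- simulatePanel(smallConfig(seed = 9L))
  expect_identical(absorbance(p1@spectra), absorbance(p2@spectra))
  expect_identical(p1@traits, p2@traits)
  p3 <- simulatePanel(smallConfig(seed = 10L))
  expect_false(identical(absorbance(p1@spectra), absorbance(p3@spectra)))
})

test_that("noiseless panels are exactly low rank", {
  p <- simulatePanel(noiselessConfig())
  pca <- fitPCA(p@spectra, k = 5L)
  expect_gte(pca@cumExplained[3], 1 - 1e-10)
  expect_lt(sum(pca@explained[4:5]), 1e-10)
})

test_that("panel ground truth reproduces the traits", {
  p <- simulatePanel(smallConfig(seed = 3L))
  reconstructed <- drop(p@concentrations %*% p@beta) + p@beta0
  expect_equal(unname(reconstructed), unname(p@trueTrait), tolerance = 1e-12)
  # replicate measurements scatter around the true trait with the
  # configured noise
  tr <- p@traits
  resid <- tr$crushing_strength_kN - p@trueTrait[tr$sample_id]
  expect_lt(abs(mean(resid)), 3 * p@config@repNoiseSd / sqrt(nrow(tr)) + 0.01)
})

test_that("the paper-like preset hits the configured trait mean", {
  p <- simulatePanel(generatorConfig(nYears = 1L, nPlots = 1L, seed = 42L,
                                     wnStep = 400))
  g <- p@trueTrait
  se <- 0.28 / sqrt(length(g))
  expect_lt(abs(mean(g) - 1.30), 3 * se + 0.28 * 0.05) # clamp shifts < 5% SD
  expect_gte(min(p@traits$crushing_strength_kN), 0.69 - 4 * 0.10)
})

test_that("zero plot effect and replicate noise give identical traits across plots", {
  p <- simulatePanel(noiselessConfig(seed = 5L))
  tr <- p@traits[p@traits$year == min(p@traits$year) & p@traits$replicate == 1L, ]
  wide <- tapply(tr$crushing_strength_kN, list(tr$genotype, tr$plot), mean)
  expect_equal(unname(wide[, 1]), unname(wide[, 2]), tolerance = 1e-12)
})

test_that("genotype traits stay approximately normal across seeds", {
  skews <- vapply(1:50, function(s) {
    p <- simulatePanel(generatorConfig(nPlots = 1L, nYears = 1L,
                                       wnStep = 400, seed = s))
    sampleSkewness(p@trueTrait)
  }, numeric(1))
  expect_true(all(abs(skews) <= 0.5))
})

test_that("tiny panels are refused", {
  expect_error(simulatePanel(smallConfig(nGenotypes = 5L)), "nGenotypes")
})

test_that("generator config invariants are enforced", {
  expect_error(generatorConfig(wnStart = 5000, wnEnd = 4000), "wnEnd")
  expect_error(generatorConfig(wnStep = -1), "positive|wnEnd")
  expect_error(generatorConfig(traitMean = 3), "traitMin")
  expect_error(generatorConfig(noiseSd = -0.1), "sd")
  expect_length(configGridLen <- defaultGrid(), 1501L)
})

test_that("force curves respect the instrument threshold", {
  for (s in 1:5) {
    cv <- simulateForceCurve(1.3, seed = s)
    expect_lte(max(cv@force), 4.0)
    expect_gte(tail(cv@force, 1), 4.0 * (1 - 1e-9))
  }
  expect_error(simulateForceCurve(4.2, seed = 1), "trueStrength")
  expect_error(simulateForceCurve(4.0, seed = 1), "trueStrength")
})

test_that("force curves are deterministic in (strength, seed)", {
  a <- simulateForceCurve(1.1, seed = 33)
  b <- simulateForceCurve(1.1, seed = 33)
  expect_identical(a@force, b@force)
  expect_identical(a@time, b@time)
  expect_equal(diff(a@time), rep(100, length(a@time) - 1))
})

test_that("designed peak heights are honoured and first peak is not the max", {
  cv <- simulateForceCurve(1.2, seed = 4, jitter = 0,
                           peaks = c(1.2, 1.5, 0.9))
  pk <- detectPeaks(cv)
  expect_equal(pk@firstPeak, 1.2)
  expect_equal(max(pk@peakForces[1:3]), 1.5)
  expect_gt(max(cv@force), 1.5) # final strengthening rise tops the peaks
})
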
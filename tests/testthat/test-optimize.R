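test_that("scatter-correcting pretreatments beat NONE on planted scatter", {
  # multiplicative scatter also multiplies the trait band, so no linear
  # model on the raw spectra can fully recover the trait; SNV/MSC undo the
  # scatter exactly and restore near-perfect calibration
  set.seed(21)
  wn <- seq(4000, by = 40, length.out = 150)
  base <- 1 + exp(-0.5 * ((wn - 6000) / 800)^2) +
    0.5 * exp(-0.5 * ((wn - 9000) / 500)^2)
  band <- exp(-0.5 * ((wn - 5000) / 300)^2)
  n <- 80
  t <- rnorm(n); m <- rnorm(n, 0, 0.2); a <- rnorm(n, 0, 0.3)
  X <- (1 + m) %o% (3 * base) + (0.1 * t * (1 + m)) %o% band +
    a %o% rep(1, length(wn))
  y <- t + rnorm(n, 0, 0.02)
  s <- toySpectra(X, wn, ids = sprintf("s%02d", 1:n))
  sc <- cvScheme(seed = 2L)
  res <- optimizeModel(s, y, pretreatments = c("NONE", "SNV", "MSC", "FD_SNV"),
                       regions = list(regionSpec(1, 1, 1)),
                       maxRank = 6, scheme = sc)
  none <- calibrate(s, y, pretreatment = "NONE", maxRank = 6, scheme = sc)
  expect_false(res@model@pretreatment@code == "NONE")
  expect_lt(res@RMSECV, 0.5 * none@RMSECV)
})

test_that("the search finds the subregion carrying the signal", {
  set.seed(31)
  n <- 60; p <- 150
  X <- matrix(rnorm(n * p), n, p)
  blocks <- floor(seq(0, p, length.out = 11))
  cols3 <- (blocks[3] + 1):blocks[4]
  y <- rowMeans(X[, cols3]) + rnorm(n, 0, 0.02)
  s <- toySpectra(X)
  res <- optimizeModel(s, y, pretreatments = "NONE", maxRank = 5,
                       scheme = cvScheme(seed = 3L))
  expect_lte(res@model@region@from, 3)
  expect_gte(res@model@region@to, 3)
  expect_gt(res@R2cv, 0.9)
})

test_that("a single-candidate search returns that candidate", {
  ms <- modelingSet(simulatePanel(smallConfig(seed = 22L)))
  res <- optimizeModel(ms$spectra, ms$y, pretreatments = "COE",
                       regions = list(regionSpec(2, 4, 5)),
                       maxRank = 4, scheme = cvScheme(seed = 1L))
  expect_identical(res@model@pretreatment@code, "COE")
  expect_identical(c(res@model@region@from, res@model@region@to), c(2L, 4L))
  expect_error(optimizeModel(ms$spectra, ms$y, pretreatments = character()),
               "empty")
})

test_that("optimisation is deterministic given seeds and inputs", {
  ms <- modelingSet(simulatePanel(smallConfig(seed = 23L)))
  run <- function() optimizeModel(ms$spectra, ms$y,
                                  pretreatments = c("NONE", "SNV", "FD"),
                                  maxRank = 5,
                                  scheme = cvScheme(seed = 5L))
  a <- run(); b <- run()
  expect_identical(a@model@pretreatment@code, b@model@pretreatment@code)
  expect_identical(a@cvCurve, b@cvCurve)
  expect_equal(a@model@coefficients, b@model@coefficients)
})

test_that("integrative recalibration pools disjoint sets and refuses overlap", {
  ms <- modelingSet(simulatePanel(smallConfig(seed = 24L)))
  sp <- ms$spectra
  plan <- splitCalibrationValidation(sampleIds(sp), seed = 2L, y = ms$y)
  xC <- sp[, plan@calibration]; yC <- ms$y[plan@calibration]
  xV <- sp[, plan@validation]; yV <- ms$y[plan@validation]
  sc <- cvScheme(seed = 6L)
  cal <- calibrate(xC, yC, pretreatment = "SNV", maxRank = 5, scheme = sc)
  pooled <- integrativeRecalibrate(cal, xC, yC, xV, yV, scheme = sc)
  expect_equal(pooled@n, length(ms$y))
  # pooling an identically distributed set should not hurt beyond CV noise
  expect_gte(pooled@R2cv, cal@R2cv - 0.02)
  expect_error(integrativeRecalibrate(cal, xC, yC, xC, yC), "overlap")
})

test_that("validation metrics use the frozen calibration model", {
  ms <- modelingSet(simulatePanel(smallConfig(seed = 25L)))
  sp <- ms$spectra
  plan <- splitCalibrationValidation(sampleIds(sp), seed = 3L, y = ms$y)
  cal <- calibrate(sp[, plan@calibration], ms$y[plan@calibration],
                   pretreatment = "FD", maxRank = 5,
                   scheme = cvScheme(seed = 7L))
  val <- validateModel(cal, sp[, plan@validation], ms$y[plan@validation])
  expect_gt(val@R2ev, 0.5)
  expect_equal(val@RPDev^2 * (1 - val@R2ev), 1, tolerance = 1e-10)
  expect_equal(val@n, length(plan@validation))
})
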
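test_that("COE subtracts the per-spectrum minimum", {
  expect_equal(coe(c(1, 2, 3)), c(0, 1, 2))
  expect_equal(coe(c(5, 5)), c(0, 0))
  expect_equal(coe(c(0, 1, 2)), c(0, 1, 2)) # min already zero
  expect_equal(coe(coe(c(4, 7, 9))), coe(c(4, 7, 9))) # idempotent
})

test_that("SSL removes the least-squares straight line", {
  wn <- seq(4000, 4100, by = 4)
  expect_equal(ssl(2 + 0.03 * wn, wn), rep(0, length(wn)), tolerance = 1e-9)
  expect_equal(ssl(rep(5, length(wn)), wn), rep(0, length(wn)))
  # quadratic on a symmetric grid: residual has zero mean and zero slope
  u <- wn - mean(wn)
  r <- ssl(u^2, wn)
  expect_lt(abs(mean(r)), 1e-9)
  expect_lt(abs(sum(r * u)), 1e-6)
  expect_error(ssl(c(1, 2), c(4000, 4004)), "3 points")
})

test_that("SNV standardises each spectrum with the n-1 SD", {
  expect_equal(snv(c(0, 1, 2)), c(-1, 0, 1))
  x <- rnorm(50)
  expect_lt(abs(mean(snv(x))), 1e-12)
  expect_equal(sd(snv(x)), 1)
  expect_error(snv(rep(2, 10)), "constant")
})

test_that("SNV exactly removes affine scatter and is idempotent", {
  s <- rnorm(80)
  expect_equal(snv(3.2 * s + 1.7), snv(s), tolerance = 1e-12)
  expect_equal(snv(snv(s)), snv(s), tolerance = 1e-12)
})

test_that("MMN maps min to 0 and max to 2 and is idempotent", {
  expect_equal(mmn(c(1, 3)), c(0, 2))
  expect_equal(mmn(c(0, 1, 2)), c(0, 1, 2))
  expect_error(mmn(rep(1, 5)), "constant")
  x <- rnorm(30)
  expect_equal(mmn(mmn(x)), mmn(x), tolerance = 1e-12)
})

test_that("MSC recovers spectra from planted affine scatter", {
  ref <- rnorm(60)
  expect_equal(mscApply(ref, ref), ref, tolerance = 1e-12)
  expect_equal(mscApply(2 * ref + 0.5, ref), ref, tolerance = 1e-12)
  X <- rbind(ref, 1.5 * ref - 1, 0.7 * ref + 2)
  expect_equal(unname(mscApply(X, ref)),
               matrix(ref, 3, length(ref), byrow = TRUE), tolerance = 1e-10)
  expect_error(mscApply(rep(1, 60), ref), "degenerate")
  expect_error(mscFit(matrix(1, 1, 4)), "2 calibration")
})

test_that("Savitzky-Golay derivatives match closed forms including edges", {
  wn <- seq(4000, 4400, by = 4)
  lin <- 3 + 0.01 * wn
  expect_equal(sgDerivative(lin, 1, 17, 2, step = 4), rep(0.01, length(wn)),
               tolerance = 1e-10)
  expect_equal(sgDerivative(rep(2, length(wn)), 1, 17, 2, step = 4),
               rep(0, length(wn)), tolerance = 1e-12)
  a <- 3e-6
  quad <- a * wn^2
  expect_equal(sgDerivative(quad, 2, 17, 2, step = 4),
               rep(2 * a, length(wn)), tolerance = 1e-10)
  # FD kills additive constants; SED kills additive linear baselines
  x <- sin(wn / 100)
  expect_equal(sgDerivative(x + 7, 1, 17, 2, 4), sgDerivative(x, 1, 17, 2, 4),
               tolerance = 1e-8)
  expect_equal(sgDerivative(x + 5 + 0.02 * wn, 2, 17, 3, 4),
               sgDerivative(x, 2, 17, 3, 4), tolerance = 1e-8)
  expect_error(sgDerivative(x[1:5], 1, 17, 2, 4), "window")
  expect_error(sgDerivative(x, 3, 17, 2, 4), "order")
})

test_that("applyPretreatment dispatches and combines stages in order", {
  wn <- seq(4000, by = 4, length.out = 100)
  lin <- outer(c(1, 2), rep(1, 100)) + outer(c(0.01, 0.02), wn)
  s <- SpectraSet(lin, wn, ids = c("a", "b"))
  expect_equal(absorbance(applyPretreatment(s, "NONE")), absorbance(s))
  # FD of a line is a constant; SSL then removes it
  out <- absorbance(applyPretreatment(s, "FD_SSL"))
  expect_equal(unname(out), matrix(0, 2, 100), tolerance = 1e-9)
})

test_that("MSC-bearing codes freeze the calibration reference", {
  set.seed(1)
  wn <- seq(4000, by = 4, length.out = 120)
  base <- sin(wn / 150)
  cal <- SpectraSet(rbind(base * 1.2 + 0.1, base * 0.8 - 0.2, base + 0.05),
                    wn, ids = c("c1", "c2", "c3"))
  val <- SpectraSet(rbind(base * 1.1 + 0.3), wn, ids = "v1")
  ref <- pretreatmentReference(cal, pretreatmentSpec("FD_MSC"))
  frozen <- absorbance(applyPretreatment(val, "FD_MSC", reference = ref))
  refit <- absorbance(applyPretreatment(
    SpectraSet(rbind(base * 1.1 + 0.3, base * 2), wn, ids = c("v1", "v2")),
    "FD_MSC"))[1, , drop = FALSE]
  expect_s4_class(applyPretreatment(cal, "FD_MSC"), "SpectraSet")
  expect_false(isTRUE(all.equal(frozen, refit)))
})

test_that("pretreatment spec validity catches bad Savitzky-Golay settings", {
  expect_error(pretreatmentSpec("FD", sgWindow = 16L), "odd")
  expect_error(pretreatmentSpec("WAVELET"), "code")
  expect_identical(length(pretreatCodes()), 11L)
})
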
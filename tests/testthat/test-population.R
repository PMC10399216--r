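test_that("splitting is a deterministic exact partition at the ratio", {
  ids <- sprintf("S%03d", 1:335)
  y <- rnorm(335, 1.3, 0.28)
  a <- splitCalibrationValidation(ids, seed = 7L, y = y, counts = c(262, 73))
  b <- splitCalibrationValidation(ids, seed = 7L, y = y, counts = c(262, 73))
  expect_identical(a@calibration, b@calibration)
  expect_length(a@calibration, 262)
  expect_length(a@validation, 73)
  expect_setequal(c(a@calibration, a@validation), ids)
  expect_length(intersect(a@calibration, a@validation), 0)

  d <- splitCalibrationValidation(ids, ratio = 4, seed = 1L, y = y)
  expect_equal(length(d@calibration), round(335 * 4 / 5))
  expect_error(splitCalibrationValidation(ids, ratio = 0.5, seed = 1, y = y),
               "ratio")
  expect_error(splitCalibrationValidation(ids[1:5], seed = 1), "10 samples")
})

test_that("coverage enforcement puts the extreme samples in calibration", {
  ids <- sprintf("S%02d", 1:50)
  for (s in 1:20) {
    y <- rnorm(50)
    pl <- splitCalibrationValidation(ids, seed = s, y = y)
    expect_true(ids[which.min(y)] %in% pl@calibration)
    expect_true(ids[which.max(y)] %in% pl@calibration)
    expect_true(pl@rangeCheck)
  }
})

test_that("group correlations recover degenerate and noiseless limits", {
  df <- data.frame(genotype = rep(letters[1:6], 2),
                   group = rep(c("P1", "P2"), each = 6),
                   value = rep(1:6, 2))
  cg <- correlateGroups(df)
  expect_equal(cg$r["P1", "P2"], 1)

  p <- simulatePanel(noiselessConfig(seed = 2L))
  tr <- p@traits[p@traits$replicate == 1 & p@traits$year == min(p@traits$year), ]
  cg2 <- correlateGroups(data.frame(genotype = tr$genotype, group = tr$plot,
                                    value = tr$crushing_strength_kN))
  expect_equal(cg2$r["P1", "P2"], 1, tolerance = 1e-12)
})

test_that("the default preset gives highly significant cross-plot correlations", {
  p <- simulatePanel(generatorConfig(nYears = 1L, wnStep = 400, seed = 42L))
  tr <- aggregate(crushing_strength_kN ~ genotype + plot, p@traits, mean)
  cg <- correlateGroups(data.frame(genotype = tr$genotype, group = tr$plot,
                                   value = tr$crushing_strength_kN))
  off <- cg$p[upper.tri(cg$p)]
  expect_true(all(off < 0.001))
  expect_true(all(cg$r[upper.tri(cg$r)] > 0.8))
})

test_that("pairs with too few shared genotypes are undefined", {
  df <- data.frame(genotype = c("a", "b", "a", "b"),
                   group = c("P1", "P1", "P2", "P2"), value = rnorm(4))
  cg <- correlateGroups(df)
  expect_true(is.na(cg$r["P1", "P2"]))
  expect_equal(cg$n["P1", "P2"], 2)
})

test_that("screening of perfectly correlated years keeps ceil(q n) genotypes", {
  v <- rnorm(100)
  wide <- cbind(`2019` = v, `2020` = v, `2021` = v)
  rownames(wide) <- sprintf("G%03d", 1:100)
  sc <- screenExtremes(wide, q = 0.1)
  expect_length(sc@high, 10)
  expect_length(sc@low, 10)
  expect_length(intersect(sc@high, sc@low), 0)
  expect_true(all(sort(wide[sc@high, 1], decreasing = TRUE) >=
                  max(wide[sc@low, 1])))
})

test_that("independent years almost never screen consistent extremes", {
  counts <- vapply(1:20, function(s) {
    wide <- withr::with_seed(s, matrix(rnorm(300 * 3), 300, 3,
                             dimnames = list(sprintf("G%03d", 1:300),
                                             c("y1", "y2", "y3"))))
    sc <- suppressWarnings(screenExtremes(wide, q = 0.1))
    length(sc@high)
  }, numeric(1))
  expect_true(all(counts <= 3)) # null expectation n q^3 = 0.3
})

test_that("screening rejects invalid quantiles and single years", {
  wide <- matrix(rnorm(60), 30, 2)
  expect_error(screenExtremes(wide, q = 0.6), "q must")
  expect_error(screenExtremes(wide[, 1, drop = FALSE]), "2 years")
})

test_that("ANOVA with LSD letters separates clear groups", {
  set.seed(8)
  g <- rep(c("A", "B"), each = 10)
  v <- c(rnorm(10, 0, 1), rnorm(10, 5, 1))
  res <- groupCompare(v, g)
  expect_lt(res$p, 0.001)
  expect_false(res$letters["A"] == res$letters["B"])

  # two identical groups: same letter, p = 1 under exact ties
  res2 <- groupCompare(rep(c(1, 2), 4), rep(c("A", "B"), each = 4))
  expect_identical(unname(res2$letters["A"]), unname(res2$letters["B"]))

  # three hugely separated groups get three distinct letters
  v3 <- c(rnorm(8, 0, 0.1), rnorm(8, 10, 0.1), rnorm(8, 20, 0.1))
  res3 <- groupCompare(v3, rep(c("lo", "mid", "hi"), each = 8))
  expect_length(unique(res3$letters), 3)
  expect_error(groupCompare(1:5, c("a", "a", "a", "a", "b")), "at least 2")
})
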
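test_that("the first PLS weight vector is proportional to X'y", {
  set.seed(11)
  X <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20)
  m <- fitPLS(X, y, rank = 1)
  w <- drop(crossprod(sweep(X, 2, colMeans(X)), y - mean(y)))
  expect_equal(unname(m@weights[, 1]), w / sqrt(sum(w^2)), tolerance = 1e-12)
})

test_that("full-rank PLS equals ordinary least squares predictions", {
  set.seed(21)
  n <- 40; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p)) + 0.5 + rnorm(n, 0, 0.3)
  m <- fitPLS(X, y, rank = p)
  # independent oracle: OLS via the normal equations
  Xi <- cbind(1, X)
  bOls <- solve(crossprod(Xi), crossprod(Xi, y))
  expect_equal(unname(predict(m, X)), drop(Xi %*% bOls), tolerance = 1e-8)
})

test_that("coefficient predictions equal sequential NIPALS score predictions", {
  set.seed(31)
  X <- matrix(rnorm(200), 25, 8)
  y <- rnorm(25)
  m <- fitPLS(X, y, rank = 4)
  # replay scores sequentially with deflation
  Xd <- sweep(X, 2, m@xMean)
  yhat <- rep(m@yMean, nrow(X))
  for (a in seq_len(m@rank)) {
    t <- drop(Xd %*% m@weights[, a])
    yhat <- yhat + m@yLoadings[a] * t
    Xd <- Xd - tcrossprod(t, m@loadings[, a])
  }
  expect_equal(unname(predict(m, X)), yhat, tolerance = 1e-8)
})

test_that("degenerate PLS inputs are refused", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fitPLS(X, rep(1, 10), rank = 2), "variance")
  expect_error(fitPLS(X, rnorm(10), rank = 10), "exceeds")
})

test_that("predicting the calibration mean spectrum returns the y mean", {
  p <- simulatePanel(noiselessConfig())
  ms <- modelingSet(p)
  m <- fitPLS(ms$spectra, ms$y, rank = 3)
  meanSpec <- SpectraSet(matrix(colMeans(absorbance(ms$spectra)), 1),
                         wavenumbers(ms$spectra), ids = "mean")
  expect_equal(unname(predict(m, meanSpec)), mean(ms$y), tolerance = 1e-8)
})

test_that("a rank-n_components model recovers noiseless traits exactly", {
  p <- simulatePanel(noiselessConfig())
  ms <- modelingSet(p)
  m <- fitPLS(ms$spectra, ms$y, rank = 3)
  expect_equal(unname(predict(m, ms$spectra)), unname(ms$y),
               tolerance = 1e-8)
})

test_that("prediction rejects mismatched grids", {
  p <- simulatePanel(noiselessConfig())
  ms <- modelingSet(p)
  m <- fitPLS(ms$spectra, ms$y, rank = 2)
  other <- SpectraSet(matrix(rnorm(10), 1), seq(900, by = 2, length.out = 10),
                      ids = "x")
  expect_error(predict(m, other), "grid mismatch")
  # a model fit on a decimated grid applies to full-grid spectra
  md <- fitPLS(decimateSpectra(ms$spectra, 2L),
               ms$y, rank = 2)
  expect_equal(predict(md, ms$spectra), predict(md, decimateSpectra(ms$spectra, 2L)))
})

test_that("leave-one-out CV equals the brute-force hold-one-out loop", {
  set.seed(5)
  X <- matrix(rnorm(5 * 3), 5, 3)
  y <- rnorm(5)
  cv <- crossValidate(X, y, maxRank = 2, scheme = cvScheme("loo"))
  for (k in 1:2) {
    pred <- vapply(1:5, function(i) {
      m <- fitPLS(X[-i, , drop = FALSE], y[-i], rank = k)
      unname(predict(m, X[i, , drop = FALSE]))
    }, numeric(1))
    expect_equal(cv$curve$RMSECV[k], sqrt(mean((pred - y)^2)),
                 tolerance = 1e-10)
  }
})

test_that("k-fold CV is reproducible under a fixed seed and null R2cv is small", {
  set.seed(77)
  X <- matrix(rnorm(200 * 10), 200, 10)
  y <- rnorm(200)
  a <- crossValidate(X, y, maxRank = 3, scheme = cvScheme("kfold", 10, seed = 4))
  b <- crossValidate(X, y, maxRank = 3, scheme = cvScheme("kfold", 10, seed = 4))
  expect_identical(a$curve, b$curve)
  expect_true(all(a$curve$R2cv <= 0.1)) # y independent of X
})

test_that("near-perfect linear data cross-validates to R2cv near 1", {
  set.seed(6)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- drop(X %*% c(1, -2, 0.5, 3)) + rnorm(60, 0, 1e-6)
  cv <- crossValidate(X, y, maxRank = 4, scheme = cvScheme("loo"))
  expect_gt(cv$curve$R2cv[4], 1 - 1e-6)
})

test_that("training RMSEC is non-increasing in rank", {
  set.seed(41)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(50, 0, 0.5)
  rmsec <- vapply(1:6, function(k) {
    m <- fitPLS(X, y, rank = k)
    sqrt(mean((predict(m, X) - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("metrics obey their closed forms and the RPD identity", {
  y <- c(1, 2, 3, 4)
  perfect <- regressionMetrics(y, y)
  expect_equal(perfect$R2, 1)
  expect_equal(perfect$RMSE, 0)
  expect_equal(perfect$bias, 0)
  expect_true(is.infinite(perfect$RPD))

  const <- regressionMetrics(y, rep(mean(y), 4))
  expect_equal(const$R2, 0)
  expect_equal(const$RPD, 1)

  set.seed(9)
  for (i in 1:20) {
    yt <- rnorm(30); yp <- yt + rnorm(30, 0, runif(1, 0.05, 2))
    m <- regressionMetrics(yt, yp)
    expect_equal(m$RPD^2 * (1 - m$R2), 1, tolerance = 1e-10)
  }
  expect_error(regressionMetrics(1, 1), "2 observations")
})

test_that("rank selection applies the 2% parsimony rule", {
  expect_equal(selectRank(c(1.0, 0.50, 0.495, 0.494)), 2)
  expect_equal(selectRank(seq(1, 0.1, length.out = 8)), 8)
  expect_equal(selectRank(rep(0.3, 5)), 1)
})

test_that("the modified-PLS variant is available and consistent at rank p", {
  set.seed(13)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- drop(X %*% rnorm(5)) + rnorm(40, 0, 0.2)
  m <- fitPLS(X, y, rank = 5, method = "mpls")
  Xi <- cbind(1, X)
  bOls <- solve(crossprod(Xi), crossprod(Xi, y))
  expect_equal(unname(predict(m, X)), drop(Xi %*% bOls), tolerance = 1e-6)
})
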
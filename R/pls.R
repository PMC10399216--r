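# Core NIPALS PLS-1 on a plain matrix. Returns centering stats, W/P/q and
# the coefficient vector for every rank 1..rank (coefs[, k]).
# method "mpls" additionally standardises residual X columns between
# factors (the WinISI-style modified PLS); scalings are recorded so
# prediction can replay them.
.nipals <- function(X, y, rank, method = c("pls", "mpls")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  rank <- as.integer(rank)
  if (rank < 1L) stop("rank must be >= 1")
  if (rank > min(n - 1L, p))
    stop("rank ", rank, " exceeds min(n-1, p) = ", min(n - 1L, p))
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("X and y must be finite")
  if (var(y) == 0) stop("y has zero variance")
  xMean <- colMeans(X)
  yMean <- mean(y)
  Xd <- sweep(X, 2, xMean)
  yd <- y - yMean
  W <- matrix(0, p, rank); P <- matrix(0, p, rank); q <- numeric(rank)
  resSd <- matrix(1, p, rank)
  for (a in seq_len(rank)) {
    if (method == "mpls") {
      s <- sqrt(colMeans(Xd^2))
      s[s < 1e-12] <- 1
      resSd[, a] <- s
      Xd <- sweep(Xd, 2, s, "/")
    }
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { # residual uncorrelated with y: stop early
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      q <- q[seq_len(a - 1L)]
      resSd <- resSd[, seq_len(a - 1L), drop = FALSE]
      rank <- a - 1L
      break
    }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    pv <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pv)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
  }
  if (rank == 0L) stop("no usable PLS factor (y uncorrelated with X)")
  coefs <- matrix(0, p, rank)
  if (method == "pls") {
    # b_k = W_k (P_k' W_k)^{-1} q_k for every k
    PtW <- crossprod(P, W) # upper triangular
    for (k in seq_len(rank)) {
      rk <- seq_len(k)
      coefs[, k] <- W[, rk, drop = FALSE] %*%
        solve(PtW[rk, rk, drop = FALSE], q[rk])
    }
  } else {
    # replay the per-factor scalings on the weight/loading space
    for (k in seq_len(rank)) {
      b <- numeric(p)
      # accumulate via the sequential definition: x-residual scaling means
      # the effective weights in original units are w_a / cumprod(scales)
      Weff <- W[, seq_len(k), drop = FALSE]
      Peff <- P[, seq_len(k), drop = FALSE]
      cum <- rep(1, p)
      for (a in seq_len(k)) {
        cum2 <- cum * resSd[, a]
        Weff[, a] <- W[, a] / cum2
        Peff[, a] <- P[, a] * cum2
        cum <- cum2
      }
      PtW <- crossprod(Peff, Weff)
      coefs[, k] <- Weff %*% solve(PtW, q[seq_len(k)])
    }
  }
  list(xMean = xMean, yMean = yMean, W = W, P = P, q = q, coefs = coefs,
       rank = rank, method = method, resSd = resSd)
}

# Region helpers -----------------------------------------------------------

#' Build a wavelength-region window
#'
#' @param from,to block indices within the partition.
#' @param nSubregions number of equal blocks the grid is split into.
#' @return a [RegionSpec-class].
#' @export
regionSpec <- function(from = 1L, to = 10L, nSubregions = 10L)
  new("RegionSpec", nSubregions = as.integer(nSubregions),
      from = as.integer(from), to = as.integer(to))

#' @rdname regionSpec
#' @param region a `RegionSpec`.
#' @param p grid length the region is applied to.
#' @return `regionColumns`: integer column indices of the window.
#' @export
regionColumns <- function(region, p) {
  bounds <- floor(seq(0, p, length.out = region@nSubregions + 1L))
  cols <- (bounds[region@from] + 1L):bounds[region@to + 1L]
  if (!length(cols)) stop("empty region window")
  cols
}

#' Fit a PLS-1 calibration model
#'
#' Centered (unscaled) NIPALS partial least squares with a single response:
#' per factor, the weight vector is proportional to `X'y` (unit norm),
#' scores `t = Xw`, loadings `p = X't/t't`, `q = y't/t't`, then X and y are
#' deflated. Regression coefficients are assembled as
#' `b = W (P'W)^{-1} q`, and predictions via `b` equal predictions via the
#' sequential scores. The `"mpls"` method is the residual-standardising
#' modified-PLS variant; the default is plain PLS.
#'
#' @param x calibration spectra: a [SpectraSet-class] or a plain numeric
#'   matrix (samples x variables) of already-pretreated data.
#' @param y response (crushing strength, kN), one value per sample.
#' @param rank number of latent variables.
#' @param pretreatment a [PretreatmentSpec-class] (or code string) applied
#'   internally when `x` is a `SpectraSet`; its MSC reference is fit on `x`
#'   and frozen in the model.
#' @param region a [RegionSpec-class] restricting the wavelength window.
#' @param method `"pls"` or `"mpls"`.
#' @return a [PLSModel-class].
#' @export
fitPLS <- function(x, y, rank, pretreatment = pretreatmentSpec("NONE"),
                   region = NULL, method = c("pls", "mpls")) {
  method <- match.arg(method)
  if (is.character(pretreatment)) pretreatment <- pretreatmentSpec(pretreatment)
  if (is(x, "SpectraSet")) {
    grid <- wavenumbers(x)
    reference <- pretreatmentReference(x, pretreatment)
    Xfull <- absorbance(applyPretreatment(x, pretreatment, reference))
  } else {
    Xfull <- as.matrix(x)
    grid <- as.numeric(seq_len(ncol(Xfull)))
    reference <- NULL
    if (pretreatment@code != "NONE")
      stop("pretreatment requires a SpectraSet input")
  }
  if (is.null(region)) region <- regionSpec(1L, 1L, 1L)
  cols <- regionColumns(region, ncol(Xfull))
  fit <- .nipals(Xfull[, cols, drop = FALSE], y, rank, method)
  new("PLSModel", rank = fit$rank, xMean = fit$xMean, yMean = fit$yMean,
      weights = fit$W, loadings = fit$P, yLoadings = fit$q,
      coefficients = fit$coefs[, fit$rank], pretreatment = pretreatment,
      region = region, mscReference = reference %||% numeric(),
      grid = grid, method = fit$method, resSd = fit$resSd)
}

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel (%s): %d latent variables, %d variables in window [%d..%d]/%d, pretreatment %s\n",
              object@method, object@rank, length(object@coefficients),
              object@region@from, object@region@to,
              object@region@nSubregions, object@pretreatment@code))
})

#' Predict crushing strength from spectra
#'
#' Applies the model's pretreatment (with frozen calibration statistics)
#' and wavelength region, then `yhat = yMean + (x - xMean) b`. The incoming
#' grid must contain the training grid; extra wavenumbers are dropped, any
#' other mismatch is an error naming the expected grid.
#'
#' @param object a [PLSModel-class].
#' @param newdata a [SpectraSet-class] or a numeric matrix already on the
#'   model's pretreated, region-restricted scale.
#' @param ... unused.
#' @return named numeric vector of predictions, kN.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  if (is(newdata, "SpectraSet")) {
    wn <- wavenumbers(newdata)
    if (length(wn) != length(object@grid) || any(abs(wn - object@grid) > 1e-6)) {
      sub <- match(round(object@grid, 6), round(wn, 6))
      if (anyNA(sub))
        stop(sprintf(
          "grid mismatch: model expects %d points %g..%g cm-1",
          length(object@grid), min(object@grid), max(object@grid)))
      newdata <- newdata[sub, ]
    }
    ref <- if (length(object@mscReference)) object@mscReference else NULL
    m <- absorbance(applyPretreatment(newdata, object@pretreatment, ref))
    cols <- regionColumns(object@region, ncol(m))
    m <- m[, cols, drop = FALSE]
  } else {
    m <- .asRowMatrix(newdata)
    if (ncol(m) != length(object@xMean))
      stop("matrix input must have ", length(object@xMean), " columns")
  }
  drop(object@yMean + sweep(m, 2, object@xMean) %*% object@coefficients)
})

#' Regression evaluation metrics: R2, RMSE, RPD, bias
#'
#' `R2 = 1 - SSE/SST` (not squared Pearson correlation),
#' `RMSE = sqrt(SSE/n)` (n denominator), `RPD = SD(y)/RMSE` with the
#' n-denominator SD, and `bias = mean(pred - obs)`. With matching
#' denominators the identity `RPD = (1 - R2)^(-1/2)` holds exactly on a
#' common evaluation set: R2 = 0.90 corresponds to RPD 3.16.
#'
#' @param yTrue,yPred observed and predicted values (kN), length >= 2.
#' @return list: R2, RMSE, RPD (`Inf` for perfect fits), bias, n.
#' @export
regressionMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) < 2) stop("need at least 2 observations")
  err <- yPred - yTrue
  sse <- sum(err^2)
  sst <- sum((yTrue - mean(yTrue))^2)
  rmse <- sqrt(sse / length(yTrue))
  list(R2 = 1 - sse / sst, RMSE = rmse,
       RPD = if (rmse == 0) Inf else sdN(yTrue) / rmse,
       bias = mean(err), n = length(yTrue))
}

#' Cross-validation schemes
#'
#' @param type `"kfold"` (default, k = 10) or `"loo"`.
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @return a list describing the scheme.
#' @export
cvScheme <- function(type = c("kfold", "loo"), k = 10L, seed = 1L) {
  type <- match.arg(type)
  list(type = type, k = as.integer(k), seed = as.integer(seed))
}

.cvFolds <- function(n, scheme) {
  if (scheme$type == "loo") return(as.list(seq_len(n)))
  k <- min(scheme$k, n)
  idx <- withSeed(scheme$seed, sample.int(n))
  folds <- split(idx, cut(seq_len(n), k, labels = FALSE))
  if (any(lengths(folds) < 2) && scheme$type == "kfold")
    stop("a fold has fewer than 2 samples; reduce k")
  unname(folds)
}

#' Cross-validate a PLS calibration over ranks
#'
#' Pools out-of-fold predictions for every rank `1..maxRank` and reports
#' `R2cv = 1 - SSE/SST` (SST about the pooled-truth mean) and
#' `RMSECV = sqrt(SSE/n)`.
#'
#' @param X numeric matrix (samples x variables), already pretreated and
#'   region-restricted.
#' @param y response, kN.
#' @param maxRank largest rank to evaluate (capped by fold size).
#' @param scheme a [cvScheme()].
#' @param method `"pls"` or `"mpls"`.
#' @return list: `curve` (data.frame rank, RMSECV, R2cv),
#'   `predictions` (n x maxRank matrix of out-of-fold predictions).
#' @export
crossValidate <- function(X, y, maxRank = 10L, scheme = cvScheme(),
                          method = "pls") {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- .cvFolds(n, scheme)
  maxRank <- min(as.integer(maxRank),
                 min(vapply(folds, function(f) n - length(f), 0L)) - 1L,
                 ncol(X))
  if (maxRank < 1L) stop("not enough samples for cross-validation")
  pred <- matrix(NA_real_, n, maxRank)
  for (f in folds) {
    fit <- .nipals(X[-f, , drop = FALSE], y[-f], maxRank, method)
    Xc <- sweep(X[f, , drop = FALSE], 2, fit$xMean)
    ph <- fit$yMean + Xc %*% fit$coefs
    pred[f, seq_len(fit$rank)] <- ph
    if (fit$rank < maxRank) # early-stopped fit: carry last rank forward
      pred[f, (fit$rank + 1L):maxRank] <- ph[, fit$rank]
  }
  sst <- sum((y - mean(y))^2)
  rmse <- sqrt(colMeans((pred - y)^2))
  data.frame(rank = seq_len(maxRank), RMSECV = rmse,
             R2cv = 1 - colSums((pred - y)^2) / sst) -> curve
  list(curve = curve, predictions = pred)
}

#' Select the PLS rank from a cross-validation curve
#'
#' Parsimony rule: the smallest rank whose RMSECV is within `tol` (2% by
#' default) of the curve minimum; ties break toward the smaller rank.
#'
#' @param rmsecv numeric RMSECV per rank 1..maxRank.
#' @param tol relative tolerance above the minimum.
#' @return integer rank.
#' @examples selectRank(c(1.0, 0.50, 0.495, 0.494)) # 2
#' @export
selectRank <- function(rmsecv, tol = 0.02) {
  stopifnot(length(rmsecv) >= 1)
  which(rmsecv <= (1 + tol) * min(rmsecv))[1]
}
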
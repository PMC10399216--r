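#' The eleven pretreatment codes used in model optimisation
#'
#' `NONE` (no-op), `COE` (constant offset elimination), `SSL` (straight-line
#' subtraction), `SNV` (standard normal variate), `MMN` (min--max
#' normalisation), `MSC` (multiplicative scatter correction), `FD`/`SED`
#' (first/second Savitzky--Golay derivative), and the derivative-then-X
#' combinations `FD_SSL`, `FD_SNV`, `FD_MSC`.
#'
#' @return character vector of codes.
#' @export
pretreatCodes <- function() .PRETREAT_CODES

#' Build a pretreatment recipe
#'
#' @param code one of [pretreatCodes()].
#' @param sgWindow,sgPolyorder Savitzky--Golay filter window (odd, points)
#'   and polynomial order; defaults 17 and 2, the vendor-software
#'   convention for this instrument class.
#' @param derivativeFirst in combination codes apply the derivative before
#'   the scatter/baseline step (default, matching the combination naming);
#'   `FALSE` reverses for sensitivity analysis.
#' @return a [PretreatmentSpec-class].
#' @export
pretreatmentSpec <- function(code = "NONE", sgWindow = 17L, sgPolyorder = 2L,
                             derivativeFirst = TRUE) {
  new("PretreatmentSpec", code = toupper(code),
      sgWindow = as.integer(sgWindow), sgPolyorder = as.integer(sgPolyorder),
      derivativeFirst = derivativeFirst)
}

# ---- elementary pretreatments, vectorised over rows of a matrix ----------

.asRowMatrix <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

#' Elementary spectral pretreatments
#'
#' Low-level operations on a spectrum (numeric vector) or a set of spectra
#' (matrix, rows = spectra):
#' * `coe(x)` subtracts each spectrum's minimum (constant offset
#'   elimination), so `min = 0`.
#' * `ssl(x, wn)` subtracts each spectrum's least-squares straight line
#'   against wavenumber; the output is orthogonal to constants and to the
#'   wavenumber axis.
#' * `snv(x)` centers and scales each spectrum to mean 0, SD 1 (n-1
#'   denominator); removes additive offsets and multiplicative scatter
#'   exactly.
#' * `mmn(x)` maps each spectrum affinely so min = 0 and max = 2.
#' * `mscFit(x)` returns the mean calibration spectrum used as the MSC
#'   reference; `mscApply(x, ref)` regresses each spectrum on the reference
#'   (`x = a + b ref`) and returns `(x - a) / b`.
#' * `sgDerivative(x, order, window, polyorder, step)` is the
#'   Savitzky--Golay derivative with respect to wavenumber (divided by
#'   `step^order`), same length as the input with polynomial fits at the
#'   edges.
#'
#' @param x numeric vector (one spectrum) or matrix (rows = spectra).
#' @param wn wavenumber grid, cm-1.
#' @param ref reference spectrum (from `mscFit` on the calibration set).
#' @param order derivative order, 1 or 2.
#' @param window,polyorder Savitzky--Golay parameters (window odd,
#'   `window > polyorder >= order`).
#' @param step grid step, cm-1.
#' @return same shape as `x`.
#' @name elementary-pretreatments
NULL

#' @rdname elementary-pretreatments
#' @export
coe <- function(x) {
  m <- .asRowMatrix(x)
  out <- m - apply(m, 1, min)
  if (is.matrix(x)) out else drop(out)
}

#' @rdname elementary-pretreatments
#' @export
ssl <- function(x, wn) {
  m <- .asRowMatrix(x)
  if (ncol(m) < 3) stop("SSL needs at least 3 points")
  w <- wn - mean(wn)
  sw2 <- sum(w^2)
  slope <- (m %*% w) / sw2
  out <- m - rowMeans(m) - slope %*% w
  if (is.matrix(x)) out else drop(out)
}

#' @rdname elementary-pretreatments
#' @export
snv <- function(x) {
  m <- .asRowMatrix(x)
  s <- apply(m, 1, sd)
  if (any(s == 0))
    stop("constant spectrum (zero SD) in rows: ",
         paste(which(s == 0), collapse = ", "))
  out <- (m - rowMeans(m)) / s
  if (is.matrix(x)) out else drop(out)
}

#' @rdname elementary-pretreatments
#' @export
mmn <- function(x) {
  m <- .asRowMatrix(x)
  lo <- apply(m, 1, min); hi <- apply(m, 1, max)
  if (any(hi == lo))
    stop("constant spectrum (max == min) in rows: ",
         paste(which(hi == lo), collapse = ", "))
  out <- (m - lo) / (hi - lo) * 2
  if (is.matrix(x)) out else drop(out)
}

#' @rdname elementary-pretreatments
#' @export
mscFit <- function(x) {
  m <- .asRowMatrix(x)
  if (nrow(m) < 2) stop("MSC reference needs at least 2 calibration spectra")
  colMeans(m)
}

#' @rdname elementary-pretreatments
#' @export
mscApply <- function(x, ref) {
  m <- .asRowMatrix(x)
  if (ncol(m) != length(ref)) stop("reference length mismatch")
  rc <- ref - mean(ref)
  vr <- sum(rc^2)
  b <- drop((m - rowMeans(m)) %*% rc) / vr
  if (any(abs(b) < 1e-10))
    stop("degenerate MSC slope (|b| < 1e-10) in rows: ",
         paste(which(abs(b) < 1e-10), collapse = ", "))
  a <- rowMeans(m) - b * mean(ref)
  out <- (m - a) / b
  if (is.matrix(x)) out else drop(out)
}

#' @rdname elementary-pretreatments
#' @export
sgDerivative <- function(x, order = 1L, window = 17L, polyorder = 2L,
                         step = 1) {
  order <- as.integer(order); window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (!order %in% 1:2) stop("order must be 1 or 2")
  if (window %% 2L != 1L || window <= polyorder || polyorder < order)
    stop("need odd window > polyorder >= order")
  m <- .asRowMatrix(x)
  if (ncol(m) < window) stop("spectrum shorter than the filter window")
  out <- t(apply(m, 1, signal::sgolayfilt, p = polyorder, n = window,
                 m = order, ts = step))
  if (is.matrix(x)) out else drop(out)
}

# ---- composite application on SpectraSet ---------------------------------

# Stage decomposition of a code: list(derivOrder, scatter)
.decodePretreat <- function(code) {
  switch(code,
    NONE = list(deriv = 0L, scatter = "NONE"),
    COE = list(deriv = 0L, scatter = "COE"),
    SSL = list(deriv = 0L, scatter = "SSL"),
    SNV = list(deriv = 0L, scatter = "SNV"),
    MMN = list(deriv = 0L, scatter = "MMN"),
    MSC = list(deriv = 0L, scatter = "MSC"),
    FD = list(deriv = 1L, scatter = "NONE"),
    SED = list(deriv = 2L, scatter = "NONE"),
    FD_SSL = list(deriv = 1L, scatter = "SSL"),
    FD_SNV = list(deriv = 1L, scatter = "SNV"),
    FD_MSC = list(deriv = 1L, scatter = "MSC"),
    stop("unknown pretreatment code: ", code))
}

.applyStages <- function(m, wn, spec, reference) {
  st <- .decodePretreat(spec@code)
  step <- if (length(wn) > 1) wn[2] - wn[1] else 1
  doDeriv <- function(m) if (st$deriv == 0L) m else
    sgDerivative(m, order = st$deriv, window = spec@sgWindow,
                 polyorder = spec@sgPolyorder, step = step)
  doScatter <- function(m) switch(st$scatter,
    NONE = m, COE = coe(m), SSL = ssl(m, wn), SNV = snv(m), MMN = mmn(m),
    MSC = mscApply(m, reference))
  if (spec@derivativeFirst) doScatter(doDeriv(m)) else doDeriv(doScatter(m))
}

#' Frozen calibration statistics for a pretreatment
#'
#' Statistics-bearing pretreatments (the MSC reference) must be fit on the
#' calibration set only and frozen for validation and prediction. For MSC
#' codes this returns the calibration mean spectrum, computed after the
#' derivative stage for `FD_MSC`; for all other codes it returns `NULL`.
#'
#' @param x the calibration [SpectraSet-class].
#' @param spec a [PretreatmentSpec-class].
#' @return numeric reference spectrum or `NULL`.
#' @export
pretreatmentReference <- function(x, spec) {
  st <- .decodePretreat(spec@code)
  if (st$scatter != "MSC") return(NULL)
  m <- absorbance(x)
  wn <- wavenumbers(x)
  if (st$deriv > 0L && spec@derivativeFirst)
    m <- sgDerivative(m, order = st$deriv, window = spec@sgWindow,
                      polyorder = spec@sgPolyorder, step = wn[2] - wn[1])
  mscFit(m)
}

#' Apply a pretreatment to a set of spectra
#'
#' Dispatches on the recipe's code; combination codes apply the derivative
#' first, then the scatter/baseline step. For MSC codes, `reference = NULL`
#' fits the reference on `x` itself (calibration use); validation and
#' prediction must pass the frozen calibration reference from
#' [pretreatmentReference()].
#'
#' @param x a [SpectraSet-class].
#' @param spec a [PretreatmentSpec-class] (or a code string).
#' @param reference frozen MSC reference, or `NULL`.
#' @return a pretreated [SpectraSet-class] on the same grid.
#' @export
applyPretreatment <- function(x, spec, reference = NULL) {
  if (is.character(spec)) spec <- pretreatmentSpec(spec)
  validObject(spec)
  if (is.null(reference)) reference <- pretreatmentReference(x, spec)
  m <- tryCatch(
    .applyStages(absorbance(x), wavenumbers(x), spec, reference),
    error = function(e)
      stop("pretreatment ", spec@code, " failed: ", conditionMessage(e),
           call. = FALSE))
  setAbsorbance(x, m)
}
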
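#' Pretreatment-by-wavelength-region model optimisation
#'
#' Emulates the vendor-style calibration search: for every candidate
#' (pretreatment code x contiguous wavelength window over an equal
#' partition of the grid), pretreat the calibration spectra (MSC references
#' fit on the calibration set), restrict columns to the window,
#' cross-validate PLS over ranks, and record the minimum RMSECV. The
#' candidate minimising RMSECV wins; ties break toward fewer latent
#' variables, then the wider region, then the lexicographically smaller
#' pretreatment code. The final model is refit on the full calibration set
#' at the parsimony-selected rank.
#'
#' @param x calibration spectra, a [SpectraSet-class].
#' @param y calibration response, kN.
#' @param pretreatments character vector of codes (default all eleven).
#' @param nSubregions partition size for the window enumeration
#'   (default 10, i.e. 55 contiguous windows).
#' @param regions optional explicit list of [RegionSpec-class] candidates
#'   (overrides the enumeration).
#' @param maxRank largest PLS rank tried (default 10).
#' @param scheme a [cvScheme()]; default seeded 10-fold.
#' @param method `"pls"` or `"mpls"`.
#' @param sgWindow,sgPolyorder Savitzky--Golay parameters for derivative
#'   codes.
#' @return a [CalibrationResult-class].
#' @export
optimizeModel <- function(x, y, pretreatments = pretreatCodes(),
                          nSubregions = 10L, regions = NULL,
                          maxRank = 10L, scheme = cvScheme(seed = 1L),
                          method = "pls", sgWindow = 17L, sgPolyorder = 2L) {
  stopifnot(is(x, "SpectraSet"), ncol(x) == length(y))
  if (is.null(regions)) {
    regions <- list()
    for (i in seq_len(nSubregions))
      for (j in i:nSubregions)
        regions[[length(regions) + 1L]] <- regionSpec(i, j, nSubregions)
  }
  if (!length(pretreatments) || !length(regions))
    stop("candidate set is empty")
  p <- length(wavenumbers(x))
  best <- NULL
  nFail <- 0L
  for (code in pretreatments) {
    spec <- pretreatmentSpec(code, sgWindow, sgPolyorder)
    pre <- tryCatch(applyPretreatment(x, spec), error = function(e) NULL)
    if (is.null(pre)) { nFail <- nFail + length(regions); next }
    M <- absorbance(pre)
    for (rg in regions) {
      cols <- regionColumns(rg, p)
      cv <- tryCatch(
        crossValidate(M[, cols, drop = FALSE], y, maxRank, scheme, method),
        error = function(e) NULL)
      if (is.null(cv)) { nFail <- nFail + 1L; next }
      sel <- selectRank(cv$curve$RMSECV)
      cand <- list(code = code, region = rg, cv = cv, selRank = sel,
                   minRMSECV = min(cv$curve$RMSECV),
                   width = rg@to - rg@from + 1L)
      if (is.null(best) || .betterCandidate(cand, best)) best <- cand
    }
  }
  if (is.null(best)) stop("all ", nFail, " candidates degenerate")
  spec <- pretreatmentSpec(best$code, sgWindow, sgPolyorder)
  model <- fitPLS(x, y, rank = best$selRank, pretreatment = spec,
                  region = best$region, method = method)
  .calibrationResult(model, x, y, best$cv, best$selRank)
}

.betterCandidate <- function(a, b) {
  if (a$minRMSECV != b$minRMSECV) return(a$minRMSECV < b$minRMSECV)
  if (a$selRank != b$selRank) return(a$selRank < b$selRank)
  if (a$width != b$width) return(a$width > b$width)
  a$code < b$code
}

.calibrationResult <- function(model, x, y, cv, rank) {
  yc <- predict(model, x)
  mc <- regressionMetrics(y, yc)
  row <- cv$curve[rank, ]
  new("CalibrationResult", R2c = mc$R2, RMSEC = mc$RMSE,
      R2cv = row$R2cv, RMSECV = row$RMSECV,
      RPDcv = sdN(y) / row$RMSECV, rank = as.integer(rank), model = model,
      cvCurve = cv$curve, n = length(y))
}

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult (n = %d, rank %d, %s, window [%d..%d]/%d)\n",
    object@n, object@rank, object@model@pretreatment@code,
    object@model@region@from, object@model@region@to,
    object@model@region@nSubregions))
  cat(sprintf("  R2c  = %.3f  RMSEC  = %.4f kN\n", object@R2c, object@RMSEC))
  cat(sprintf("  R2cv = %.3f  RMSECV = %.4f kN  RPDcv = %.2f\n",
              object@R2cv, object@RMSECV, object@RPDcv))
})

#' Calibrate a PLS model with a fixed pretreatment and region
#'
#' Cross-validates over ranks with the given recipe, picks the parsimony
#' rank, and refits on the whole set — [optimizeModel()] without the
#' candidate search.
#'
#' @inheritParams optimizeModel
#' @param pretreatment a [PretreatmentSpec-class] or code string.
#' @param region a [RegionSpec-class] (default: full grid).
#' @return a [CalibrationResult-class].
#' @export
calibrate <- function(x, y, pretreatment = "NONE", region = NULL,
                      maxRank = 10L, scheme = cvScheme(seed = 1L),
                      method = "pls") {
  if (is.character(pretreatment)) pretreatment <- pretreatmentSpec(pretreatment)
  if (is.null(region)) region <- regionSpec(1L, 1L, 1L)
  pre <- applyPretreatment(x, pretreatment)
  cols <- regionColumns(region, length(wavenumbers(x)))
  cv <- crossValidate(absorbance(pre)[, cols, drop = FALSE], y, maxRank,
                      scheme, method)
  sel <- selectRank(cv$curve$RMSECV)
  model <- fitPLS(x, y, rank = sel, pretreatment = pretreatment,
                  region = region, method = method)
  .calibrationResult(model, x, y, cv, sel)
}

#' Externally validate a calibrated model
#'
#' Predicts a held-out validation set and reports R2ev, RMSEP, RPDev
#' (`SD(y)/RMSEP`, n-denominator) and bias.
#'
#' @param result a [CalibrationResult-class] (or a [PLSModel-class]).
#' @param x validation spectra, a [SpectraSet-class].
#' @param y observed crushing strength, kN.
#' @return a [ValidationResult-class].
#' @export
validateModel <- function(result, x, y) {
  model <- if (is(result, "CalibrationResult")) result@model else result
  m <- regressionMetrics(y, predict(model, x))
  new("ValidationResult", R2ev = m$R2, RMSEP = m$RMSE, RPDev = m$RPD,
      bias = m$bias, n = m$n)
}

setMethod("show", "ValidationResult", function(object) {
  cat(sprintf(
    "ValidationResult (n = %d): R2ev = %.3f  RMSEP = %.4f kN  RPDev = %.2f  bias = %+.4f kN\n",
    object@n, object@R2ev, object@RMSEP, object@RPDev, object@bias))
})

#' Integrative recalibration on the pooled calibration + validation sets
#'
#' After external validation, the calibration and validation sets are
#' pooled and the calibration is rerun on all samples, either refitting
#' the already-selected pretreatment/region recipe (default) or repeating
#' the full optimisation search. Sample ids must be disjoint.
#'
#' @param result the [CalibrationResult-class] from the initial calibration.
#' @param xCal,yCal calibration spectra and response.
#' @param xVal,yVal external-validation spectra and response.
#' @param scheme a [cvScheme()].
#' @param research if `TRUE`, rerun [optimizeModel()] on the pooled set
#'   instead of refitting the selected recipe.
#' @param ... passed to [optimizeModel()] when `research = TRUE`.
#' @return a [CalibrationResult-class] for the pooled set.
#' @export
integrativeRecalibrate <- function(result, xCal, yCal, xVal, yVal,
                                   scheme = cvScheme(seed = 1L),
                                   research = FALSE, ...) {
  idsC <- sampleIds(xCal); idsV <- sampleIds(xVal)
  if (length(intersect(idsC, idsV)))
    stop("calibration and validation sets overlap: ",
         paste(head(intersect(idsC, idsV), 5), collapse = ", "))
  shared <- intersect(colnames(sampleData(xCal)), colnames(sampleData(xVal)))
  md <- rbind(as.data.frame(sampleData(xCal))[, shared, drop = FALSE],
              as.data.frame(sampleData(xVal))[, shared, drop = FALSE])
  pooled <- SpectraSet(rbind(absorbance(xCal), absorbance(xVal)),
                       wavenumbers(xCal), sampleData = md,
                       ids = c(idsC, idsV))
  yPool <- c(yCal, yVal)
  if (research)
    return(optimizeModel(pooled, yPool, scheme = scheme, ...))
  model <- result@model
  calibrate(pooled, yPool, pretreatment = model@pretreatment,
            region = model@region, maxRank = max(10L, result@rank),
            scheme = scheme, method = model@method)
}
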
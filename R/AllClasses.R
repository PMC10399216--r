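#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats sd var rnorm runif quantile cor cor.test pt pf aov anova
#'   predict coef lm
#' @importFrom utils read.csv write.csv head tail packageVersion
NULL

#' SpectraSet: near-infrared spectra with sample metadata
#'
#' A container for a set of NIR spectra sharing one uniform wavenumber grid,
#' built on [SummarizedExperiment::SummarizedExperiment]. Rows are
#' wavenumbers (grid stored in `rowData(x)$wavenumber`), columns are samples;
#' the single assay `"absorbance"` holds log10(1/R) absorbance values.
#' Sample metadata (genotype, plot, year, ...) lives in `colData`.
#'
#' Use the constructor [SpectraSet()] rather than `new()`; it accepts the
#' chemometrics orientation (samples x wavenumbers) and transposes.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @seealso [absorbance()], [wavenumbers()], [readSpectra()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

.validSpectraSet <- function(object) {
  msg <- character()
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'absorbance' is required")
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn)) {
    msg <- c(msg, "rowData must contain a 'wavenumber' column")
  } else if (length(wn) >= 2) {
    d <- diff(wn)
    if (any(d <= 0)) msg <- c(msg, "wavenumber grid must be strictly ascending")
    if (diff(range(d)) > 1e-9 * max(abs(wn)))
      msg <- c(msg, "wavenumber grid must be uniform")
  }
  ids <- colnames(object)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  a <- SummarizedExperiment::assay(object, "absorbance")
  if (length(a) && !all(is.finite(a)))
    msg <- c(msg, "absorbance values must be finite")
  if (length(msg)) msg else TRUE
}
setValidity("SpectraSet", .validSpectraSet)

#' ForceCurve: a sampled compression force trace
#'
#' A single force--displacement trace from a stalk compression assay.
#' The load cell samples force every 100 ms; the run stops when force
#' reaches the instrument threshold (4 kN by default).
#'
#' @slot time numeric, sampling times in ms (uniform step).
#' @slot force numeric, non-negative forces in kN.
#' @slot sampleId,genotype character scalars (may be `NA`).
#' @slot replicate integer replicate index.
#' @slot threshold numeric, instrument stop threshold in kN.
#' @export
setClass("ForceCurve", representation(
  time = "numeric", force = "numeric",
  sampleId = "character", genotype = "character",
  replicate = "integer", threshold = "numeric"))

.validForceCurve <- function(object) {
  msg <- character()
  n <- length(object@time)
  if (n != length(object@force)) msg <- c(msg, "time and force lengths differ")
  if (n < 2) msg <- c(msg, "a force curve needs at least 2 samples")
  if (n >= 2) {
    d <- diff(object@time)
    if (any(d <= 0)) msg <- c(msg, "time must be strictly increasing")
    else {
      step <- stats::median(d)
      if (any(abs(d - step) > 0.01 * step))
        msg <- c(msg, "sampling step varies by more than 1%")
    }
  }
  if (!all(is.finite(object@force)) || any(object@force < 0))
    msg <- c(msg, "force must be finite and non-negative")
  if (length(msg)) msg else TRUE
}
setValidity("ForceCurve", .validForceCurve)

#' PeakSet: detected peaks of a force curve
#'
#' @slot peakIndices integer positions into the trace, strictly increasing.
#' @slot peakForces numeric peak forces in kN (from the raw trace).
#' @slot prominences numeric peak prominences in kN.
#' @slot firstPeak numeric, the crushing-strength statistic (`NA` if no peak).
#' @slot states character compressive-state label per peak
#'   (elasticity / yield / compaction_strengthening).
#' @slot sampleId character.
#' @export
setClass("PeakSet", representation(
  peakIndices = "integer", peakForces = "numeric", prominences = "numeric",
  firstPeak = "numeric", states = "character", sampleId = "character"))

.validPeakSet <- function(object) {
  msg <- character()
  if (is.unsorted(object@peakIndices, strictly = TRUE) &&
      length(object@peakIndices) > 1)
    msg <- c(msg, "peakIndices must be strictly increasing")
  if (length(object@peakForces) != length(object@peakIndices))
    msg <- c(msg, "peakForces and peakIndices lengths differ")
  if (length(object@peakForces) &&
      !isTRUE(all.equal(object@firstPeak, object@peakForces[1])))
    msg <- c(msg, "firstPeak must equal the first element of peakForces")
  if (length(msg)) msg else TRUE
}
setValidity("PeakSet", .validPeakSet)

.PRETREAT_CODES <- c("NONE", "COE", "SSL", "SNV", "MMN", "MSC",
                     "FD", "SED", "FD_SSL", "FD_SNV", "FD_MSC")

#' PretreatmentSpec: a spectral pretreatment recipe
#'
#' Identifies one of the eleven pretreatments used in model optimisation
#' (no-op, constant offset elimination, straight-line subtraction, standard
#' normal variate, min--max normalisation, multiplicative scatter correction,
#' first/second Savitzky--Golay derivative, and the three
#' derivative-then-scatter combinations), plus the Savitzky--Golay filter
#' parameters.
#'
#' @slot code one of `pretreatCodes()`.
#' @slot sgWindow odd filter window length (points), default 17.
#' @slot sgPolyorder polynomial order of the filter, default 2.
#' @slot derivativeFirst logical; in combination codes apply the derivative
#'   before the scatter/baseline step (the default, matching the
#'   "first derivative + X" naming); `FALSE` reverses the order for
#'   sensitivity analysis.
#' @export
setClass("PretreatmentSpec", representation(
  code = "character", sgWindow = "integer", sgPolyorder = "integer",
  derivativeFirst = "logical"))

.validPretreatmentSpec <- function(object) {
  msg <- character()
  if (length(object@code) != 1L || !object@code %in% .PRETREAT_CODES)
    msg <- c(msg, paste("code must be one of:",
                        paste(.PRETREAT_CODES, collapse = ", ")))
  if (object@sgWindow %% 2L != 1L || object@sgWindow <= object@sgPolyorder)
    msg <- c(msg, "sgWindow must be odd and greater than sgPolyorder")
  if (object@sgPolyorder < 2L && object@code %in%
      c("SED"))
    msg <- c(msg, "second derivative needs sgPolyorder >= 2")
  if (length(msg)) msg else TRUE
}
setValidity("PretreatmentSpec", .validPretreatmentSpec)

#' RegionSpec: a contiguous wavelength-region window
#'
#' The grid is partitioned into `nSubregions` equal blocks; a region is a
#' contiguous run of blocks `from..to`. The default search enumerates all
#' 55 windows of a 10-block partition.
#'
#' @slot nSubregions integer partition size (default 10).
#' @slot from,to integer block indices, `1 <= from <= to <= nSubregions`.
#' @export
setClass("RegionSpec", representation(
  nSubregions = "integer", from = "integer", to = "integer"))

setValidity("RegionSpec", function(object) {
  ok <- length(object@from) == 1L && length(object@to) == 1L &&
    object@from >= 1L && object@from <= object@to &&
    object@to <= object@nSubregions
  if (ok) TRUE else "need 1 <= from <= to <= nSubregions"
})

#' PLSModel: a calibrated PLS-1 regression model
#'
#' Centered NIPALS PLS-1 state together with everything needed to apply it
#' to new spectra: the pretreatment recipe (with frozen calibration
#' statistics such as the MSC reference), the wavelength region, and the
#' training grid.
#'
#' @slot rank number of latent variables.
#' @slot xMean,yMean centering statistics (per retained column / scalar kN).
#' @slot weights,loadings matrices W and P (columns = factors; W unit-norm).
#' @slot yLoadings numeric q, one per factor.
#' @slot coefficients regression vector b over retained columns;
#'   predictions are `yMean + (x - xMean) %*% b`.
#' @slot pretreatment a [PretreatmentSpec-class].
#' @slot region a [RegionSpec-class].
#' @slot mscReference frozen calibration reference spectrum for MSC codes
#'   (empty otherwise; stored on the derivative scale for `FD_MSC`).
#' @slot grid full training wavenumber grid (before region restriction).
#' @slot method `"pls"` (NIPALS) or `"mpls"` (residual-standardising variant).
#' @slot resSd per-factor residual column scalings (mpls only).
#' @export
setClass("PLSModel", representation(
  rank = "integer", xMean = "numeric", yMean = "numeric",
  weights = "matrix", loadings = "matrix", yLoadings = "numeric",
  coefficients = "numeric", pretreatment = "PretreatmentSpec",
  region = "RegionSpec", mscReference = "numeric", grid = "numeric",
  method = "character", resSd = "matrix"))

setValidity("PLSModel", function(object) {
  msg <- character()
  if (object@rank < 1L) msg <- c(msg, "rank must be >= 1")
  if (ncol(object@weights) != object@rank)
    msg <- c(msg, "weights must have rank columns")
  wn <- sqrt(colSums(object@weights^2))
  if (any(abs(wn - 1) > 1e-6))
    msg <- c(msg, "weight columns must be unit-norm")
  if (length(object@coefficients) != length(object@xMean))
    msg <- c(msg, "coefficients and xMean lengths differ")
  if (length(msg)) msg else TRUE
})

#' PCAModel: a centered principal-component model of spectra
#'
#' @slot center per-column mean of the fitting matrix.
#' @slot rotation loading vectors (columns, orthonormal), sign convention:
#'   the largest-magnitude element of each loading is positive.
#' @slot scoreVar per-component score variance (n-1 denominator),
#'   non-increasing.
#' @slot explained,cumExplained per-component and cumulative fractions of
#'   the total (full-rank) variance.
#' @slot n fitting-set size.
#' @slot grid wavenumber grid the model was fit on.
#' @export
setClass("PCAModel", representation(
  center = "numeric", rotation = "matrix", scoreVar = "numeric",
  explained = "numeric", cumExplained = "numeric", n = "integer",
  grid = "numeric"))

setValidity("PCAModel", function(object) {
  msg <- character()
  if (any(diff(object@scoreVar) > 1e-8 * max(object@scoreVar)))
    msg <- c(msg, "score variances must be non-increasing")
  if (any(object@cumExplained < -1e-12 | object@cumExplained > 1 + 1e-12))
    msg <- c(msg, "cumulative explained fractions must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' GHReport: GH (global Mahalanobis) leverage of samples in PC score space
#'
#' GH is the Mahalanobis distance of a sample in principal-component score
#' space divided by the number of components, so a typical fitting-set
#' sample scores about 1; samples with GH above the threshold (3.0 by
#' convention) are flagged as spectral outliers.
#'
#' @slot sampleId character ids.
#' @slot gh numeric GH values (>= 0).
#' @slot flagged logical, `gh > threshold`.
#' @slot threshold numeric (default 3.0).
#' @export
setClass("GHReport", representation(
  sampleId = "character", gh = "numeric", flagged = "logical",
  threshold = "numeric"))

setValidity("GHReport", function(object) {
  if (any(object@gh < 0)) "GH values must be non-negative" else TRUE
})

#' CalibrationResult: calibration and cross-validation summary of a model
#'
#' @slot R2c,RMSEC calibration-set fit statistics (RMSEC in kN).
#' @slot R2cv,RMSECV pooled out-of-fold cross-validation statistics.
#' @slot RPDcv `sd(y)/RMSECV` with n-denominator SD.
#' @slot rank chosen number of latent variables.
#' @slot model the fitted [PLSModel-class].
#' @slot cvCurve data.frame of RMSECV/R2cv per candidate rank.
#' @slot n calibration-set size.
#' @export
setClass("CalibrationResult", representation(
  R2c = "numeric", RMSEC = "numeric", R2cv = "numeric", RMSECV = "numeric",
  RPDcv = "numeric", rank = "integer", model = "PLSModel",
  cvCurve = "data.frame", n = "integer"))

#' ValidationResult: external-validation summary of a model
#'
#' @slot R2ev,RMSEP,RPDev external-validation statistics (RMSEP in kN).
#' @slot bias mean of predicted minus observed, kN.
#' @slot n validation-set size.
#' @export
setClass("ValidationResult", representation(
  R2ev = "numeric", RMSEP = "numeric", RPDev = "numeric", bias = "numeric",
  n = "integer"))

#' GeneratorConfig: parameters of the synthetic germplasm-panel generator
#'
#' Defines the study conditions the generator emulates: panel layout
#' (genotypes x plots x years with replicated trait measurements), the
#' wavenumber grid, the latent-constituent model behind the spectra, the
#' trait distribution (kN), and the artifact/noise magnitudes.
#'
#' @slot nGenotypes,nPlots,nYears,nReplicates panel layout counts.
#' @slot wnStart,wnEnd,wnStep wavenumber grid, cm-1.
#' @slot nComponents latent constituents behind the spectra.
#' @slot traitMean,traitSd,traitMin,traitMax genotype-level crushing-strength
#'   distribution, kN (normal, clamped to \[traitMin, traitMax\]).
#' @slot noiseSd i.i.d. spectral noise SD, absorbance units.
#' @slot scatterMultSd,scatterOffsetSd,scatterSlopeSd multiplicative /
#'   additive-offset / linear-baseline scatter artifact SDs.
#' @slot plotEffectSd genotype-by-environment effect SD, kN.
#' @slot repNoiseSd replicate measurement noise SD, kN.
#' @slot seed integer RNG seed.
#' @export
setClass("GeneratorConfig", representation(
  nGenotypes = "integer", nPlots = "integer", nYears = "integer",
  nReplicates = "integer", wnStart = "numeric", wnEnd = "numeric",
  wnStep = "numeric", nComponents = "integer", traitMean = "numeric",
  traitSd = "numeric", traitMin = "numeric", traitMax = "numeric",
  noiseSd = "numeric", scatterMultSd = "numeric", scatterOffsetSd = "numeric",
  scatterSlopeSd = "numeric", plotEffectSd = "numeric", repNoiseSd = "numeric",
  seed = "integer"))

.validGeneratorConfig <- function(object) {
  msg <- character()
  if (object@wnEnd <= object@wnStart) msg <- c(msg, "wnEnd must exceed wnStart")
  if (object@wnStep <= 0) msg <- c(msg, "wnStep must be positive")
  npts <- (object@wnEnd - object@wnStart) / object@wnStep
  if (abs(npts - round(npts)) > 1e-9)
    msg <- c(msg, "grid must land exactly on wnEnd")
  if (!(object@traitMin < object@traitMean && object@traitMean < object@traitMax))
    msg <- c(msg, "need traitMin < traitMean < traitMax")
  sds <- c(object@traitSd, object@noiseSd, object@scatterMultSd,
           object@scatterOffsetSd, object@scatterSlopeSd, object@plotEffectSd,
           object@repNoiseSd)
  if (any(sds < 0)) msg <- c(msg, "all sd parameters must be >= 0")
  if (object@nComponents < 1L) msg <- c(msg, "nComponents must be >= 1")
  if (length(msg)) msg else TRUE
}
setValidity("GeneratorConfig", .validGeneratorConfig)

#' SyntheticPanel: a generated germplasm panel with ground truth
#'
#' Output of [simulatePanel()]: one spectrum per genotype x plot x year,
#' a replicated trait table, and the generating ground truth
#' (pure-component spectra, per-sample concentrations, and the linear
#' trait coefficients) enabling parameter-recovery tests.
#'
#' @slot spectra a [SpectraSet-class], samples = genotype x plot x year.
#' @slot traits data.frame: sample_id, genotype, plot, year, replicate,
#'   crushing_strength_kN.
#' @slot concentrations sample x component matrix.
#' @slot pureComponents component x wavenumber matrix.
#' @slot beta,beta0 true linear map: trait = beta0 + concentrations %*% beta.
#' @slot trueTrait per-sample noise-free trait, kN.
#' @slot clampedFraction fraction of genotype traits hit by the range clamp.
#' @slot config the [GeneratorConfig-class] used.
#' @export
setClass("SyntheticPanel", representation(
  spectra = "SpectraSet", traits = "data.frame", concentrations = "matrix",
  pureComponents = "matrix", beta = "numeric", beta0 = "numeric",
  trueTrait = "numeric", clampedFraction = "numeric",
  config = "GeneratorConfig"))

setValidity("SyntheticPanel", function(object) {
  msg <- character()
  cfg <- object@config
  nExp <- cfg@nGenotypes * cfg@nPlots * cfg@nYears
  if (ncol(object@spectra) != nExp)
    msg <- c(msg, "spectra sample count must be genotypes x plots x years")
  if (nrow(object@concentrations) != ncol(object@spectra))
    msg <- c(msg, "concentrations rows must match spectra samples")
  if (length(msg)) msg else TRUE
})

#' SplitPlan: a calibration / external-validation partition
#'
#' @slot calibration,validation disjoint character id vectors whose union is
#'   the full sample set.
#' @slot ratio numeric target calibration:validation ratio.
#' @slot seed integer.
#' @slot rangeCheck logical; `TRUE` when the calibration trait range covers
#'   the validation range.
#' @export
setClass("SplitPlan", representation(
  calibration = "character", validation = "character", ratio = "numeric",
  seed = "integer", rangeCheck = "logical"))

setValidity("SplitPlan", function(object) {
  if (length(intersect(object@calibration, object@validation)))
    "calibration and validation ids must be disjoint" else TRUE
})

#' ScreeningResult: model-based multi-year germplasm screening
#'
#' @slot predictions data.frame: genotype, year, predicted_kN.
#' @slot correlations cross-year Pearson correlation matrix of predictions.
#' @slot high,low genotype lists consistently extreme (every year) at the
#'   screening quantile.
#' @slot q screening quantile.
#' @export
setClass("ScreeningResult", representation(
  predictions = "data.frame", correlations = "matrix",
  high = "character", low = "character", q = "numeric"))

setValidity("ScreeningResult", function(object) {
  if (length(intersect(object@high, object@low)))
    "high and low groups must be disjoint" else TRUE
})
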
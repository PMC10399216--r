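#' Serialize / restore a PLS model as JSON
#'
#' Full-precision JSON with the training grid stored explicitly, so a
#' saved model applies bit-reproducibly on any machine.
#'
#' @param model a [PLSModel-class].
#' @param path output / input file path.
#' @return `readModel` returns a [PLSModel-class]; `writeModel` returns
#'   `path` invisibly.
#' @export
writeModel <- function(model, path) {
  obj <- list(
    rank = model@rank, xMean = model@xMean, yMean = model@yMean,
    weights = model@weights, loadings = model@loadings,
    yLoadings = model@yLoadings, coefficients = model@coefficients,
    pretreatment = list(code = model@pretreatment@code,
                        sgWindow = model@pretreatment@sgWindow,
                        sgPolyorder = model@pretreatment@sgPolyorder,
                        derivativeFirst = model@pretreatment@derivativeFirst),
    region = list(nSubregions = model@region@nSubregions,
                  from = model@region@from, to = model@region@to),
    mscReference = model@mscReference, grid = model@grid,
    method = model@method, resSd = model@resSd)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PLSModel", rank = as.integer(o$rank), xMean = as.numeric(o$xMean),
      yMean = as.numeric(o$yMean),
      weights = matrix(as.numeric(o$weights), ncol = o$rank),
      loadings = matrix(as.numeric(o$loadings), ncol = o$rank),
      yLoadings = as.numeric(o$yLoadings),
      coefficients = as.numeric(o$coefficients),
      pretreatment = pretreatmentSpec(o$pretreatment$code,
                                      o$pretreatment$sgWindow,
                                      o$pretreatment$sgPolyorder,
                                      o$pretreatment$derivativeFirst),
      region = regionSpec(o$region$from, o$region$to, o$region$nSubregions),
      mscReference = as.numeric(o$mscReference %||% numeric()),
      grid = as.numeric(o$grid), method = o$method,
      resSd = if (length(o$resSd)) matrix(as.numeric(o$resSd), ncol = o$rank)
              else matrix(1, 0, o$rank))
}

.CONFIG_KEYS <- c("seed", "nGenotypes", "nPlots", "nYears", "counts",
                  "ratio", "maxRank", "nSubregions", "pretreatments",
                  "decimate", "ghThreshold", "screenQuantile", "cvFolds",
                  "method", "forceCurves")

#' Validate a pipeline run configuration
#'
#' Schema check performed before any computation: unknown keys are
#' rejected, types and ranges verified. Returns the config completed with
#' defaults.
#'
#' @param config named list (e.g. from `yaml::read_yaml`).
#' @return completed config list.
#' @export
validateRunConfig <- function(config) {
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(seed = 42L, nGenotypes = 335L, nPlots = 3L, nYears = 3L,
                   counts = NULL, ratio = 4, maxRank = 10L,
                   nSubregions = 10L, pretreatments = pretreatCodes(),
                   decimate = 1L, ghThreshold = 3.0, screenQuantile = 0.1,
                   cvFolds = 10L, method = "pls", forceCurves = FALSE)
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$ratio > 1, cfg$maxRank >= 1, cfg$nSubregions >= 1,
            cfg$ghThreshold > 0, cfg$screenQuantile > 0,
            cfg$screenQuantile < 0.5,
            all(cfg$pretreatments %in% pretreatCodes()),
            cfg$method %in% c("pls", "mpls"))
  cfg
}

#' Run the end-to-end phenotyping pipeline on synthetic data
#'
#' Executes the whole workflow: simulate a germplasm panel; extract the
#' modeling set; split calibration/validation with range coverage; run the
#' pretreatment-by-region optimisation; validate externally; integratively
#' recalibrate on the pooled set; apply the final model across years with
#' GH outlier flagging; screen consistently high/low germplasm. Artifacts
#' (model JSON, metric report, screening table, run manifest with the seed
#' and package version) are written under `outDir`.
#'
#' @param config named list, see [validateRunConfig()]; a YAML file path is
#'   also accepted.
#' @param outDir output directory (created).
#' @return invisibly, a list with the calibration, validation, pooled
#'   recalibration, screening results and the output paths.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("canecrush_run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validateRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  gen <- generatorConfig(nGenotypes = cfg$nGenotypes, nPlots = cfg$nPlots,
                         nYears = cfg$nYears, seed = seed)
  panel <- simulatePanel(gen)
  writePanel(panel, file.path(outDir, "simulated"),
             forceCurves = isTRUE(cfg$forceCurves))
  ms <- modelingSet(panel)
  spectra <- ms$spectra
  if (cfg$decimate > 1L) spectra <- decimateSpectra(spectra, cfg$decimate)

  ids <- sampleIds(spectra)
  plan <- splitCalibrationValidation(ids, ratio = cfg$ratio,
                                     seed = subSeed(seed, 11L), y = ms$y,
                                     counts = cfg$counts)
  xCal <- spectra[, plan@calibration]; yCal <- ms$y[plan@calibration]
  xVal <- spectra[, plan@validation]; yVal <- ms$y[plan@validation]

  scheme <- cvScheme("kfold", k = cfg$cvFolds, seed = subSeed(seed, 12L))
  calib <- optimizeModel(xCal, yCal, pretreatments = cfg$pretreatments,
                         nSubregions = cfg$nSubregions,
                         maxRank = cfg$maxRank, scheme = scheme,
                         method = cfg$method)
  valid <- validateModel(calib, xVal, yVal)
  pooled <- integrativeRecalibrate(calib, xCal, yCal, xVal, yVal,
                                   scheme = scheme)

  # apply the pooled model across years with GH flagging, then screen
  pca <- fitPCA(xCal, k = min(10L, ncol(xCal) - 1L))
  preds <- NULL
  for (yr in seq_len(cfg$nYears)) {
    msy <- modelingSet(panel, year = yr)
    sp <- msy$spectra
    if (cfg$decimate > 1L) sp <- decimateSpectra(sp, cfg$decimate)
    gh <- ghValues(pca, sp, threshold = cfg$ghThreshold)
    keep <- !gh@flagged
    if (!any(keep)) stop("all samples flagged as outliers in year ", yr)
    yhat <- predict(pooled@model, sp[, keep])
    preds <- rbind(preds, data.frame(
      genotype = as.character(sampleData(sp)$genotype[keep]),
      year = as.character(sampleData(sp)$year[keep]),
      predicted_kN = unname(yhat)))
  }
  screening <- screenExtremes(preds, q = cfg$screenQuantile)

  modelPath <- file.path(outDir, "model.json")
  writeModel(pooled@model, modelPath)
  report <- list(
    calibration = list(n = calib@n, rank = calib@rank,
                       pretreatment = calib@model@pretreatment@code,
                       region = c(calib@model@region@from,
                                  calib@model@region@to),
                       R2c = calib@R2c, RMSEC = calib@RMSEC,
                       R2cv = calib@R2cv, RMSECV = calib@RMSECV,
                       RPDcv = calib@RPDcv),
    validation = list(n = valid@n, R2ev = valid@R2ev, RMSEP = valid@RMSEP,
                      RPDev = valid@RPDev, bias = valid@bias),
    pooled = list(n = pooled@n, rank = pooled@rank, R2c = pooled@R2c,
                  RMSEC = pooled@RMSEC, R2cv = pooled@R2cv,
                  RMSECV = pooled@RMSECV, RPDcv = pooled@RPDcv))
  jsonlite::write_json(report, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(preds, file.path(outDir, "screening.csv"), row.names = FALSE)
  manifest <- list(seed = seed, config = cfg[order(names(cfg))],
                   package_version = as.character(packageVersion("canecrush")),
                   outputs = c("simulated/", "model.json", "metrics.json",
                               "screening.csv"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(panel = panel, plan = plan, calibration = calib,
                 validation = valid, pooled = pooled,
                 screening = screening, dir = outDir))
}
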
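#' Configure the synthetic germplasm-panel generator
#'
#' Builds a [GeneratorConfig-class] with defaults emulating the study
#' conditions of a large online-NIRS sugarcane panel: 335 genotypes over
#' 3 plots and 3 years with 3 replicate strength measurements, spectra on
#' the 4000--10000 cm-1 / 4 cm-1 grid driven by 3 latent constituents, and
#' genotype crushing strength normal with mean 1.30 kN and SD 0.28 kN,
#' clamped to [0.69, 2.13] kN.
#'
#' @param nGenotypes,nPlots,nYears,nReplicates panel layout.
#' @param wnStart,wnEnd,wnStep wavenumber grid, cm-1.
#' @param nComponents latent constituents.
#' @param traitMean,traitSd,traitMin,traitMax genotype trait distribution, kN.
#' @param noiseSd i.i.d. spectral noise SD (absorbance).
#' @param scatterMultSd,scatterOffsetSd,scatterSlopeSd scatter artifact SDs
#'   (multiplicative factor; additive offset, absorbance; linear baseline
#'   slope over the grid, absorbance).
#' @param plotEffectSd genotype-by-plot/year effect SD, kN.
#' @param repNoiseSd replicate measurement noise SD, kN.
#' @param seed integer seed; every draw the generator makes flows from it.
#' @return a validated [GeneratorConfig-class].
#' @export
generatorConfig <- function(nGenotypes = 335L, nPlots = 3L, nYears = 3L,
                            nReplicates = 3L,
                            wnStart = 4000, wnEnd = 10000, wnStep = 4,
                            nComponents = 3L,
                            traitMean = 1.30, traitSd = 0.28,
                            traitMin = 0.69, traitMax = 2.13,
                            noiseSd = 0.002,
                            scatterMultSd = 0.03, scatterOffsetSd = 0.02,
                            scatterSlopeSd = 0.01,
                            plotEffectSd = 0.08, repNoiseSd = 0.10,
                            seed = 42L) {
  new("GeneratorConfig",
      nGenotypes = as.integer(nGenotypes), nPlots = as.integer(nPlots),
      nYears = as.integer(nYears), nReplicates = as.integer(nReplicates),
      wnStart = wnStart, wnEnd = wnEnd, wnStep = wnStep,
      nComponents = as.integer(nComponents),
      traitMean = traitMean, traitSd = traitSd,
      traitMin = traitMin, traitMax = traitMax,
      noiseSd = noiseSd, scatterMultSd = scatterMultSd,
      scatterOffsetSd = scatterOffsetSd, scatterSlopeSd = scatterSlopeSd,
      plotEffectSd = plotEffectSd, repNoiseSd = repNoiseSd,
      seed = as.integer(seed))
}

configGrid <- function(config)
  seq(config@wnStart, config@wnEnd, by = config@wnStep)

# Fixed true trait-concentration coefficients. Concentration 1 carries the
# trait signal; 2 and 3 (and any further) are independent nuisance
# constituents that also enter the trait linearly.
.trueBeta <- function(k) {
  base <- c(1.0, 0.35, -0.25)
  if (k <= 3) base[seq_len(k)] else c(base, rep(0.1, k - 3))
}
.concMean <- 2.0
.concSd <- 0.8

#' Generate pure-component spectra
#'
#' Each latent constituent gets a smooth, positive NIR-like spectrum: a sum
#' of 3--8 Gaussian bands with centers uniform on the grid and widths of
#' 50--400 cm-1. Components are checked for linear independence.
#'
#' @param config a [GeneratorConfig-class].
#' @return numeric matrix, component x wavenumber.
#' @export
simulatePureComponents <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  wn <- configGrid(config)
  k <- config@nComponents
  withSeed(subSeed(config@seed, 1L), {
    S <- matrix(0, k, length(wn))
    for (j in seq_len(k)) {
      nb <- sample(3:8, 1L)
      centers <- runif(nb, config@wnStart, config@wnEnd)
      widths <- runif(nb, 50, 400)
      amps <- runif(nb, 0.2, 1.0)
      for (b in seq_len(nb))
        S[j, ] <- S[j, ] + amps[b] * exp(-0.5 * ((wn - centers[b]) / widths[b])^2)
      S[j, ] <- S[j, ] + 0.05 # small positive floor
    }
    if (qr(S)$rank < k)
      stop("degenerate pure components; choose another seed")
    S
  })
}

#' Generate a synthetic germplasm panel
#'
#' Emulates the statistical structure a large online-NIRS germplasm study
#' assumes: a genotype-level crushing strength drawn once per genotype
#' (normal, clamped to the configured range), genotype-by-plot/year effects
#' and replicate measurement noise on top of it, and spectra produced by
#' Beer--Lambert linear mixing of the pure components plus the standard NIR
#' artifact model (additive offset, linear baseline, multiplicative scatter,
#' i.i.d. noise). Per-sample concentrations are solved so the sample's
#' noise-free trait is an exact known linear function of its concentrations,
#' which makes full parameter recovery testable.
#'
#' @param config a [GeneratorConfig-class]; `nGenotypes` must be at least 10.
#' @return a [SyntheticPanel-class]. Same config (same seed) gives a
#'   bit-identical panel.
#' @export
simulatePanel <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  if (config@nGenotypes < 10L)
    stop("nGenotypes must be >= 10 for non-degenerate statistics")
  wn <- configGrid(config)
  k <- config@nComponents
  S <- simulatePureComponents(config)
  beta <- .trueBeta(k)
  beta0 <- config@traitMean - sum(beta * .concMean)

  nG <- config@nGenotypes; nP <- config@nPlots; nY <- config@nYears
  genotypes <- sprintf("G%03d", seq_len(nG))
  withSeed(subSeed(config@seed, 2L), {
    gTrait <- rnorm(nG, config@traitMean, config@traitSd)
    clamped <- gTrait < config@traitMin | gTrait > config@traitMax
    gTrait <- pmin(pmax(gTrait, config@traitMin), config@traitMax)
    # nuisance concentrations fixed per genotype
    cNuis <- if (k > 1)
      matrix(rnorm(nG * (k - 1), .concMean, .concSd), nG, k - 1) else
      matrix(0, nG, 0)

    layout <- expand.grid(genotype = seq_len(nG), plot = seq_len(nP),
                          year = seq_len(nY), KEEP.OUT.ATTRS = FALSE)
    nS <- nrow(layout)
    env <- rnorm(nS, 0, config@plotEffectSd)
    trueTrait <- gTrait[layout$genotype] + env

    conc <- matrix(0, nS, k)
    if (k > 1) conc[, -1] <- cNuis[layout$genotype, , drop = FALSE]
    conc[, 1] <- (trueTrait - beta0 -
                    if (k > 1) conc[, -1, drop = FALSE] %*% beta[-1] else 0) / beta[1]

    A <- conc %*% S
    u <- (wn - mean(wn)) / diff(range(wn)) # centered, unit-range baseline axis
    mult <- rnorm(nS, 0, config@scatterMultSd)
    off <- rnorm(nS, 0, config@scatterOffsetSd)
    slope <- rnorm(nS, 0, config@scatterSlopeSd)
    A <- (1 + mult) * A + outer(off, rep(1, length(wn))) + outer(slope, u)
    if (config@noiseSd > 0)
      A <- A + matrix(rnorm(nS * length(wn), 0, config@noiseSd), nS)

    ids <- sprintf("%s_P%d_Y%d", genotypes[layout$genotype], layout$plot,
                   layout$year)
    md <- data.frame(genotype = genotypes[layout$genotype],
                     plot = sprintf("P%d", layout$plot),
                     year = 2018L + layout$year,
                     stringsAsFactors = FALSE)
    spectra <- SpectraSet(A, wn, sampleData = md, ids = ids)

    reps <- config@nReplicates
    traits <- data.frame(
      sample_id = rep(ids, each = reps),
      genotype = rep(md$genotype, each = reps),
      plot = rep(md$plot, each = reps),
      year = rep(md$year, each = reps),
      replicate = rep(seq_len(reps), times = nS),
      crushing_strength_kN = rep(trueTrait, each = reps) +
        rnorm(nS * reps, 0, config@repNoiseSd),
      stringsAsFactors = FALSE)

    rownames(conc) <- ids
    new("SyntheticPanel", spectra = spectra, traits = traits,
        concentrations = conc, pureComponents = S, beta = beta,
        beta0 = beta0, trueTrait = stats::setNames(trueTrait, ids),
        clampedFraction = mean(clamped), config = config)
  })
}

setMethod("show", "SyntheticPanel", function(object) {
  cfg <- object@config
  cat(sprintf("SyntheticPanel: %d genotypes x %d plots x %d years (%d spectra)\n",
              cfg@nGenotypes, cfg@nPlots, cfg@nYears, ncol(object@spectra)))
  cat(sprintf("  trait: N(%.2f, %.2f) kN clamped to [%.2f, %.2f] (%.1f%% clamped)\n",
              cfg@traitMean, cfg@traitSd, cfg@traitMin, cfg@traitMax,
              100 * object@clampedFraction))
})

#' Extract a modeling set from a panel
#'
#' The modeling experiment uses one spectrum per genotype: each genotype is
#' assigned a home plot (cycled across plots so all plots contribute) and
#' its spectrum from the requested year is paired with the mean of its
#' replicate strength measurements in that plot/year — the measured trait a
#' calibration would regress on.
#'
#' @param panel a [SyntheticPanel-class].
#' @param year which year to use (index into the panel's years, default 1).
#' @return list with `spectra` (a [SpectraSet-class], one sample per
#'   genotype) and `y` (named numeric, measured crushing strength, kN).
#' @export
modelingSet <- function(panel, year = 1L) {
  cfg <- panel@config
  stopifnot(year >= 1L, year <= cfg@nYears)
  g <- seq_len(cfg@nGenotypes)
  homePlot <- ((g - 1L) %% cfg@nPlots) + 1L
  ids <- sprintf("G%03d_P%d_Y%d", g, homePlot, as.integer(year))
  spectra <- panel@spectra[, ids]
  tr <- panel@traits
  key <- tr$sample_id
  y <- vapply(ids, function(id)
    mean(tr$crushing_strength_kN[key == id]), numeric(1))
  list(spectra = spectra, y = y)
}

#' Generate a synthetic compression force curve
#'
#' Produces a 100 ms-sampled force trace with the canonical shape of a
#' stalk compression assay: a monotone elastic rise to a first peak at the
#' true crushing strength, a crack (sharp drop), several oscillation peaks
#' of varying height (the yield phase), and a final compaction-strengthening
#' rise that stops when the force reaches the instrument threshold.
#' Later peaks get substantially larger height jitter than the first peak,
#' mirroring their larger replicate variation.
#'
#' @param trueStrength first-peak force, kN; must lie in (0, threshold).
#' @param seed integer; same (trueStrength, seed) gives an identical trace.
#' @param jitter relative SD of the first-peak height (0 = exact).
#' @param threshold instrument stop threshold, kN (default 4).
#' @param peaks optional explicit peak heights (first element is the first
#'   peak) overriding the random design.
#' @param sampleId,genotype,replicate metadata passed to the curve.
#' @return a [ForceCurve-class].
#' @export
simulateForceCurve <- function(trueStrength, seed, jitter = 0.02,
                               threshold = 4.0, peaks = NULL,
                               sampleId = NA_character_,
                               genotype = NA_character_, replicate = 1L) {
  if (!is.numeric(trueStrength) || trueStrength <= 0 ||
      trueStrength >= threshold)
    stop("trueStrength must lie in (0, threshold)")
  withSeed(subSeed(seed, 3L), {
    if (is.null(peaks)) {
      first <- trueStrength * (1 + jitter * rnorm(1))
      nFollow <- sample(2:5, 1L)
      follow <- trueStrength * runif(nFollow, 0.7, 1.6) *
        (1 + 4 * jitter * rnorm(nFollow))
      follow <- pmin(follow, 0.95 * threshold)
      peaks <- c(first, follow)
    }
    peaks <- pmin(peaks, 0.999 * threshold)
    nPk <- length(peaks)
    valleys <- numeric(nPk) # valley after each peak
    for (i in seq_len(nPk)) {
      nxt <- if (i < nPk) peaks[i + 1] else peaks[i]
      valleys[i] <- runif(1, 0.35, 0.5) * min(peaks[i], nxt)
    }

    half <- function(a, b, n) { # half-cosine arc from a to b over n steps
      s <- seq_len(n) / n
      a + (b - a) * (1 - cos(pi * s)) / 2
    }
    nRise <- 15L + sample(0:10, 1L)
    f <- peaks[1] * (seq_len(nRise) / nRise)^1.7
    for (i in seq_len(nPk)) {
      f <- c(f, half(peaks[i], valleys[i], 6L + sample(0:4, 1L)))
      if (i < nPk)
        f <- c(f, half(valleys[i], peaks[i + 1], 6L + sample(0:4, 1L)))
    }
    nFinal <- 20L + sample(0:10, 1L)
    f <- c(f, valleys[nPk] +
             (threshold - valleys[nPk]) * (seq_len(nFinal) / nFinal)^1.6)
    f <- c(0, pmin(f, threshold))
    new("ForceCurve", time = 100 * (seq_along(f) - 1), force = f,
        sampleId = sampleId, genotype = genotype,
        replicate = as.integer(replicate), threshold = threshold)
  })
}

#' Write a simulated panel to disk
#'
#' Writes `spectra.csv` (CSV dialect of [writeSpectra()]), `traits.csv`
#' (sample_id, genotype, plot, year, replicate, crushing_strength_kN),
#' `truth.json` (true beta, beta0, seed, clamped fraction), and optionally
#' a `forcecurves/` directory with one `time_ms,force_kN` CSV per modeling
#' sample.
#'
#' @param panel a [SyntheticPanel-class].
#' @param dir output directory (created if needed).
#' @param forceCurves logical; also write per-sample force curves for the
#'   year-1 modeling samples.
#' @return `dir`, invisibly.
#' @export
writePanel <- function(panel, dir, forceCurves = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSpectra(panel@spectra, file.path(dir, "spectra.csv"))
  write.csv(panel@traits, file.path(dir, "traits.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(beta = panel@beta, beta0 = panel@beta0,
         seed = panel@config@seed, clamped_fraction = panel@clampedFraction),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  if (forceCurves) {
    fdir <- file.path(dir, "forcecurves")
    dir.create(fdir, showWarnings = FALSE)
    ms <- modelingSet(panel)
    ids <- sampleIds(ms$spectra)
    for (i in seq_along(ids)) {
      cv <- simulateForceCurve(min(ms$y[i], 0.999 * 4), seed =
                                 subSeed(panel@config@seed, 100L + i),
                               sampleId = ids[i])
      write.csv(data.frame(time_ms = cv@time, force_kN = cv@force),
                file.path(fdir, paste0(ids[i], ".csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}
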
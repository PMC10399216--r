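#' Construct a ForceCurve
#'
#' @param time sampling times, ms (uniform step; 1% jitter tolerated).
#' @param force forces, kN, non-negative.
#' @param sampleId,genotype,replicate optional metadata.
#' @param threshold instrument stop threshold, kN.
#' @return a validated [ForceCurve-class].
#' @export
ForceCurve <- function(time, force, sampleId = NA_character_,
                       genotype = NA_character_, replicate = 1L,
                       threshold = 4.0) {
  new("ForceCurve", time = as.numeric(time), force = as.numeric(force),
      sampleId = as.character(sampleId), genotype = as.character(genotype),
      replicate = as.integer(replicate), threshold = threshold)
}

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf("ForceCurve '%s': %d samples, step %g ms, max %.3f kN\n",
              object@sampleId, length(object@force),
              stats::median(diff(object@time)), max(object@force)))
})

#' Read a force curve from CSV
#'
#' Expects a two-column CSV with header `time_ms,force_kN`. Non-uniform
#' sampling is tolerated within 1% step jitter. Parse errors name the
#' offending row.
#'
#' @param path file path.
#' @param ... metadata passed to [ForceCurve()].
#' @return a [ForceCurve-class].
#' @export
readForceCurve <- function(path, ...) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop("empty force curve file: ", path)
  need <- c("time_ms", "force_kN")
  if (!all(need %in% colnames(df)))
    stop("missing columns in ", path, ": ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  t <- df$time_ms; f <- df$force_kN
  bad <- which(!is.finite(t) | !is.finite(f))
  if (length(bad)) stop("non-numeric value at row ", bad[1], " of ", path)
  if (any(diff(t) <= 0))
    stop("time not increasing at row ", which(diff(t) <= 0)[1] + 1L,
         " of ", path)
  if (any(f < 0)) stop("negative force at row ", which(f < 0)[1], " of ", path)
  if (length(t) > 2) {
    step <- stats::median(diff(t))
    j <- which(abs(diff(t) - step) > 0.01 * step)
    if (length(j)) stop("sampling step jitter beyond 1% at row ", j[1] + 1L,
                        " of ", path)
  }
  ForceCurve(t, f, ...)
}

# Strict local maxima of a numeric vector (plateaus collapse to their first
# index); endpoints never qualify.
.localMaxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3) return(integer())
  i <- 2:(k - 1)
  keep <- r$values[i] > r$values[i - 1] & r$values[i] > r$values[i + 1]
  starts[i][keep]
}

# Classic prominence: height minus the higher of the two key saddles
# (minimum down to the nearest higher ground on each side, or to the end).
.prominence <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    if (i <= 1L || i >= n) return(0)
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    hiL <- which(left > h)
    minL <- if (!length(hiL)) min(left)
            else if (max(hiL) == i - 1L) h   # adjacent higher point: not a peak
            else min(left[(max(hiL) + 1L):(i - 1L)])
    right <- x[(i + 1L):n]
    hiR <- which(right > h)
    minR <- if (!length(hiR)) min(right)
            else if (min(hiR) == 1L) h
            else min(right[seq_len(min(hiR) - 1L)])
    h - max(minL, minR)
  }, numeric(1))
}

#' Detect peaks in a compression force curve
#'
#' Local maxima of the moving-average-smoothed trace whose prominence is at
#' least `minPromFrac` of the curve's maximum force, ordered by time. Peak
#' positions are refined to the raw-trace maximum within half a smoothing
#' window, and peak forces are read from the raw trace, so the reported
#' first peak does not depend on the smoothing window for clean curves.
#' A curve with no qualifying peak yields an empty [PeakSet-class] with
#' `firstPeak = NA` (not an error), so batch runs continue.
#'
#' Detected peaks are labelled with the three compressive states: the first
#' peak ends the elastic phase, subsequent oscillation peaks are the yield
#' phase, and any peak on the final rise belongs to compaction
#' strengthening. The labels are descriptive only.
#'
#' @param curve a [ForceCurve-class].
#' @param minPromFrac required prominence as a fraction of `max(force)`,
#'   in (0, 1); default 0.05.
#' @param smoothWindow odd moving-average window (points), default 5.
#' @return a [PeakSet-class].
#' @export
setMethod("detectPeaks", "ForceCurve",
          function(curve, minPromFrac = 0.05, smoothWindow = 5L) {
  stopifnot(minPromFrac > 0, minPromFrac < 1,
            smoothWindow >= 1, smoothWindow %% 2 == 1)
  f <- curve@force
  sm <- movingAverage(f, smoothWindow)
  cand <- .localMaxima(sm)
  if (!length(cand))
    return(new("PeakSet", peakIndices = integer(), peakForces = numeric(),
               prominences = numeric(), firstPeak = NA_real_,
               states = character(), sampleId = curve@sampleId))
  # refine to the raw-trace maximum near each smoothed peak
  h <- (as.integer(smoothWindow) - 1L) %/% 2L
  idx <- vapply(cand, function(i) {
    w <- max(1L, i - h):min(length(f), i + h)
    w[which.max(f[w])]
  }, integer(1))
  idx <- sort(unique(idx))
  # re-check: refined indices must still be raw local maxima candidates
  prom <- .prominence(f, idx)
  keep <- prom >= minPromFrac * max(f)
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx))
    return(new("PeakSet", peakIndices = integer(), peakForces = numeric(),
               prominences = numeric(), firstPeak = NA_real_,
               states = character(), sampleId = curve@sampleId))
  states <- c("elasticity",
              rep("yield", max(0L, length(idx) - 1L)))
  if (length(idx) > 2L) states[length(idx)] <- "compaction_strengthening"
  new("PeakSet", peakIndices = as.integer(idx), peakForces = f[idx],
      prominences = prom, firstPeak = f[idx[1]], states = states,
      sampleId = curve@sampleId)
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet '%s': %d peaks; first peak %.3f kN\n",
              object@sampleId, length(object@peakIndices), object@firstPeak))
})

#' Crushing strength of a stalk: the first-peak force
#'
#' The crushing-strength statistic is the force at the first detected peak
#' of the compression curve — the end of the elastic phase, when the first
#' crack appears. Replicate variation of the first peak is much smaller
#' than that of later peaks, which is why it (and not the global maximum)
#' is the trait.
#'
#' @param curve a [ForceCurve-class].
#' @param ... passed to [detectPeaks()].
#' @return first-peak force in kN, or `NA` when the curve has no detected
#'   peak (e.g. truncated before any crack).
#' @export
setMethod("crushingStrength", "ForceCurve", function(curve, ...) {
  detectPeaks(curve, ...)@firstPeak
})

#' Replicate statistics of detected peaks
#'
#' Aligns the peaks of replicate curves of one genotype by ordinal index
#' and reports per-index mean and relative standard deviation
#' (RSD% = sample SD / mean x 100). When replicates disagree on the number
#' of peaks, statistics are restricted to the common prefix with a warning.
#'
#' @param curves list of [ForceCurve-class] replicates of one genotype.
#' @param ... passed to [detectPeaks()].
#' @return data.frame: peak (ordinal), mean_kN, rsd_pct, n_replicates.
#' @export
replicateStats <- function(curves, ...) {
  if (length(curves) < 2) stop("need at least 2 replicate curves")
  pk <- lapply(curves, function(cv) detectPeaks(cv, ...)@peakForces)
  counts <- lengths(pk)
  if (any(counts == 0)) stop("a replicate has no detected peak")
  m <- min(counts)
  if (length(unique(counts)) > 1)
    warning("replicates differ in peak count; using common prefix of ", m)
  M <- vapply(pk, function(p) p[seq_len(m)], numeric(m))
  M <- matrix(M, nrow = m) # peaks x replicates
  data.frame(peak = seq_len(m),
             mean_kN = rowMeans(M),
             rsd_pct = apply(M, 1, sd) / rowMeans(M) * 100,
             n_replicates = length(curves))
}

#' Batch-extract crushing strength from a directory of force-curve CSVs
#'
#' @param dir directory of `time_ms,force_kN` CSV files.
#' @param ... passed to [detectPeaks()].
#' @return data.frame: sample_id (file stem), crushing_strength_kN
#'   (`NA` where no peak was found).
#' @export
batchCrushingStrength <- function(dir, ...) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no CSV files in ", dir)
  vals <- vapply(files, function(f) {
    cv <- readForceCurve(f, sampleId = sub("\\.csv$", "", basename(f)))
    crushingStrength(cv, ...)
  }, numeric(1))
  data.frame(sample_id = sub("\\.csv$", "", basename(files)),
             crushing_strength_kN = unname(vals))
}
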
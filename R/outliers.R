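#' Fit a centered PCA of spectra
#'
#' Principal components of the (raw or pretreated) absorbance matrix via
#' singular value decomposition of the centered data. Deterministic sign
#' convention: each loading's largest-magnitude element is positive.
#' Explained fractions are relative to the total (full-rank) variance.
#'
#' @param x a [SpectraSet-class] or numeric matrix (samples x variables).
#' @param k number of components to retain (default 10); must be < n.
#' @return a [PCAModel-class].
#' @export
fitPCA <- function(x, k = 10L) {
  m <- if (is(x, "SpectraSet")) absorbance(x) else as.matrix(x)
  grid <- if (is(x, "SpectraSet")) wavenumbers(x) else as.numeric(seq_len(ncol(m)))
  n <- nrow(m)
  k <- as.integer(k)
  if (k >= n) stop("k must be smaller than the number of samples")
  center <- colMeans(m)
  mc <- sweep(m, 2, center)
  sv <- svd(mc, nu = 0, nv = k)
  rot <- sv$v
  # sign convention
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  d2 <- sv$d^2
  total <- sum(mc^2)
  expl <- d2[seq_len(k)] / total
  new("PCAModel", center = center, rotation = rot,
      scoreVar = d2[seq_len(k)] / (n - 1),
      explained = expl, cumExplained = cumsum(expl),
      n = as.integer(n), grid = grid)
}

setMethod("show", "PCAModel", function(object) {
  k <- length(object@explained)
  cat(sprintf("PCAModel: %d components fit on %d samples\n", k, object@n))
  cat(sprintf("  cumulative explained: %s\n",
              paste(sprintf("%.2f%%", 100 * object@cumExplained[seq_len(min(5, k))]),
                    collapse = " ")))
})

#' GH (global Mahalanobis) leverage of samples in PC score space
#'
#' `GH_i = (1/k) * sum_a t_ia^2 / s_a^2`, with scores `t` from projecting
#' onto the model's loadings and `s_a^2` the score variances of the
#' fitting set. Dividing by `k` makes an average fitting-set sample score
#' about 1 (the fitting-set mean GH is exactly `(n-1)/n`), which gives the
#' conventional outlier threshold of 3.0 its meaning. Prediction-time GH
#' must reuse the frozen calibration PCA, never a refit.
#'
#' @param model a [PCAModel-class].
#' @param x a [SpectraSet-class] or matrix on the model's grid.
#' @param threshold flag samples with GH above this (default 3.0).
#' @return a [GHReport-class].
#' @export
setMethod("ghValues", "PCAModel", function(model, x, threshold = 3.0) {
  m <- if (is(x, "SpectraSet")) absorbance(x) else .asRowMatrix(x)
  if (is(x, "SpectraSet")) {
    wn <- wavenumbers(x)
    if (length(wn) != length(model@grid) ||
        any(abs(wn - model@grid) > 1e-6))
      stop("grid mismatch with the PCA model")
  } else if (ncol(m) != length(model@center))
    stop("matrix input must have ", length(model@center), " columns")
  ids <- if (is(x, "SpectraSet")) sampleIds(x) else
    rownames(m) %||% sprintf("S%04d", seq_len(nrow(m)))
  scores <- sweep(m, 2, model@center) %*% model@rotation
  sv <- model@scoreVar
  ok <- sv > 1e-12 * max(sv)
  if (!all(ok))
    warning("dropping ", sum(!ok), " zero-variance component(s) from GH")
  k <- sum(ok)
  gh <- rowSums(sweep(scores[, ok, drop = FALSE]^2, 2, sv[ok], "/")) / k
  new("GHReport", sampleId = ids, gh = unname(gh),
      flagged = unname(gh > threshold), threshold = threshold)
})

setMethod("show", "GHReport", function(object) {
  cat(sprintf("GHReport: %d samples, %d flagged at GH > %.1f\n",
              length(object@gh), sum(object@flagged), object@threshold))
})

#' @rdname ghValues
#' @param report a `GHReport`.
#' @return `as.data.frame`: sample_id, gh, flagged.
#' @export
ghTable <- function(report)
  data.frame(sample_id = report@sampleId, gh = report@gh,
             flagged = report@flagged)

#' Exclude GH-flagged outlier samples
#'
#' Removes flagged samples from the set; the exclusion list (ids and GH
#' values) is reported via `message`. Refuses to empty the set.
#'
#' @param x a [SpectraSet-class].
#' @param report a [GHReport-class] aligned to `x`.
#' @return the filtered [SpectraSet-class].
#' @export
excludeOutliers <- function(x, report) {
  if (!identical(report@sampleId, sampleIds(x)))
    stop("report is not aligned to the spectra set")
  if (all(report@flagged)) stop("all samples flagged; refusing to return an empty set")
  if (any(report@flagged))
    message("excluding ", sum(report@flagged), " outlier(s): ",
            paste(sprintf("%s (GH %.2f)", report@sampleId[report@flagged],
                          report@gh[report@flagged]), collapse = ", "))
  x[, !report@flagged]
}
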
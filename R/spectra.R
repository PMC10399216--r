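#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix, samples x wavenumbers, log10(1/R)
#'   absorbance. A descending wavenumber grid is accepted and stored
#'   ascending with columns reversed.
#' @param wavenumbers numeric vector, cm-1, one per column of `absorbance`.
#' @param sampleData data.frame (or DataFrame) of per-sample metadata
#'   (genotype, plot, year, ...); row order matches `absorbance` rows.
#' @param ids character sample ids; defaults to `rownames(absorbance)` or
#'   `sampleData$sample_id`.
#' @return a [SpectraSet-class].
#' @examples
#' s <- SpectraSet(matrix(1:6 / 10, 2, 3), c(4000, 4004, 4008),
#'                 data.frame(genotype = c("A", "B")))
#' dim(absorbance(s))
#' @export
SpectraSet <- function(absorbance, wavenumbers,
                       sampleData = NULL, ids = NULL) {
  absorbance <- as.matrix(absorbance)
  if (length(wavenumbers) != ncol(absorbance))
    stop("wavenumbers length must match absorbance columns")
  if (length(wavenumbers) >= 2 && wavenumbers[1] > wavenumbers[2]) {
    o <- order(wavenumbers)
    wavenumbers <- wavenumbers[o]
    absorbance <- absorbance[, o, drop = FALSE]
  }
  if (is.null(ids)) {
    ids <- rownames(absorbance)
    if (is.null(ids) && !is.null(sampleData) && "sample_id" %in% colnames(sampleData))
      ids <- as.character(sampleData$sample_id)
    if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(absorbance)))
  }
  if (anyDuplicated(ids)) stop("duplicate sample ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cd <- if (is.null(sampleData)) S4Vectors::DataFrame(row.names = ids)
        else S4Vectors::DataFrame(sampleData, row.names = ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = t(unname(absorbance))),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = cd)
  colnames(se) <- ids
  new("SpectraSet", se)
}

#' @rdname SpectraSet
#' @export
setMethod("absorbance", "SpectraSet", function(x) {
  m <- t(SummarizedExperiment::assay(x, "absorbance"))
  dimnames(m) <- list(colnames(x), NULL)
  m
})

#' @rdname SpectraSet
#' @export
setMethod("wavenumbers", "SpectraSet", function(x)
  as.numeric(SummarizedExperiment::rowData(x)$wavenumber))

#' @rdname SpectraSet
#' @export
setMethod("sampleData", "SpectraSet", function(x)
  SummarizedExperiment::colData(x))

#' @rdname SpectraSet
#' @export
setMethod("sampleIds", "SpectraSet", function(x) colnames(x))

setMethod("show", "SpectraSet", function(object) {
  wn <- wavenumbers(object)
  cat("SpectraSet:", ncol(object), "samples x", length(wn), "wavenumbers\n")
  if (length(wn))
    cat(sprintf("  grid: %g..%g cm-1, step %g\n", wn[1], wn[length(wn)],
                if (length(wn) > 1) wn[2] - wn[1] else NA))
  md <- colnames(SummarizedExperiment::colData(object))
  if (length(md)) cat("  metadata:", paste(md, collapse = ", "), "\n")
})

# Replace the absorbance matrix (samples x wavenumbers), keeping metadata.
setAbsorbance <- function(x, m, wavenumbers = NULL) {
  wn <- wavenumbers %||% canecrush::wavenumbers(x)
  SpectraSet(m, wn, sampleData = as.data.frame(sampleData(x)),
             ids = sampleIds(x))
}

#' The default online-NIRS wavenumber grid
#'
#' Ascending grid from 4000 to 10000 cm-1 in 4 cm-1 steps (1501 points),
#' the acquisition grid of the online instrument.
#'
#' @param start,end,step grid limits and step, cm-1.
#' @return numeric vector of wavenumbers.
#' @export
defaultGrid <- function(start = 4000, end = 10000, step = 4)
  seq(start, end, by = step)

#' Convert reflectance to absorbance
#'
#' NIR spectra are modeled on the absorbance scale `A = log10(1/R)`.
#'
#' @param R reflectance values in (0, 1].
#' @return absorbance values, same shape.
#' @examples reflectanceToAbsorbance(c(1, 0.1, 0.01)) # 0 1 2
#' @export
reflectanceToAbsorbance <- function(R) {
  if (any(!is.finite(R)) || any(R <= 0) || any(R > 1))
    stop("reflectance must lie in (0, 1]")
  log10(1 / R)
}

#' Read / write spectra as CSV
#'
#' CSV dialect: first column `sample_id`, remaining column headers are
#' numeric wavenumbers (ascending or descending); one row per sample.
#' `readSpectra(writeSpectra(x, f))` round-trips to 1e-12.
#'
#' @param path file path.
#' @param metadata optional data.frame of sample metadata to attach, keyed
#'   by a `sample_id` column.
#' @return a [SpectraSet-class].
#' @export
readSpectra <- function(path, metadata = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("spectra CSV needs a sample_id column and at least one wavenumber")
  if (colnames(df)[1] != "sample_id")
    stop("first column must be 'sample_id'")
  wn <- suppressWarnings(as.numeric(colnames(df)[-1]))
  if (any(is.na(wn))) stop("non-numeric wavenumber header: ",
                           paste(colnames(df)[-1][is.na(wn)], collapse = ", "))
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("spectra values must all be finite numerics")
  md <- NULL
  if (!is.null(metadata)) {
    i <- match(ids, metadata$sample_id)
    if (any(is.na(i))) stop("metadata missing for some sample ids")
    md <- metadata[i, setdiff(colnames(metadata), "sample_id"), drop = FALSE]
  }
  SpectraSet(m, wn, sampleData = md, ids = ids)
}

#' @rdname readSpectra
#' @param x a `SpectraSet`.
#' @export
writeSpectra <- function(x, path) {
  m <- absorbance(x)
  df <- data.frame(sample_id = sampleIds(x), check.names = FALSE)
  df[as.character(wavenumbers(x))] <- as.data.frame(m)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a single spectrum from a JCAMP-DX file
#'
#' Minimal reader for fixed-point `##XYDATA=(X++(Y..Y))` blocks, honouring
#' XFACTOR/YFACTOR/FIRSTX/LASTX/NPOINTS. Intended for single exported
#' spectra; batch work uses the CSV dialect.
#'
#' @param path file path.
#' @param id sample id; defaults to the file's `##TITLE`.
#' @return a one-sample [SpectraSet-class].
#' @export
readJcamp <- function(path, id = NULL) {
  ln <- readLines(path, warn = FALSE)
  getField <- function(key) {
    i <- grep(paste0("^##", key, "="), ln)
    if (!length(i)) return(NULL)
    sub(paste0("^##", key, "="), "", ln[i[1]])
  }
  title <- getField("TITLE") %||% "spectrum"
  xf <- as.numeric(getField("XFACTOR") %||% "1")
  yf <- as.numeric(getField("YFACTOR") %||% "1")
  np <- as.numeric(getField("NPOINTS"))
  firstx <- as.numeric(getField("FIRSTX"))
  lastx <- as.numeric(getField("LASTX"))
  i0 <- grep("^##XYDATA=", ln)
  if (!length(i0)) stop("no ##XYDATA block in ", path)
  iEnd <- grep("^##END", ln)
  iEnd <- iEnd[iEnd > i0[1]][1]
  if (is.na(iEnd)) iEnd <- length(ln) + 1L
  body <- ln[(i0[1] + 1L):(iEnd - 1L)]
  y <- unlist(lapply(body, function(s) {
    v <- strsplit(trimws(s), "[[:space:]]+")[[1]]
    as.numeric(v[-1]) # first token is the line's X value
  }))
  if (!is.na(np) && length(y) != np)
    stop("NPOINTS mismatch: expected ", np, ", found ", length(y))
  wn <- seq(firstx, lastx, length.out = length(y)) * xf
  SpectraSet(matrix(y * yf, nrow = 1), wn, ids = id %||% title)
}

#' Average replicate spectra
#'
#' Arithmetic mean per group of a metadata key, by default on the
#' absorbance scale (`on = "reflectance"` converts to reflectance, averages,
#' and converts back, mirroring instrument-side averaging).
#' Averaging an already-averaged set is the identity.
#'
#' @param x a [SpectraSet-class].
#' @param by name of a `sampleData(x)` column to group by.
#' @param on `"absorbance"` (default) or `"reflectance"`.
#' @return a [SpectraSet-class] with one sample per group; the group size is
#'   recorded in the `n_averaged` metadata column.
#' @export
averageReplicates <- function(x, by, on = c("absorbance", "reflectance")) {
  on <- match.arg(on)
  cd <- sampleData(x)
  if (!by %in% colnames(cd)) stop("no metadata column '", by, "'")
  g <- as.character(cd[[by]])
  if (anyNA(g)) stop("grouping key '", by, "' missing for some samples")
  m <- absorbance(x)
  if (on == "reflectance") m <- 10^(-m)
  groups <- unique(g)
  avg <- rowsum(m, group = g, reorder = FALSE) /
    as.vector(table(factor(g, levels = unique(g))))
  if (on == "reflectance") avg <- log10(1 / avg)
  keep <- vapply(colnames(cd), function(col) {
    all(tapply(as.character(cd[[col]]), g, function(v) length(unique(v)) == 1))
  }, logical(1))
  md <- as.data.frame(cd[match(groups, g), keep, drop = FALSE])
  md$n_averaged <- as.vector(table(factor(g, levels = groups)))
  SpectraSet(avg, wavenumbers(x), sampleData = md, ids = groups)
}

#' Thin the wavenumber grid
#'
#' Keeps every `by`-th grid point (starting from the first), e.g. `by = 2`
#' turns a 4 cm-1 grid into an 8 cm-1 grid. Used as a fast mode for the
#' model-optimisation search.
#'
#' @param x a [SpectraSet-class].
#' @param by integer decimation factor.
#' @export
decimateSpectra <- function(x, by = 2L) {
  by <- as.integer(by)
  stopifnot(by >= 1L)
  if (by == 1L) return(x)
  idx <- seq(1L, length(wavenumbers(x)), by = by)
  x[idx, ]
}

#' Subset a SpectraSet
#'
#' Standard `[wavenumber-index, sample-index]` subsetting inherited from
#' SummarizedExperiment; the result is revalidated as a `SpectraSet`.
#' @param x a `SpectraSet`; `i` wavenumber indices, `j` sample ids/indices.
#' @name SpectraSet-subset
NULL
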
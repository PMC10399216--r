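#' Split samples into calibration and external-validation sets
#'
#' Seeded random split at a target ratio (roughly 4:1 by default), with
#' optional explicit counts (e.g. 262/73). With `enforceCoverage` the
#' samples carrying the minimum and maximum response are forced into the
#' calibration set (swapped with random calibration members), so the
#' calibration range always covers the validation range and predictions
#' never extrapolate beyond the model's range.
#'
#' @param ids character sample ids (n >= 10).
#' @param ratio calibration:validation ratio, > 1 (default 4).
#' @param seed integer seed.
#' @param y response values aligned to `ids` (required for coverage).
#' @param counts optional `c(nCalibration, nValidation)` overriding the
#'   ratio; must sum to `length(ids)`.
#' @param enforceCoverage force the min/max-response samples into
#'   calibration (default `TRUE`; needs `y`).
#' @return a [SplitPlan-class].
#' @export
splitCalibrationValidation <- function(ids, ratio = 4, seed = 1L, y = NULL,
                                       counts = NULL,
                                       enforceCoverage = TRUE) {
  n <- length(ids)
  if (n < 10) stop("need at least 10 samples to split")
  if (anyDuplicated(ids)) stop("duplicate ids")
  if (ratio <= 1) stop("ratio must exceed 1")
  nCal <- if (!is.null(counts)) {
    if (sum(counts) != n) stop("counts must sum to the number of ids")
    as.integer(counts[1])
  } else as.integer(round(n * ratio / (ratio + 1)))
  withSeed(seed, {
    calIdx <- sort(sample.int(n, nCal))
    if (enforceCoverage) {
      if (is.null(y)) stop("enforceCoverage requires y")
      for (i in c(which.min(y), which.max(y)))
        if (!i %in% calIdx) {
          out <- sample(setdiff(calIdx, c(which.min(y), which.max(y))), 1L)
          calIdx <- sort(c(setdiff(calIdx, out), i))
        }
    }
    rangeCheck <- if (is.null(y)) NA else
      min(y[calIdx]) <= min(y[-calIdx]) && max(y[calIdx]) >= max(y[-calIdx])
    new("SplitPlan", calibration = ids[calIdx],
        validation = ids[setdiff(seq_len(n), calIdx)],
        ratio = as.numeric(ratio), seed = as.integer(seed),
        rangeCheck = as.logical(rangeCheck))
  })
}

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d calibration / %d validation (seed %d)%s\n",
              length(object@calibration), length(object@validation),
              object@seed,
              if (isTRUE(object@rangeCheck)) ", range covered" else ""))
})

#' Pairwise correlation of a trait across groups (plots or years)
#'
#' Reshapes a genotype-by-group trait table and computes pairwise Pearson
#' correlations on the genotypes present in both groups of each pair
#' (pairwise deletion), with two-sided p-values from the t transform.
#' Pairs sharing fewer than 3 genotypes are reported as `NA`.
#'
#' @param data data.frame with genotype, group and value columns.
#' @param genotype,group,value column names (defaults `"genotype"`,
#'   `"group"`, `"value"`).
#' @return list: `r`, `p`, `n` (square matrices by group).
#' @export
correlateGroups <- function(data, genotype = "genotype", group = "group",
                            value = "value") {
  g <- as.character(data[[genotype]])
  gr <- as.character(data[[group]])
  v <- data[[value]]
  groups <- unique(gr)
  wide <- tapply(v, list(g, gr), mean)
  k <- length(groups)
  r <- p <- nm <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    ok <- stats::complete.cases(wide[, c(groups[i], groups[j])])
    nm[i, j] <- nm[j, i] <- sum(ok)
    if (sum(ok) < 3) next
    ct <- cor.test(wide[ok, groups[i]], wide[ok, groups[j]])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  diag(nm) <- colSums(!is.na(wide))[groups]
  list(r = r, p = p, n = nm)
}

#' Screen consistently extreme germplasm across years
#'
#' High group: genotypes in the top `q` quantile of predicted strength in
#' every year; low group analogously at the bottom. Quantiles use the
#' deterministic nearest-rank rule (the top/bottom `ceiling(q * n)`
#' genotypes per year, ties broken by genotype id). An empty intersection
#' yields an empty group with a warning, not an error.
#'
#' @param predictions data.frame with genotype, year and predicted value
#'   columns, or a genotype x year matrix.
#' @param q screening quantile in (0, 0.5), default 0.1.
#' @param genotype,year,value column names when `predictions` is a
#'   data.frame.
#' @return a [ScreeningResult-class].
#' @export
screenExtremes <- function(predictions, q = 0.1, genotype = "genotype",
                           year = "year", value = "predicted_kN") {
  if (!(q > 0 && q < 0.5)) stop("q must lie in (0, 0.5)")
  if (is.matrix(predictions)) {
    wide <- predictions
    df <- data.frame(
      genotype = rep(rownames(wide) %||% as.character(seq_len(nrow(wide))),
                     times = ncol(wide)),
      year = rep(colnames(wide) %||% as.character(seq_len(ncol(wide))),
                 each = nrow(wide)),
      predicted_kN = as.vector(wide))
  } else {
    df <- data.frame(genotype = as.character(predictions[[genotype]]),
                     year = as.character(predictions[[year]]),
                     predicted_kN = predictions[[value]])
    wide <- tapply(df$predicted_kN, list(df$genotype, df$year), mean)
  }
  years <- colnames(wide)
  if (length(years) < 2) stop("need at least 2 years")
  topSets <- lowSets <- list()
  for (yr in years) {
    v <- wide[, yr]
    ok <- names(v)[!is.na(v)]
    v <- v[ok]
    m <- ceiling(q * length(v))
    o <- order(-v, names(v)) # deterministic: value desc, then id
    topSets[[yr]] <- names(v)[o][seq_len(m)]
    o2 <- order(v, names(v))
    lowSets[[yr]] <- names(v)[o2][seq_len(m)]
  }
  high <- Reduce(intersect, topSets)
  low <- Reduce(intersect, lowSets)
  low <- setdiff(low, high)
  if (!length(high) || !length(low))
    warning("screening produced an empty ",
            paste(c("high", "low")[!c(length(high), length(low))],
                  collapse = " and "), " group")
  cr <- if (nrow(wide) >= 3)
    stats::cor(wide, use = "pairwise.complete.obs") else
    matrix(NA_real_, length(years), length(years),
           dimnames = list(years, years))
  new("ScreeningResult", predictions = df, correlations = cr,
      high = sort(high), low = sort(low), q = q)
}

setMethod("show", "ScreeningResult", function(object) {
  cat(sprintf("ScreeningResult (q = %.2f): %d high, %d low genotypes over %d years\n",
              object@q, length(object@high), length(object@low),
              length(unique(object@predictions$year))))
})

#' One-way ANOVA with Fisher's LSD letters
#'
#' One-way ANOVA across groups followed by Fisher's LSD pairwise
#' comparisons at `alpha` (0.05 by default) and a compact letter display
#' (groups sharing a letter do not differ). If every group has zero
#' within-group variance the comparison degenerates to exact ties: groups
#' differ exactly when their means differ.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length; >= 2 groups with
#'   >= 2 values each.
#' @param alpha significance level for the letter display.
#' @return list: `F`, `p` (ANOVA), `pairwise` (p-value matrix), `letters`
#'   (named character, groups ordered by decreasing mean), `means`.
#' @export
groupCompare <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 values")
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  mse <- tab["Residuals", "Mean Sq"]
  dfres <- tab["Residuals", "Df"]
  lev <- levels(groups)
  k <- length(lev)
  pw <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (mse == 0) {
      pw[i, j] <- pw[j, i] <- if (means[i] == means[j]) 1 else 0
    } else {
      tstat <- (means[i] - means[j]) /
        sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      pw[i, j] <- pw[j, i] <- 2 * pt(-abs(tstat), dfres)
    }
  }
  ord <- order(-means)
  letters <- .compactLetters(pw[ord, ord, drop = FALSE] < alpha)
  letters <- letters[lev[ord]][lev]
  names(letters) <- lev
  list(F = tab["groups", "F value"], p = tab["groups", "Pr(>F)"],
       pairwise = pw, letters = letters, means = means)
}

# Insert-and-absorb compact letter display from a logical "differs"
# matrix whose rows/cols are ordered by decreasing mean.
.compactLetters <- function(differs) {
  g <- nrow(differs)
  lev <- rownames(differs)
  sets <- list(seq_len(g))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (!differs[i, j]) next
    for (s in seq_along(sets)) {
      if (all(c(i, j) %in% sets[[s]])) {
        a <- setdiff(sets[[s]], i)
        b <- setdiff(sets[[s]], j)
        sets[[s]] <- a
        sets[[length(sets) + 1L]] <- b
      }
    }
    # drop subsets
    keep <- rep(TRUE, length(sets))
    for (s in seq_along(sets)) for (t in seq_along(sets))
      if (s != t && keep[t] &&
          all(sets[[s]] %in% sets[[t]]) && length(sets[[s]]) < length(sets[[t]]))
        keep[s] <- FALSE
    dup <- duplicated(lapply(sets, sort))
    sets <- sets[keep & !dup]
  }
  sets <- sets[order(vapply(sets, min, 0L))]
  out <- character(g)
  for (s in seq_along(sets))
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  stats::setNames(out, lev)
}
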
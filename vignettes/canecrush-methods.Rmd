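---
title: "Methods: NIRS calibration for sugarcane stalk crushing strength"
author: "canecrush"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIRS calibration for sugarcane stalk crushing strength}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canecrush)
```

# The phenotyping problem

Lodging — stalks buckling under their own weight or wind — is a major
yield loss in sugarcane, and breeding for lodging resistance needs a
mechanical-strength phenotype that can be measured at germplasm scale.
The laboratory reference assay compresses a stalk internode in a
universal testing machine until a 4 kN threshold and records force every
100 ms. The **crushing strength** trait is the force at the *first* peak
of that curve: the end of the elastic phase, when the first longitudinal
crack appears. The first peak is used rather than the global maximum
because its replicate-to-replicate relative standard deviation is far
smaller than that of the later yield-phase oscillation peaks — a fact the
synthetic force-curve generator reproduces by construction and the test
suite verifies.

The laboratory assay is accurate but slow. The package's core is the
high-throughput alternative: calibrate near-infrared (NIR) diffuse
reflectance spectra, collected online on a 4000–10000 cm⁻¹ grid in
4 cm⁻¹ steps and expressed as absorbance $A = \log_{10}(1/R)$, against
the laboratory trait with partial least squares (PLS) regression, and
then phenotype whole panels spectroscopically.

# The calibration model

## Pretreatment

Ten pretreatments (plus the no-op) are available, the standard set a
vendor optimisation would search: constant offset elimination (COE),
straight-line subtraction (SSL), standard normal variate (SNV), min–max
normalisation (MMN), multiplicative scatter correction (MSC), first and
second Savitzky–Golay derivatives (FD, SED), and the combinations
FD+SSL, FD+SNV, FD+MSC. In combinations the derivative is applied first,
matching the naming; a flag reverses the order for sensitivity analysis.
Savitzky–Golay parameters default to window 17, polynomial order 2 —
the convention of the instrument-class software — and are configurable.
Derivative filters evaluate the edge points from the edge polynomial
fits rather than trimming, so every pretreatment preserves the grid
length. MSC is the one statistics-bearing pretreatment: its reference
(the calibration mean spectrum, computed after the derivative stage for
FD+MSC) is fit on the calibration set only and frozen inside the model
for validation and prediction.

## PLS-1, rank choice and the optimisation search

The regression is centered, unscaled NIPALS PLS-1: per factor
$w \propto X^\top y$ (unit norm), $t = Xw$, $p = X^\top t / t^\top t$,
$q = y^\top t / t^\top t$, deflate and repeat; coefficients are
assembled as $b = W (P^\top W)^{-1} q$. At full rank on full-column-rank
data the predictions coincide with ordinary least squares, which the
tests assert against a normal-equations oracle at 1e-8. A
residual-standardising "modified PLS" variant is provided behind
`method = "mpls"` but is not the default: plain PLS is what the
instrument software implements.

Rank is chosen from a seeded 10-fold cross-validation curve (LOO
available) by a parsimony rule: the smallest rank whose RMSECV is within
2% of the curve minimum. The model search mirrors the vendor-style
optimisation: the grid is cut into 10 equal subregions, all 55
contiguous windows are crossed with the 11 pretreatment codes, each
candidate is cross-validated over ranks 1–10, and the candidate with the
smallest RMSECV wins (ties: fewer latent variables, then the wider
window, then lexicographic code). Only contiguous windows are searched;
non-contiguous unions can be passed explicitly.

## Evaluation metrics

$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ (not a squared correlation),
$\mathrm{RMSE} = \sqrt{\mathrm{SSE}/n}$, and
$\mathrm{RPD} = \mathrm{SD}(y)/\mathrm{RMSE}$ with the $n$-denominator
SD. These conventions are chosen deliberately so that
$\mathrm{RPD} = (1 - R^2)^{-1/2}$ holds *exactly* on a common
evaluation set — e.g. $R^2 = 0.90 \Leftrightarrow \mathrm{RPD} = 3.16$ —
which is asserted for every metrics call in the tests. RPD ≥ 3 is the
conventional "excellent" calibration threshold.

## Outliers: GH in principal-component score space

Spectral outliers are flagged by the GH ("global H") statistic:
Mahalanobis distance in the score space of a centered PCA of the raw
calibration spectra (10 components by default), divided by the number of
components so that an average calibration sample scores about 1; the
fitting-set mean GH is exactly $(n-1)/n$ and the fitting-set total is
exactly $n - 1$, both asserted in tests. Samples with GH > 3.0 are
excluded before modeling, and the *same frozen* PCA flags prediction-time
outliers — refitting PCA on a prediction set would silently redefine the
reference population. No spectral-residual (Q/SPE) statistic is
computed; GH is the only criterion.

## Splitting, integrative recalibration and screening

Calibration/validation splits are seeded random draws at a roughly 4:1
ratio (explicit counts such as 262/73 are honoured exactly), with the
minimum- and maximum-trait samples forced into calibration so the
calibration range always covers the validation range. After external
validation the two sets are pooled and the selected recipe is
recalibrated on all samples ("integrative recalibration"), which is how
the final deployable equation is produced.

Screening applies the final model across years, drops GH-flagged
samples, and selects genotypes that fall in the top (bottom) decile of
predicted strength in *every* year, with deterministic nearest-rank
quantiles and ties broken by genotype id. The per-year-quantile
intersection is this package's explicit, reproducible rule for an
operation that field practice usually leaves informal; under independent
(null) years the expected number of consistent extremes is
$n q^{3} \approx 0.3$ for $n = 300, q = 0.1$, and the tests check that
no more than 3 appear over 20 seeds. Group separation is confirmed by
one-way ANOVA with Fisher's LSD letters at $\alpha = 0.05$.

# The synthetic panel generator

No germplasm NIRS dataset of this kind is public, so the package ships a
generator that emulates the statistical structure the analysis assumes,
and the whole pipeline is exercised end to end on it.

* **Trait.** Genotype-level crushing strength is normal with mean
  1.30 kN and SD 0.28 kN, clamped to [0.69, 2.13] kN — the range centred
  on the mean; clamping (not resampling) keeps the draw simple and the
  clamped fraction (~2% at the defaults) is recorded. A
  genotype-by-plot/year effect (SD 0.08 kN) keeps cross-plot genotype
  correlations high (~0.92) while allowing environment variation, and
  each plot/year cell carries 3 replicate measurements with 0.10 kN
  noise — chosen so that the replicate RSD at the trait mean is ~8%,
  typical of a mechanical assay, and so that the measured-trait noise
  floor puts cross-validated RMSE near 0.09 kN at the default panel
  size.
* **Spectra.** Beer–Lambert linear mixing of 3 latent constituents
  (smooth sums of 3–8 Gaussian bands, widths 50–400 cm⁻¹, linearly
  independent), plus the standard NIR artifact stack the ten
  pretreatments exist to remove: additive offset (SD 0.02), linear
  baseline tilt (SD 0.01 over the grid), multiplicative scatter
  (SD 0.03) and i.i.d. noise (SD 0.002 absorbance). With these
  magnitudes the first three principal components carry ≥ 99.9% of the
  spectral variance, comfortably emulating the low-rank structure of
  real online-NIRS germplasm spectra.
* **Identifiability.** Per-sample constituent concentrations are solved
  so the sample's noise-free trait is an exact known linear function of
  them. Consequently, with all noise and scatter switched off, a
  rank-3 PLS model recovers the trait with $R^2 = 1$ to 1e-8 — the
  generator's ground truth makes full parameter recovery testable, not
  just plausible.
* **Force curves.** A monotone elastic rise ending exactly at the true
  strength, a crack, 2–5 yield oscillation peaks whose heights carry
  four times the first peak's jitter (so first-peak RSD is smallest, as
  in the laboratory assay), then a compaction-strengthening rise ending
  exactly at the 4 kN threshold.

All randomness flows from explicit seeds; identical configurations give
bit-identical panels and curves, and the run manifest of the pipeline
allows byte-identical replay.

What the generator does **not** emulate: real sucrose/fibre chemistry
(constituents are abstract), wavelength-dependent scatter, instrument
drift between standardisations, and missing genotypes per plot. Passing
the recovery tests therefore shows the algorithms are correct and the
pipeline is well-posed under the stated noise model — it does not
certify performance on any particular instrument.

# Numerical and design choices

* Averaging of replicate spectra is done on the absorbance scale by
  default (`on = "reflectance"` mirrors instrument-side averaging of
  reflectance); for small within-sample variation the difference is
  second order.
* $\log_{10}$ is used for absorbance, the standard NIR convention.
* MMN maps to [0, 2], mirroring the vendor convention; the scale matters
  because per-spectrum normalisation is method-defining, so it is fixed
  and documented rather than configurable.
* Peak detection is prominence-based (default 5% of the curve maximum)
  on a lightly smoothed trace (window 5), with peak heights read from
  the raw trace at the refined position, so the reported first peak is
  invariant to the smoothing window on clean curves.
* RMSE denominators are $n$ everywhere, paired with $n$-denominator SDs
  in RPD, for the exact RPD identity; `sd()`'s $n-1$ convention is used
  only inside SNV, where it is the community definition.
* Degenerate inputs (constant spectra in SNV/MMN, zero MSC slope,
  zero-variance response, all-flagged outlier sets) raise informative
  errors naming the offending samples; a force curve with no detectable
  peak yields a missing value rather than an error so batch extraction
  continues.
* Test and example problem sizes: unit tests run the full statistical
  structure at reduced scale (40 genotypes, 151-point grid); the
  end-to-end recovery experiment uses the full 335-genotype preset with
  the 8 cm⁻¹ decimated grid, and the acceptance script repeats it on
  the full 1501-point grid. Decimation changes none of the
  qualitative conclusions — both modes pass the same thresholds.

# Known limitations

* The optimisation search is exhaustive over its candidate grid; with
  custom, much larger candidate lists the cost grows linearly.
* GH is computed in PCA score space; some vendor implementations use
  PLS score space at prediction time. With the low-rank spectra both
  flag the same gross outliers, but values are not interchangeable.
* The exact enumeration and internal cross-validation segmentation of
  the vendor optimiser are proprietary; this package's search is an
  explicit, documented approximation, and its seeded 10-fold CV is the
  reproducible stand-in for the vendor's unstated scheme.
* Fisher's LSD makes no multiplicity correction by design (it is the
  field's convention for germplasm letters); treat letters as
  descriptive.
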
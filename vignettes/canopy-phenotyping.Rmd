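---
title: "Canopy phenotyping from ground and UAV imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy phenotyping from ground and UAV imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyx)
```

# The problem

Field trials that compare cereal genotypes under different nitrogen
fertilization regimens traditionally rely on destructive sampling and
post-harvest yield data. High-throughput phenotyping replaces much of that
with imagery: an RGB camera held over each plot (or flown over the trial on a
UAV), a multispectral camera sampling narrow bands from 450 to 950 nm, and a
thermal camera. `canopyx` implements the full analysis path from those
sensors to trial-level statistics:

1. **RGB colour indices** — per-plot means of colour components (HSI hue,
   saturation, intensity; CIE-Lab lightness, a\*, b\*; CIE-Luv u\*, v\*) and
   the hue-window classification indices GA (Green Area), GGA (Greener Green
   Area) and CSI (Crop Senescence Index).
2. **Multispectral indices** — NDVI, PRI, SAVI, MCARI, WBI, RDVI, EVI, ARI2,
   CRI2, TCARI, OSAVI and the TCARI/OSAVI ratio from 11-band reflectance
   stacks.
3. **Thermal summaries** — per-plot mean and standard deviation of canopy
   temperature from raw 16-bit counts.
4. **Plot extraction** — cutting orthomosaics into per-plot mini-rasters from
   polygon definitions.
5. **Nitrogen-use efficiency** — agronomic NUE (aNUE) and N partial factor
   productivity (NPFP) from the trial table.
6. **Trial statistics** — ANOVA with Tukey HSD compact letter displays, PCA,
   thresholded correlation networks, and stepwise yield-model selection with
   LMG variance decomposition.

Because real trial imagery is bulky and rarely redistributable, the package
ships a synthetic-trial generator with a fully known generative model, so
every stage can be tested end to end against ground truth.

# Colour models

Plot images are 8-bit sRGB. The package assumes the standard sRGB decoding
(piecewise gamma) and the D65 white point; consumer cameras write sRGB JPEGs,
and no colour-calibration metadata is available in this workflow, so this is
a documented assumption rather than a measured property. The white point is
taken as the image of RGB = (1, 1, 1) under the sRGB-to-XYZ matrix, which
guarantees that grey pixels land exactly on the achromatic axis (a\* = b\* =
u\* = v\* = 0) instead of inheriting rounding residue from independently
tabulated constants.

For HSI, Intensity is the mean of the normalized channels, Saturation is
`1 - min/Intensity`, and Hue is the hexagonal hue angle (red 0°, green 120°,
blue 240°). Achromatic pixels get hue 0° by convention and are excluded from
hue-window classification via a saturation guard (default 0.02), because hue
is undefined on the grey axis and letting such pixels fall into a window
would bias GA on overexposed or shadowed plots.

Per-image colour components are arithmetic means over *all* pixels, not over
classified pixels: the colour components serve as whole-image vegetation
indices, distinct from the classification indices GA/GGA. Mean hue is the
arithmetic mean of per-pixel hue angles; for canopy images whose hues
concentrate in the 30°–140° range this is unambiguous, but it would be
misleading for hue distributions spanning the 0°/360° wrap (a known
limitation, irrelevant to vegetation imagery).

# GA, GGA and CSI

GA is the fraction of pixels whose hue falls in a wide green window, GGA the
fraction in a narrower window that excludes yellowish (senescent) hues. The
defaults are GA = [60°, 180°] and GGA = [80°, 180°], following the BreedPix
convention; both windows are configuration-exposed because the exact
thresholds are a software convention, not a physical constant. Window nesting
is enforced, which makes GGA ≤ GA an invariant rather than a hope.

CSI = 100 × (GA − GGA) / GA rescales the senescent share of the green area
to percent. At GA = 0 (bare plots) CSI is defined as 0 rather than NaN so
that bare-soil plots do not poison downstream ANOVA and correlation tables.
Trial summaries average per-plot CSI values; recomputing CSI from pooled
GA/GGA means gives systematically different numbers (a ratio of means is not
the mean of ratios) and is treated as approximate only.

# Multispectral indices

Each index formula is evaluated on the **per-plot mean band reflectance**
(means first, then the formula), matching the standard per-plot export
workflow of orthomosaic processing. The alternative — computing the index
per pixel and averaging — is available by passing single-pixel stacks, but
is not the default because ratio indices are not linear in the bands.

Two design points deserve emphasis:

* **Reflectance scale is declared, never guessed.** The additive constants in
  SAVI (`L = 0.5`), EVI (`+1`) and OSAVI (`+0.16`) act on whatever scale the
  reflectances are on, so an index computed on [0, 255] data differs from the
  same index on [0, 1] data by more than a scale factor. The I/O layer
  accepts `"unit"` and `"8bit"` declarations and performs no silent
  rescaling. The synthetic generator works on the unit scale.
* **Band bookkeeping.** The camera has 12 sensors with 11 distinct centre
  wavelengths (780 nm is duplicated). The formulas use exactly the
  wavelengths they name — OSAVI uses 780 nm, NDVI/SAVI/RDVI/EVI/ARI2 use
  840 nm — and the 720 and 860 nm bands are carried through I/O unused.

Zero denominators (e.g. R670 = 0 for MCARI, R950 = 0 for WBI, OSAVI = 0 for
the TCARI/OSAVI ratio) produce NaN with an explicit warning, never a silent
infinity.

Thermal rasters are stored as 16-bit counts. A literal "Kelvin times ten
thousand" encoding cannot fit a 16-bit integer (300 K would need 3 × 10⁶), so
the package defaults to 0.01 K per count (centi-Kelvin, 0–655 K range) and
exposes the scale as a parameter; conversions outside [−100, 150] °C trigger
a plausibility warning. The per-plot summary is the arithmetic mean and the
population standard deviation over unmasked pixels.

# Plot extraction

Mosaics are cut with an explicit, stated convention: pixel coordinates are
0-based with x = column and y = row increasing downward; the pixel at
(row i, col j) has centre (j + 0.5, i + 0.5); a pixel belongs to a polygon
when its centre lies inside (centre sampling), so adjacent plots sharing an
edge partition pixels without double counting. A polygon that leaves the
mosaic produces an error record while the batch continues — a single bad
polygon must not abort a 90-plot extraction.

An optional inward buffer erodes each (convex) polygon before masking, to
trim plot borders and alleys; the default is 0 because the source workflow
describes no edge trimming. Erosion is implemented by shifting each edge
inward along its normal and re-intersecting; over-erosion is detected by
edge-direction reversal and rejected.

# Nitrogen-use efficiency

With GY the grain yield (kg/ha) and N the total applied nitrogen (kg/ha):

* aNUE = (GY − GY₀) / N, where GY₀ is the mean yield of the *same genotype's*
  zero-N plots (genotype-specific baselines matter because genotypes differ
  at N0);
* NPFP = GY / N.

Both are flagged undefined (NA) at N = 0. The identity
NPFP = aNUE + GY₀ / N makes a published aNUE/NPFP grid over-determined: every
non-zero-N row implies the baseline GY₀ = (NPFP − aNUE) × N. The
`table2_consistency()` report exploits this: for the bundled reference grid
the implied baselines per genotype agree to a coefficient of variation below
0.5% and cross-row NPFP predictions reproduce the printed cells within
±0.02 — the printing precision of two-decimal inputs. That 0.02 tolerance is
the rounding propagation bound, not a fitted number.

Yield components are linked by GY [kg/ha] = 0.01 × NG [m⁻²] × TGW [g];
`yield_component_check()` returns the relative discrepancy.

# Trial statistics

**ANOVA + Tukey letters.** One-way ANOVA per trait and factor, with Tukey HSD
pairwise comparisons (Tukey–Kramer on unbalanced data, as excluded plots can
unbalance groups) and a compact letter display built by the insert-and-absorb
algorithm; two levels share a letter exactly when their pairwise Tukey
p-value is ≥ α (default 0.05). Zero residual variance short-circuits to exact
mean-equality grouping. The genotype × treatment interaction is computed by
`anova_interaction()`, though main effects are the default display.

**PCA** is computed on standardized traits (correlation-matrix PCA), constant
traits dropped with a warning, and signs fixed so each component's
largest-magnitude loading is positive — a reproducibility convention, since
eigenvector signs are arbitrary.

**Correlation networks** keep edges with |r| > 0.6 and p < 0.001 (exact
t-transform on n − 2 df). The p-threshold is deliberately applied without
multiple-testing correction, matching the convention of correlation-network
displays; at n = 90 the joint threshold is conservative regardless.

**Stepwise yield models.** Forward and backward searches are both run
(default `direction = "both"`); disagreement between the two selected sets is
reported with a warning, never silently resolved, and the lower-AIC set
provides the returned fit. The default criterion is AIC via `stats::step`; a
classical p-enter/p-remove search is provided as the alternative because
legacy statistical software often used p-thresholds. Candidates are sorted
lexicographically so ties break deterministically, and perfectly collinear
candidates are dropped with a warning before the search.

**LMG variance decomposition.** Each predictor's share of the model R² is its
incremental R² averaged over all orderings of the predictor set, computed
exactly by subset enumeration with weights |S|!(p−|S|−1)!/p! (identical to
the permutation average, but 2^p fits instead of p! fits). Shares are
non-negative for OLS and sum to R² — both asserted in tests against a
brute-force all-permutations oracle. Exact enumeration refuses more than 12
predictors; a sampling fallback over random orderings is available.

**SEP** (standard error of prediction) is the residual standard error,
√(RSS / (n − p − 1)) — stated explicitly because the term is used loosely in
the application literature.

# The synthetic trial

The generator emulates a barley N-fertilization trial: 3 genotypes × 10
N regimens × 3 replicate blocks = 90 plots, with the ten reference schedules
(four split doses summing to 0–170 kg/ha) bundled as a fixture. Its defaults
are fixed study conditions, not tuning knobs:

* **Plot images** are mixtures of three hue populations — green 110°,
  senescent 70°, soil 30° — with Gaussian hue jitter (sd 3°) and fixed
  mid-range saturation (0.5) and value (0.6). The centres sit ≥ 10° from the
  GA/GGA window edges so classification recovers class fractions exactly when
  jitter is disabled; with the default jitter, misclassification is below
  10⁻³ per pixel. Class pixel counts are allocated by largest-remainder
  rounding (deterministic); only jitter and pixel placement are random.
  Default image size is 100 × 100 px — large enough that the 1/n binomial
  granularity (10⁻⁴) is negligible.
* **Reflectance stacks** are cover-weighted averages of three endmember
  spectra (green canopy with the 670 nm absorption trough and NIR plateau;
  senescent tissue; soil) on the unit scale, plus optional per-pixel noise
  (sd 0.005), at 20 × 20 px.
* **Thermal rasters** put green canopy cooler than soil (morning
  17/20/24 °C, afternoon 11.5/13/16 °C for green/senescent/soil, pixel noise
  sd 0.3 °C), so plot means equal the cover-weighted class mixture.
* **Green cover** rises with N supply from genotype-specific baselines
  (0.30/0.38/0.40 + 0.5 × N/N_max, plot noise sd 0.04, clipped to
  [0.02, 0.97]); the non-green remainder splits 30/70 between senescent
  tissue and soil.
* **Yields** follow GY = 1.41 + 6.46 × green cover + N(0, 0.4) t/ha — the
  published ground-model coefficients reused as the generative truth, with a
  noise level chosen to give residual scatter comparable to the published
  SEP (≈ 0.5–0.6 t/ha). TGW is drawn per plot (45 ± 3 g) and NG derived so
  GY = 0.01 × NG × TGW holds exactly.

Randomness is controlled by one master seed; per-artifact seeds are derived
from it by plot index, so a fixed configuration reproduces the trial byte for
byte (asserted by hashing the written files) and any single plot can be
regenerated without replaying the whole trial.

**What the generator does not emulate:** within-plot spatial structure
(pixels are exchangeable — real senescence patches and row structure are
absent), illumination geometry and shadows, BRDF effects, atmospheric and
sensor calibration error, and spatial field trends across blocks. Passing
recovery tests therefore demonstrates the correctness of the index
arithmetic and the statistical machinery under the stated generative model,
not robustness to those real-world effects.

# Problem sizes in the test suite

The suite exercises the full 90-plot design throughout. Images are generated
at 100 × 100 px where a single trial is processed, and at 24 × 24 px inside
the 100-repetition stepwise-recovery study, where only the plot-level GGA
(a spatial average whose accuracy depends on pixel count, 1/576 ≈ 0.002,
far below the cover signal) feeds the selection; the repeated-run study is a
statement about model selection, not about image resolution. Reflectance and
thermal rasters use 4 × 4 to 20 × 20 px since per-plot indices consume only
band means.

# Known limitations

* Hue means are arithmetic, not circular (harmless for canopy hues, wrong
  near the red wrap).
* `inward_buffer()` supports convex polygons only; field plots are
  rectangles in practice.
* Geo-referenced extraction expects polygons already expressed in mosaic
  pixel coordinates; coordinate-system transformation is out of scope.
* The published headline model fits (r² of 0.716–0.827) are not recomputable
  without the original 90-plot measurements, which were never deposited; the
  printed models ship as fixtures for prediction, and the statistical layer
  is validated on synthetic data with known truth instead.
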
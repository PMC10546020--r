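---
title: "Estimating cotton yield physiology from UAV imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cotton yield physiology from UAV imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Lint yield in cotton is the product of three physiological drivers: the
photosynthetically active radiation the canopy intercepts over the season
(IPAR), the efficiency with which intercepted radiation is converted to dry
matter (radiation use efficiency, RUE), and the fraction of biomass
allocated to lint (harvest index, HI). `cottonphys` implements a complete,
testable pipeline that estimates all three from plot-level UAV imagery —
multispectral reflectance during the season and RGB immediately before
harvest — together with a synthetic-scene generator that stands in for
field data, so that every stage of the chain can be verified against known
ground truth.

## The processing chain

1. **Thermal time.** Daily growing degree days are
   `max(0, (min(Tmax, 33.9) + Tmin)/2 − 15.6)` °C·d, accumulated from the
   planting day inclusive. Only the maximum temperature is capped; the
   zero floor is applied per day, not after averaging across days. These
   base/ceiling values are the standard cotton parameters.
2. **Canopy segmentation.** Each five-band reflectance raster (blue,
   green, red, red-edge, NIR) is classified with the product
   NDVI × ExG, where NDVI = (NIR−R)/(NIR+R) and ExG = 2G−R−B, both on
   reflectance. Pixels with index strictly greater than 0.02 are canopy.
   Band means are then taken over canopy pixels whose centers fall inside
   the plot ROI (the middle two crop rows).
3. **Vegetation indices.** Twenty indices plus the five raw band means
   are computed from each band-mean record (`vi_names()`); all are
   candidate predictors. Two formulas are kept exactly as tabulated in
   the source formulary even though they differ from the classical
   literature forms: EVI with numerator `2.5·NIR − R` (the classical
   variant is available as `"EVI_classic"`) and
   RGBVI = (G − B·R)/(G² + B·R). Zero denominators propagate `NA`
   markers; affected records are dropped from fitting with a count.
4. **Radiation budget.** IPAR_f = (PAR_above − PAR_below)/PAR_above,
   clamped to [1e−6, 1−1e−6] so the beta likelihood stays finite at the
   boundaries. Cumulative incident PAR is 45% of summed daily solar
   radiation from planting; cumulative IPAR is its product with IPAR_f.
   RUE_n = Δbiomass/ΔIPAR relative to the first sampling date, per plot.
   Measured HI is lint yield over 10 × the seasonal maximum biomass
   (g m⁻² → kg ha⁻¹).
5. **Model screening.** For each candidate predictor, a GLM is fitted by
   maximum likelihood: beta/logit for IPAR_f, gamma/log for biomass
   (linear predictor `1 + VI + GDD + VI·GDD`), gaussian/identity for RUE
   (intercept + period-averaged VI). Records are pooled, outliers
   removed once per response by the 1.5·IQR rule (type-7 quantiles),
   then split 60/40 stratified by sampling date. Training models are
   scored by generalized R², AICc and BIC (k counts the dispersion
   parameter); validation by squared Pearson correlation (R²cv) and
   RMSEcv. Ranking is by ascending RMSEcv, ties broken by descending
   R²cv then ascending AICc.
6. **CFI and lint yield.** Pre-harvest RGB is converted to grayscale
   (mean of channels), smoothed with an edge-preserving bilateral filter,
   sharpened by adding a 5×5 Laplacian response (−1 ring, +24 center,
   clipped to 0–255), smoothed with a 3×3 arithmetic mean, and
   thresholded at >150. CFI is the white-pixel fraction of the ROI; lint
   yield is an ordinary least-squares function of CFI (no validation
   split — one harvest point per plot).
7. **Mechanistic RUE and HI.** RUE is rebuilt from model outputs
   (predicted IPAR_f × cumulative incident PAR; biomass modeled or
   measured by flag), and HI as CFI-predicted yield over 10 × the
   maximum of the predicted biomass trajectory, evaluated per season and
   pooled.

## Why these model families

IPAR_f is a fraction on (0, 1) with variance that shrinks near the
boundaries — the beta distribution with a logit mean link captures both.
Biomass is positive with multiplicative errors — gamma with a log link.
RUE is approximately linear in the period-averaged index with roughly
constant variance — gaussian with identity link, equivalent to ordinary
linear regression (the package's fit reproduces `lm()` to 1e−8, which the
tests assert). The interaction term `VI·GDD` is included by default
because the slope and intercept of the VI–response relationship drift
with crop stage; a main-effects-only fit is available through `terms`.

The beta likelihood is maximized directly (BFGS with the analytic score,
predictors standardized internally so coefficients spanning several
orders of magnitude are equally conditioned, then mapped back; the
observed-information covariance is computed in the standardized space and
transformed exactly). The gamma fit pairs IRLS coefficients with the ML
shape estimate; its coefficient covariance uses the expected information
at the ML shape.

## Numerical and convention choices

* **Generalized R²** uses the Nagelkerke normalization
  `(1 − exp(−(2/n)(ℓ₁−ℓ₀))) / (1 − exp((2/n)ℓ₀))`. For continuous
  responses whose null log-likelihood is positive (densities above 1 —
  routinely the case for beta-distributed fractions and for RUE on its
  natural scale), the normalizing denominator is negative and the
  statistic can leave [0, 1] and even lose monotonicity in ℓ₁. This is an
  intrinsic property of the likelihood-ratio construction, not a defect
  of the fit; model ranking therefore relies on cross-validation error,
  and the training R² column is reported as-is. The statistic behaves
  classically wherever ℓ₀ < 0 (e.g. biomass), and the test suite asserts
  nested-model monotonicity there.
* **Pixel conventions.** Pixel (i, j) (1-based) has center
  (x = j−0.5, y = i−0.5), y increasing downward; ROI containment is
  strict interior by even-odd ray casting, boundary pixels excluded.
* **Thresholds are strict** (`> 0.02`, `> 150`), matching their
  definitions.
* **Scale invariance.** Pure band-ratio indices (NDVI, RVI, WDRVI, …)
  are invariant to a common positive rescaling of all bands;
  soil-adjusted forms with additive constants (SAVI, OSAVI, MSAVI, EVI,
  TCARI and the TCARI/OSAVI ratio) are not. Note that WDRVI *is*
  homogeneous of degree zero and TCARI/OSAVI is *not* — the +0.16 in
  OSAVI's denominator breaks the homogeneity of the ratio — and the
  property tests assert exactly this algebra.
* **Stratified split.** `round(0.6·n)` per date stratum to training,
  remainder to validation; singleton strata go to training. The split is
  seeded and restores the caller's RNG state.
* **Filter parameters.** The bilateral σ_spatial = 3 px and σ_range = 30
  intensity units, and the 3×3 mean window, are chosen to preserve boll
  blobs of ≥3 px radius (boll/background contrast ≈ 100–135 units, far
  above σ_range) while averaging away background texture (≈ 10–30
  units, below σ_range); all are configurable. Convolutions use reflect
  padding.

## The synthetic study

`generate_study()` emulates a randomized complete block trial: 5 nitrogen
rates (0, 44, 89, 135, 179 kg N ha⁻¹) × 5 blocks, sampled 5 times over a
150-day season (25 plots × 5 dates = 125 records), the layout used to
create wide variability in canopy development and yield.

* **Weather** is sinusoidal with gaussian noise (Tmax 32 ± 4 °C over the
  season phase, Tmin 10 °C below, solar 18 ± 6 MJ m⁻² d⁻¹), which places
  the sampled GDD range at roughly 500–1700 °C·d — comparable to a
  southeastern US cotton season.
* **Canopy cover** follows a logistic in GDD whose asymptote rises
  linearly with nitrogen rate (0.55 → 0.95); plot rasters place exactly
  `round(cover · npixels)` canopy pixels along four crop-row strips
  (weighted sampling without replacement), each pixel drawn as its
  endmember spectrum + N(0, 0.01) band noise. The canopy red endmember
  declines with nitrogen rate as a chlorophyll proxy; endmember spectra
  are invented, documented constants — configuration, not claims.
* **Physiology** mirrors the fitted model forms exactly: IPAR_f is
  beta-distributed with logit mean linear in (VI, GDD, VI·GDD) at
  precision φ = 60; biomass is gamma-distributed with log mean in the
  same terms at shape α = 25 (CV ≈ 20%, a realistic biomass sampling
  error). The biomass coefficients are set so the mean trajectory runs
  from ≈50 g m⁻² at first sampling to ≈800–1100 g m⁻² at peak — a
  realistic cotton range. True HI is truncated-normal (0.4 ± 0.03 on
  (0.2, 0.6)) and true lint yield is HI × 10 × peak mean biomass.
  PAR readings are back-computed from the drawn IPAR_f with
  PAR_above = 2000, so the interception equation round-trips exactly.
* **Harvest imagery** paints near-achromatic boll disks (radius 2–4 px,
  intensity N(235, 8)) over soil N(100, 10) and defoliated-vegetation
  blobs N(130, 10); the boll count is Poisson with mean 0.05 × yield, and
  the painted fraction is recorded as true CFI.

All randomness derives from a single root seed through fixed per-stage
sub-seeds (1 weather, 2 physiology, 3 harvest measurement, 100+ rasters,
500+ harvest images); two runs with the same configuration are
byte-identical, and no statistic of the data depends on anything outside
the configuration and seed.

What the generator deliberately does **not** emulate: radiative-transfer
canopy optics (pixels are linear endmember mixtures), shadows and
illumination gradients, georeferencing and orthomosaicking artifacts,
late-season biomass decline (the mean trajectory is monotone), bolls
hidden below the canopy top, and any spatial correlation between
neighboring plots. Passing tests therefore demonstrate that the
*algorithmic chain* is correct and identifiable under its own
assumptions — not that those assumptions hold for any particular field
dataset.

## Design choices that were genuinely open

* **Comparing mechanistic RUE.** The mechanistic RUE built from measured
  biomass and modeled IPAR_f is evaluated against the measured RUE
  series (measured biomass and measured IPAR_f), the comparison that
  isolates the interception model's contribution; both sides share the
  biomass draws, so biomass sampling noise cancels. Evaluating against
  the noise-free generative trajectory instead would be dominated by the
  gamma biomass noise the generator itself mandates.
* **Recovery-study design.** The coefficient-recovery studies use a 2×2
  factorial over VI ∈ {0, 1} and GDD ∈ {0, 1600} with replication
  weighted by inverse root cell information (32/14/14/40%), a
  Ds-optimal-style allocation: the interaction coefficient is tiny
  relative to its sampling error under a random-uniform design, and the
  weighted factorial is what makes it identifiable at n = 250.
* **Measured-HI bias.** Measured HI divides by the *maximum* of several
  noisy biomass draws, which is upward-biased relative to the maximum of
  the underlying means; predicted HI (smooth model trajectory) therefore
  sits systematically above measured HI by a few hundredths. This is a
  property of the definition, visible in the field protocol as well.
* **Period-averaged RUE predictors** are running means of each index
  from the first sampling date through date n, matching the RUE
  calculation period; each period is treated as an independent record.
* **Problem sizes.** The test suite exercises the full default study at
  seeds 1–10 and the recovery studies at 100 replicates of n = 250;
  smaller 3×3-plot studies are used for structural checks. These sizes
  make every property measurable while keeping the suite quick to run.

## Known limitations

RUE remains weakly predictable from period-averaged indices — in the
synthetic study exactly as in the field: the response is a ratio of two
noisy differences, and most of its variance is measurement noise rather
than canopy signal. HI inherits the combined errors of the yield and
biomass models and is the weakest link of the chain. The CFI chain
slightly over-counts white area on low-contrast imagery (sharpened boll
rims survive the mean filter), which the yield regression absorbs into
its slope; on clean imagery the painted fraction is recovered within 15%.
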
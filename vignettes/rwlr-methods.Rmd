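---
title: "From bedrock chemistry to vegetation productivity: methods and design of the rwlr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From bedrock chemistry to vegetation productivity: methods and design of the rwlr package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwlr)
```

## The scientific problem

Karst landscapes sit on soluble carbonate bedrock. Dissolution opens
crevices that drain water out of the regolith, so vegetation on Ca-rich
bedrock experiences faster soil drying during rain-free periods than
vegetation on Si-rich (insoluble) bedrock, and — the hypothesis goes —
lower productivity. Direct regolith monitoring at regional scale is
impossible, so the chain is tested statistically:

1. **Dryness from space.** The Temperature Vegetation Dryness Index
   (TVDI) summarises the NDVI/surface-temperature scatter: for a given
   NDVI, pixels near the warm *dry edge* `T_d = a + b * NDVI` are
   water-stressed and pixels near the cool *wet edge* `T_w = c + d * NDVI`
   are wet, giving `TVDI = (T_obs - T_w) / (T_d - T_w)` in `[0, 1]`.
2. **Regolith water loss rate (RWLR).** Within each *dry spell* (>= 5
   consecutive days without precipitation), the slope of the zone-mean
   TVDI over time measures how fast the regolith dries. Per critical-zone
   unit (CZU; a 20-km disc around a meteorological station), RWLR is the
   mean per-spell drying slope, scaled by 100.
3. **Variable importance.** All-subsets linear models, AIC, Akaike
   weights, the 95% cumulative-weight best subset and the relative
   variable importance (RVI) rank RWLR against climate and soil
   predictors of net primary productivity (NPP), and bedrock oxides
   against RWLR, after a `|r| > 0.70` collinearity screen.
4. **Path analysis.** Two recursive path models (one per bedrock oxide,
   since Si and Ca oxides are strongly negatively correlated) quantify
   the indirect effect bedrock -> RWLR -> NPP alongside the direct
   temperature effect.
5. **Global signal.** Per pixel, the correlation between growing-season
   (April-September) mean NDVI and temperature is compared between the
   inside and outside rings of carbonate-area boundaries with a
   Mann-Whitney-Wilcoxon test.

The real inputs (decade-long station records, 5-day satellite composites,
bedrock geochemistry surveys) are not redistributable, so the package
ships generators that create all of them with known structure; every
downstream claim is tested against that known structure.

## The synthetic world

The generators state a fixed world; their defaults are not tuning knobs.

**Precipitation** (`gen_precip`) is a first-order two-state Markov chain —
the simplest occurrence process with a controllable dry-run-length
distribution (geometric with parameter `p_dry_to_wet`). Defaults
(`p_wet_to_wet = 0.7`, `p_dry_to_wet = 0.15`, exponential depths of mean
8 mm) give a humid, strongly intermittent climate with a realistic supply
of >= 5-day dry spells over a multi-year record. The chain is
season-free: the real region concentrates dry spells in autumn/winter,
which this world does not emulate.

**Scenes** (`gen_scene_stack`) couple a per-pixel soil-moisture bucket
`S_{t+1} = clip(S_t + min(I_t, 1 - S_t) - lambda * S_t)` to the triangle:
`LST = T_d - S * (T_d - T_w)`, so ground-truth TVDI is exactly
`1 - S`. Leakage varies across pixels (uniform multiplier `1 +/- 0.4`) to
mimic crevice-density heterogeneity and to give each composite a scatter
with spread. Infiltration is generous (`0.1` bucket fill per mm, i.e. a
10 mm day refills an empty bucket): buckets re-saturate between spells,
so dry spells start from comparable moisture in every leakage scenario
and the within-spell decay rate — the quantity RWLR measures — is the
isolated signal. NDVI is static per pixel (+ optional jitter): the study
treats the vegetation pattern as fixed within the inversion, and the
forward model only needs the moisture signal in LST. No forward model is
claimed by the source method (only the inverse index), so these coupling
choices are the package's own.

**CZU tables** (`gen_czu_table`) draw from a recursive structural system
on unit-variance z-scores, then rescale affinely to field units (bedrock
CaO uniform over 4.8-74.2%, MAT ~ 15.5 +/- 2.5 °C, NPP ~ 640 +/- 260
g C m^-2 yr^-1, matching the emulated survey's printed ranges). Because
the system is built on z-scores, at `noise_sd = 1` the default betas
(`rwlr_brca = 0.85`, `npp_rwlr = -0.67`, `npp_mat = 0.32`,
`si_ca = -0.90`) *are* the population standardized path coefficients —
chosen so the NPP equation explains 55% of variance (0.67^2 + 0.32^2 ≈
0.55) with the dominant negative water-loss effect and weaker positive
temperature effect of the emulated system. AP, solar duration, PDSI,
soil N and the Mg/Fe/Al oxides are independent noise (they were
non-significant in the emulated analysis). The truth sidecar records both
the population standardized coefficients implied by any `noise_sd` and
the realized-sample standardized coefficients; the latter are what
equation-wise OLS recovers exactly as `noise_sd -> 0` (sample
standard-deviation ratios, not population ones, enter the standardized
estimate at finite n).

**Global grids** (`gen_global_grid`) plant a correlation contrast
directly: per pixel `z_ndvi = r * z_temp + sqrt(1 - r^2) * noise` with
`r` chosen by mask membership. Pixels are independent — real NDVI fields
are spatially autocorrelated, so a green type-I-error test here does
*not* establish calibration under spatial dependence (a known
limitation of the buffer-contrast design itself).

## Numerical and procedural choices

- **Edge fitting** (`fit_triangle_edges`) is per scatter, not per pixel:
  edge estimation needs the whole NDVI/LST space, and scene-level fitting
  is the standard triangle formulation. 20 equal-width NDVI bins over the
  observed range; per-bin extremes are *order statistics* (inverse-ECDF
  quantiles), so `edge_percentile = 1` is exactly the bin maximum and a
  0.95 trim discards points rather than interpolating — which keeps a
  noise-free fit bit-stable under trimming. Pixels with NDVI < 0.05 are
  excluded (bare-surface/water guard). Fits with fewer than two usable
  bins, or a dry edge not strictly above the wet edge over the fitted
  range, error out rather than return a nonsense triangle.
- **TVDI** values outside `[0, 1]` are clipped, not masked — the index is
  defined as bounded — and the clipped fraction is reported so an
  over-tight triangle is visible. The identity `TVDI = 1 - moisture` on
  noise-free scenes is asserted with the generator's true edges; edge
  *fitting* can only recover the planted lines when every bin contains
  both moisture extremes, so exact-recovery tests use a constructed
  scene with points on the lines, and generated-stack tests assert a
  valid (positive-separation) triangle instead.
- **RWLR aggregation**: the source formulation prints a sum of per-spell
  mean slopes but describes an average; the package defaults to the
  mean (a sum would confound the index with the site-varying spell
  count) and implements both. Slopes use consecutive valid composite
  pairs (all information; `endpoints` mode available); a spell needs at
  least 2 composites to contribute; a site with zero usable spells
  returns `NA`, distinct from a genuine zero.
- **AIC convention**: `n log(RSS/n) + 2(k + 2)`, constants dropped; it is
  recorded in every result and held fixed, so weights are unaffected
  (they are shift-invariant). Plain AIC, not AICc, mirroring the emulated
  analysis — a caveat at n = 23 that the user can override by ranking
  with their own criterion. The null model is included in the enumeration
  by default (a recorded choice, since it changes the weights). Main
  effects only; no interactions.
- **Path models** are manifest-variable and recursive; OLS per equation
  is the ML solution when exogenous covariances are free, and the
  chi-square compares the implied covariance `(I-B)^{-1} Psi (I-B)^{-T}`
  with the ML sample covariance via `(n-1) F_ML`. CFI uses the
  independence baseline; the RMSEA 90% interval inverts the noncentral
  chi-square cdf. Saturated models report chi-square 0 / CFI 1 with a
  "zero df" note. Exactly collinear (e.g. noise-free) data make the
  sample covariance singular: coefficients are still returned, fit
  indices become `NA` with an explanatory note, and the acceptance
  verdict is `NA` rather than a false pass. Si and Ca oxides are refused
  in a single model; two variants are the supported design. Residual
  covariances and modification-index additions are not implemented —
  base specs only.
- **Buffer zones** use an 8-connected structuring element by default
  (4-connected available). "Inner" defaults to the boundary-symmetric
  ring (mask minus erosion) so the contrast compares equal-width strips;
  `inner_mode = "full"` uses the whole carbonate body, since the
  original description is ambiguous. A desert screen drops pixels whose
  mean NDVI is below 0.1 before zoning. The rank-sum test is exact (no
  ties, both zones <= 20 pixels) and otherwise the tie-corrected normal
  approximation; zone means carry normal-approximation 95% CIs.
- **Pipeline** (`run_pipeline`) expands one master seed into per-stage
  seeds by a counter scheme, writes CSV/JSON artifacts plus an MD5
  manifest, and validates configs strictly (unknown keys are rejected
  with a nearest-key hint). Its TVDI stage defaults to fitting one
  triangle on the scatter pooled over composites: in the synthetic world
  a single post-rain composite can collapse to a line (every pixel
  equally wet) and a per-scene fit would rightly error. Pooling is a
  stability choice for the synthetic demonstration, not a claim about
  how the real composites should be processed; `edges_mode = "truth"`
  and per-scene fitting remain available.

Grid/stack serialization is plain text (CSV values + JSON geometry
sidecars): this build targets an environment without GeoTIFF/NetCDF
libraries, and the analysis itself only needs in-memory arrays.

## What a green test establishes — and what it does not

The test suite proves internal correctness (oracle agreement for spell
detection, enumeration and ranking; closed-form TVDI and effect
decompositions; exact morphology counts; type-I error calibration under
the planted null) and mechanism coherence (higher leakage => strictly
higher RWLR => lower synthetic NPP; planted path signs recovered at
n = 23). It does not — cannot — reproduce the real region's numbers:
those depend on unreleased station, satellite and field archives, and no
numeric acceptance targets are defined for this build. Nothing in this
vignette states an empirical result that the tests or the acceptance
script do not themselves compute.

## A worked example

```{r example, eval = FALSE}
library(rwlr)

p <- gen_precip(1825, seed = 1)                       # 5 years of daily rain
st <- gen_scene_stack(p, leakage = 0.05, noise_sd = 0, seed = 2)
scenes <- stack_tvdi(st, edges = "truth")
series <- czu_mean_tvdi(scenes, disc = list(x = 10, y = 10, radius = 7))

spells <- detect_dry_spells(p)
spn <- data.frame(start_date = as.numeric(spells$start_date - p$date[1]) + 1,
                  end_date = as.numeric(spells$end_date - p$date[1]) + 1)
compute_rwlr(series, spn)

tab <- gen_czu_table(n = 23, seed = 3)
all_subsets_rank(tab$npp,
                 as.matrix(tab[, c("rwlr", "soil_n", "sd", "ap", "mat", "pdsi")]))$rvi
fit_path_model(tab, c("npp ~ rwlr + mat", "rwlr ~ br_ca"))
```
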
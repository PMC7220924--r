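# rwlr

Statistical machinery linking **bedrock geochemistry** to **vegetation
productivity** in karst landscapes, via the **Regolith Water Loss Rate
(RWLR)** — the rate at which a satellite dryness index rises during
rain-free periods.

Karst terrain sits on soluble carbonate bedrock. Dissolution crevices
drain water out of the regolith, so sites on Ca-rich bedrock dry faster
during dry spells than sites on Si-rich bedrock — and, the hypothesis
goes, support lower net primary productivity (NPP). The package
implements the full inference chain used to test this at regional scale,
plus synthetic-data generators so every stage is testable without
station or satellite archives:

1. **TVDI triangle method** — fit dry/wet edges `T_d = a + b·NDVI`,
   `T_w = c + d·NDVI` to the NDVI/surface-temperature scatter and compute
   `TVDI = (T_obs − T_w)/(T_d − T_w)` per pixel
   (`fit_triangle_edges`, `compute_tvdi`, `resample_nearest`).
2. **Dry spells & RWLR** — detect runs of ≥ 5 rain-free days in daily
   precipitation, average the within-spell TVDI slope per critical-zone
   unit (a 20-km disc around a station), scale by 100
   (`detect_dry_spells`, `czu_mean_tvdi`, `compute_rwlr`, `filter_sites`).
3. **Variable importance** — all-subsets OLS, AIC, Akaike weights
   `w ∝ exp(−ΔAIC/2)`, the 95% cumulative-weight best subset, relative
   variable importance (RVI), and a `|r| > 0.70` collinearity screen with
   the Si/Ca two-subset split (`all_subsets_rank`, `collinearity_screen`).
4. **Path models** — recursive manifest-variable SEMs (bedrock → RWLR →
   NPP, with temperature), ML chi-square, CFI, RMSEA with 90% CI, total
   effects as sums of products of standardized coefficients
   (`fit_path_model`, `total_effects`, `accept_model`).
5. **Karst temperature signal** — per-pixel growing-season (Apr–Sep)
   NDVI–temperature correlation, morphological buffer rings around a
   carbonate mask, Mann–Whitney contrast (`karst_signal`, `buffer_zones`,
   `compare_zones`).
6. **Generators & pipeline** — Markov-chain precipitation, a per-pixel
   soil-moisture bucket scene model whose ground-truth TVDI is
   `1 − moisture`, a structured covariate table with known standardized
   path coefficients, planted-correlation global grids, and an
   orchestrated, seeded, checksummed pipeline (`gen_*`, `run_pipeline`).

## Worked example

```r
library(rwlr)

p      <- gen_precip(1825, seed = 1)                     # 5 y of daily rain
st     <- gen_scene_stack(p, leakage = 0.05, noise_sd = 0, seed = 2)
scenes <- stack_tvdi(st, edges = "truth")
series <- czu_mean_tvdi(scenes, disc = list(x = 10, y = 10, radius = 7))

spells <- detect_dry_spells(p)                           # 104 spells >= 5 d
spn <- data.frame(start_date = as.numeric(spells$start_date - p$date[1]) + 1,
                  end_date   = as.numeric(spells$end_date   - p$date[1]) + 1)
compute_rwlr(series, spn)
#> RWLR result: rwlr = 4.487581 (aggregate = mean, 58 spells used)
```

58 of the 104 spells contain ≥ 2 usable composites; the zone-mean TVDI
climbs by 0.045/day on average within them, i.e. RWLR ≈ 4.5 on the ×100
scale — the faster the regolith drains, the larger this number.

```r
tab <- gen_czu_table(n = 23, seed = 3)     # planted: Ca -> RWLR -> NPP
round(all_subsets_rank(tab$npp,
  as.matrix(tab[, c("rwlr","soil_n","sd","ap","mat","pdsi")]))$rvi, 3)
#>   rwlr soil_n     sd     ap    mat   pdsi
#>  0.958  0.518  0.251  0.270  0.671  0.270

fit_path_model(tab, c("npp ~ rwlr + mat", "rwlr ~ br_ca"))
#> Recursive path model (n = 23): chisq = 3.083 on 2 df (p = 0.214),
#>   CFI = 0.978, RMSEA = 0.157 [0.000, 0.480]
#> ACCEPTED
#>    from   to      est est_std       p
#> 1  rwlr  npp -102.978  -0.768 5.2e-05
#> 2   mat  npp   27.595   0.242 1.2e-01
#> 3 br_ca rwlr    0.077   0.882 2.8e-08
#> R2: npp = 0.570, rwlr = 0.777
```

RWLR tops the importance ranking (RVI 0.96) and the path model recovers
the planted sign pattern — bedrock Ca raises the water loss rate
(+0.88), which depresses productivity (−0.77), while temperature helps
(+0.24) — and passes the chi-square/CFI/RMSEA acceptance rule.

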
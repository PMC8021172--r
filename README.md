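# landhab

Land-use change simulation and habitat-quality assessment on categorical
raster landscapes.

`landhab` is for landscape ecologists and land-use planners who want to ask:
*if land use keeps changing the way it has — or the way a policy would steer
it — what happens to habitat?* It implements the widely used coupling of two
models as one reproducible, tested R pipeline:

1. **CA–Markov land-use projection.** A transition probability matrix
   `P` is estimated by cross-tabulating two dated land-use maps
   (`p_ij = A_ij / Σ_j A_ij`, rows = origin class) and projected as a Markov
   chain, `S(t+1) = Pᵀ S(t)`. A cellular-automata step then allocates the
   projected class areas in space, ranking cells by
   `suitability × neighbourhood density` (5 × 5 filter) under per-scenario
   constraints (growth rates, forbidden transitions, protected classes).
   Suitability surfaces come from per-class logistic regressions,
   `logit P_i = β₀ + β₁x₁ + … + βₙxₙ`, on driver layers. Simulated maps are
   validated against observations with the kappa coefficient
   `(P_o − P_c)/(1 − P_c)`.
2. **Habitat-quality scoring.** Per-cell degradation accumulates
   distance-decayed threats,
   `D_x = Σ_r Σ_y (w_r/Σw_r) · r_y · i_r(d_xy) · β_x · S_jr`, with linear or
   exponential (`exp(−2.99 d/d_max)`) decay kernels, and quality applies a
   half-saturation transform `Q_x = H_j · k^z/(D_x^z + k^z)` (`z = 2.5`,
   `k` = half the maximum baseline degradation). Quality is graded I (best,
   0.8–1) through V (worst, 0–0.2) and grade changes between dates or
   scenarios are accounted as km² change matrices.

Three policy scenarios ship as editable YAML: fast urban growth (urban land
+5.68 %/yr), farmland conservation (+1.45 %/yr, farmland protected) and
ecological conservation (urban growth halted, woodland/grassland/water
protected). Default threat and sensitivity tables for the eight-class
legend (farmland, woodland, grassland, water, urban, rural residential,
industrial/traffic, barren) are packaged. A synthetic-landscape module
generates landscapes, driver stacks and temporal pairs with known ground
truth, so the whole chain is testable without proprietary rasters.

Rasters are plain-text Esri ASCII grids (`.asc`); everything is matrix-based
with no GIS stack required.

## Worked example

```r
library(landhab)

# a synthetic 100 x 100 km farmland-dominated landscape
lu <- generate_landscape(c(100, 100), seed = 42, autocorr = 4)
area_summary(lu)
#>                class code area_km2 pct
#> 1           farmland    1     6800  68
#> 2           woodland    2      700   7
#> ...
#> 6  rural_residential    6     1100  11

# habitat quality under the packaged threat/sensitivity tables
sens <- default_sensitivity()
D <- degradation(lu, default_threats(), sens)
k <- half_saturation(D)
Q <- habitat_quality(D, lu, sens, k)
sprintf("k = %.3f, mean habitat quality = %.4f", k, mean_quality(Q))
#> "k = 4.611, mean habitat quality = 0.3084"
grade(Q)
#> grade_map (I best ... V worst):
#>    I   II  III   IV    V
#>  373  394  737 6879 1617
```

The mean quality 0.31 and the dominance of grade IV reflect a
farmland-dominated landscape: farmland has intrinsic suitability 0.3, and
built-up cells (quality 0) pull the mean down while woodland/water patches
score high.

The full pipeline — transition estimation, suitability atlas, hindcast
validation, three scenario projections, quality scoring and grade-change
accounting — runs from one config:

```r
cfg <- make_fixture("huaihe-mini", tempfile(), seed = 42)
res <- run_pipeline(cfg)
res$kappa
#> 0.9144            # hindcast agreement, simulated vs observed later map
sapply(res$scenarios, function(s) s$mean_quality)
#> fast_urban_growth   farmland_conservation   ecological_conservation
#>            0.2808                  0.2967                    0.3089
mean_quality(res$baseline$Q)
#> 0.3003
```

Mean habitat quality falls under fast urban growth, falls slightly under
farmland conservation and rises under ecological conservation — the
qualitative signature this model coupling exists to quantify. Output
rasters, CSV matrices, a JSON run manifest and a log are written to the
config's output directory.

A thin command-line wrapper over the same functions is installed at
`inst/cli/landhab.R` (subcommands `simulate`, `validate`, `hq`,
`pipeline`).

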
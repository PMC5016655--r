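# dungdist

Integrated distance sampling of ungulate dung surveys.

`dungdist` is an R package for estimating the density, abundance and
habitat selection of sympatric desert ungulates (a scimitar-horned-oryx /
dorcas-gazelle style two-species system) from **indirect** strip-transect
surveys of fecal pellet groups. It is aimed at ecologists analyzing paired
wadi/plain transect designs where animals are hard to count directly and
standing dung integrates habitat use over the pellets' long persistence in
arid climates.

## What it computes

The core is an **integrated likelihood** that jointly estimates, from
distance-binned pellet counts:

* a global half-normal detection function
  `g(y) = exp(-y² / 2σ²_det)` over three perpendicular-distance
  intervals (0–1.33, 1.33–2.67, 2.67–4 m), and
* a Poisson density model with log link,
  `log D_j = β₀ + x_jᵀβ + b_s(j)`, `b_s ~ N(0, σ²_b)`,
  where `x_j` are transect habitat covariates (rock cover, plant species
  richness, vegetation structure, biomass, gradients, predator sign) and
  `b_s` is a wadi-system random intercept, integrated out by adaptive
  Gauss–Hermite quadrature.

Around that core the package provides: event bookkeeping with midden
exclusion; AICc candidate sets built from univariate screening plus
pairwise combinations with interactions; Akaike weights, 95% confidence
sets, predictor importance and model-averaged coefficients; conversion of
pellet-group density to animal density and abundance through defecation
and decay rates (`D_dung = D_animal · r · T`); and habitat partitioning —
Ward clustering of transects, Manly standardized selection ratios `B_i`,
key-resource flags (`B_i ≥ 0.5`), Shannon–Wiener diversity of habitat use,
and midrank/exact Wilcoxon wadi-plain contrasts. A synthetic survey
generator reproduces the full study design (18 pairs, 8 wadi systems,
200 × 8 m strips, 11 quadrats per transect) so the whole chain is testable
end to end.

## Worked example

```r
library(dungdist)

ds <- simulate_survey(seed = 1)
ds
#> Pellet-group survey dataset
#>   transects: 36 (18 pairs, 8 wadi systems)
#>   pellet events: 1123 recorded (75 middens)
#>     oryx: 939 recorded, 13 middens
#>     gazelle: 184 recorded, 62 middens

fit_integrated(ds, integrated_spec("oryx", ~ richness + rock_cover))
#> Integrated model [oryx]: ~ richness + rock_cover
#>   logLik -242.877 | k = 5 | AICc 497.755
#> (Intercept)    richness  rock_cover     sigma_b   sigma_det
#>     -4.3202      0.2156     -0.0414      0.3279      1.5278
```

The fit recovers the generator's truth (richness effect 0.208 per species,
rock-cover effect −0.031 per %, `σ_det` 1.5 m, `σ_b` 0.3): oryx
pellet-group density rises with plant species richness and falls with rock
cover, and detection falls to `exp(-1/2) ≈ 0.61` at 1.5 m from the line.
`k = 5` counts the intercept, two covariates, `σ_b` and `σ_det`; AICc
compares this model against the rest of the candidate set
(`build_candidates()`, `fit_candidates()`, `model_table()`).

Selection ratios summarize habitat use: a species using the wadi with
standardized ratio 0.74 against 0.26 for the plain has habitat-use
diversity

```r
shannon_diversity(selection_ratio(c(wadi = 0.74, plain = 0.26)))
#> [1] 0.573
```

i.e. fairly specialized use (the maximum for two habitats is
`log 2 ≈ 0.693`). `run_pipeline(pipeline_config(seed = 1))` chains every
stage — simulation or CSV input, midden filtering, candidate fitting,
model averaging, abundance conversion, and both habitat classifications —
into one reproducible report bundle.

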
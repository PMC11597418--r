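# paddynr

Nitrogen runoff loss from flooded rice fields under green-manure
fertilizer substitution.

## The problem

Rice paddies in the middle and lower Yangtze region lose substantial
nitrogen to surface water: after each fertilization the flood-water N
concentration spikes, and any runoff event — a storm overflowing the bund,
or managed drainage — carries that nitrogen off the field, feeding
nonpoint-source pollution. Winter-grown Chinese milk vetch (a leguminous
green manure, GM) incorporated before transplanting can substitute part of
the mineral fertilizer; the question is how much runoff N that saves, and
whether the saving persists across wet, normal and dry years.

`paddynr` is an R package for agronomists and water-quality modellers that
implements the full computational chain needed to answer this: a daily
paddy water balance with threshold runoff, lumped surface-water nitrogen
dynamics under fertilizer / green-manure / straw management, runoff-loss
accounting, trial-and-error calibration with standard evaluation indices,
stochastic weather generation, and multi-decade scenario analysis
stratified by rainfall year type. A synthetic-data module generates
realistic site configurations and noisy "field observations", so
calibration, validation and scenarios are fully testable without any
external data.

## The model in brief

**Water.** Daily ponding depth follows
`Pd_n = Pd_{n-1} + Prem_n + Irri_n − ET_n − Inf_n − Rf_n`,
with runoff `Rf_n = max(0, Pd_n − Pd_max)` (threshold overflow at the bund)
plus forced drainage during mid-season and pre-harvest drying windows.
ET is Hargreaves–Samani (or a supplied ET0 column) scaled by a crop
coefficient; percolation is a constant calibratable rate.

**Nitrogen.** Four surface-water pools (NH4-N, NO3-N, DON, PN) carry
per-area masses; concentrations derive from mass and depth
(`mg/L = 100 · kg/ha ÷ mm`), composite forms by the difference method
(DIN = NH4 + NO3, DTN = DIN + DON, TN = DTN + PN). Pools decay by exact
first-order exponential steps; fertilizer adds `f_surf` of its N to the
NH4 pool on the application day; organic inputs mineralize first-order
from incorporation, with straw additionally immobilizing mineral N.
Runoff export is fully mixed: `loss (kg/ha) = conc (mg/L) · Rf (mm) · 10⁻²`.

**Evaluation.** RMSE, Nash–Sutcliffe efficiency `E` and the index of
agreement `d`; calibration is seeded coordinate descent on refined grids,
fitted on the conventional treatment and validated on the others.

**Weather and scenarios.** A monthly two-state first-order Markov chain
with two-parameter Gamma wet-day amounts generates any number of years;
years are classified by the drought index `DI = (P − A)/σ` (wet if
`DI > 0.35`, dry if `DI < −0.35`). Four treatments — FR (conventional),
FRS (+straw), MR (GM, 40% less fertilizer), MRS (GM + straw, 40% less) —
run over shared weather, and losses are summarized by treatment × year
type with a seeded paired bootstrap for significance.

## Worked example

```r
library(paddynr)

site <- make_site("default")            # Nanjing-like synthetic station
weather <- generate_weather(site$weather_params, n_years = 1, seed = 7,
                            start_year = 2023)
season <- simulate_season(weather, treatment_schedule(site, "FR"),
                          site$soil, site$policy, site$rates, site$latitude)
season
#> <paddy_season> FR: 2023-06-11 -> 2023-10-01 (113 days)
#>   runoff: 213.3 mm in 6 event(s)
#>   TN loss: 8.725 kg N/ha (DIN 5.252, DON 2.909, PN 0.564)
```

One 113-day season under conventional fertilization (200 kg N/ha at a 6:4
basal:tillering split) produced 213 mm of runoff in 6 events and lost
8.7 kg N/ha as total N, of which 5.3 kg was dissolved inorganic N — the
form green manure substitution targets. Scenario analysis over shared
weather shows the treatment and year-type structure:

```r
w10 <- generate_weather(site$weather_params, n_years = 10, seed = 7)
losses <- run_scenarios(site, w10)
classes <- drought_index(season_rainfall(w10, site$transplant, site$harvest))
summ <- summarize_by_year_type(losses, classes, n_boot = 500, seed = 1)
summ$by_group
#> # A tibble: 12 × 7
#>    treatment label  n_years mean_tn sd_tn mean_din sd_din
#>    <fct>     <fct>    <int>   <dbl> <dbl>    <dbl>  <dbl>
#>  1 FR        dry          5    7.83 0.696     4.50  0.746
#>  2 FR        normal       3   12.1  3.76      7.92  3.44
#>  3 FR        wet          2    9.85 1.36      5.67  0.649
#>  4 FRS       dry          5    7.56 0.660     4.06  0.725
#>  ...
#> 10 MRS       dry          5    6.87 0.422     3.42  0.387
#> 11 MRS       normal       3   10.3  2.15      6.07  1.93
#> 12 MRS       wet          2    8.77 1.90      4.41  1.23
```

Within every year type the mean losses order FR > FRS > MR > MRS: straw
return trims losses slightly (microbial immobilization of mineral N), and
the green-manure treatments cut them further by replacing 40% of the
fertilizer. `autoplot(summ)` draws the grouped bar chart;
`tidy(summ)` returns the reduction table with bootstrap significance flags.
(Ten years is illustrative; with 50 years each class holds ~15 years and
the wet > normal > dry ordering of means emerges as well.)

The full chain — synthetic observations, calibration, 50-year scenarios,
output tables with provenance headers — is one call:

```r
res <- run_pipeline("out/", profile = "default", seed = 1)
tidy(res$fit)      # fitted parameters with bounds
res$summary        # scenario summary by year type
```

## Documentation

The vignette `vignettes/paddynr-methods.Rmd` documents the model equations
and assumptions, every default parameter with units and rationale, the
synthetic-data generator's scope, and known limitations.
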
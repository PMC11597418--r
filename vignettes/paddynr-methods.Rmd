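---
title: "Model and methods behind paddynr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind paddynr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paddynr)
```

`paddynr` simulates how nitrogen leaves a flooded rice field with surface
runoff, and how winter green manure (Chinese milk vetch) combined with a 40%
cut in mineral fertilizer changes that loss. This vignette describes the
model, its assumptions, the parameters that matter, the design choices that
were genuinely open, and what the synthetic-data generator does and does not
emulate.

## 1. Ponding-water balance

The field is represented as a single fully mixed pond. The depth `Pd`
(mm) advances daily:

```
Pd_n = Pd_{n-1} + Prem_n + Irri_n - ET_n - Inf_n - Rf_n
```

with precipitation `Prem`, irrigation `Irri`, crop evapotranspiration `ET`,
percolation `Inf` and runoff `Rf`, all in mm per day. Runoff is threshold
overflow: water above the bund height `Pd_max` spills. Because only the
daily sum is defined by this balance, the within-day order of fluxes is a
design choice that affects runoff totals; `paddynr` applies, in order: rain,
the irrigation decision (so management reacts to same-day rain), ET,
percolation (each capped at the available water, so the depth can never go
negative), then overflow. During management drainage windows (mid-season
drying, pre-harvest drying) irrigation is suppressed and the pond is
force-drained; the drained volume is reported as runoff, since at field
scale both leave over the same outlet.

Three simplifications relative to a full soil-column model:

* **Percolation** is a constant daily rate under ponding (unit-gradient
  saturated flow). A Richards/Green-Ampt treatment of the unsaturated zone
  is deliberately out of scope; only the ponded case matters for runoff, and
  the rate is a calibration parameter.
* **Evapotranspiration** uses a supplied reference-ET column when present
  and otherwise the Hargreaves–Samani estimate from the diurnal temperature
  range, latitude and day of year. A Penman–Monteith computation needs
  humidity, wind and radiation, which daily precipitation/temperature
  records usually lack. Actual ET is `kc × ET0` with a three-phase crop
  coefficient schedule (defaults 1.05 / 1.20 / 0.90).
* **Irrigation** refills to `pd_target` whenever the depth falls below
  `pd_lower`, with unlimited supply.

The budget closes exactly by construction; `simulate_water_season()` and
`simulate_season()` report the residual, and the test suite asserts it below
10^-9 mm per season.

## 2. Surface-water nitrogen pools

Runoff loss depends only on the surface-water concentration at the moment of
an event, so the package models the four measured pools directly as per-area
masses (kg N/ha): NH4-N, NO3-N, dissolved organic N (DON) and particulate N
(PN). Composite forms follow the difference method: DIN = NH4 + NO3,
DTN = DIN + DON, TN = DTN + PN. Concentration (mg/L) is always *derived*
from mass and the current depth (`conc = 100 × mass / Pd`), never integrated
directly — this makes dilution by rain and concentration by evaporation
exact and keeps the mass balance closed.

Each pool decays by an exact daily exponential step with a lumped
first-order rate: `k_nh4` aggregates ammonia volatilization, nitrification,
crop uptake and adsorption; a fraction `nitrif_frac` of the NH4 removal is
credited to the NO3 pool. `k_no3` aggregates denitrification, uptake and
leaching (fast in an anoxic flooded soil, default 1.2/day); `k_don` is
microbial DON turnover; `k_pn` is particle settling. A soil
convection–dispersion/organic-turnover model is intentionally replaced by
this calibratable lumped system.

Inputs to the pools:

* **Mineral fertilizer.** On the application day a fraction `f_surf`
  (default 0.3 for broadcast urea, a calibration parameter) of the applied N
  enters the NH4 pool — urea is assumed hydrolyzed within the daily step —
  and a small fraction `f_pn` (default 0.02) enters PN; the rest goes to the
  soil store outside the surface system. Application onto a dry or draining
  field is deferred to the next day that retains a pond, with a warning.
* **Organic inputs** (green manure, straw) mineralize first-order from
  their incorporation day. Only a fraction `f_surf = 0.10` of the release
  enters the flood water (mineralization happens inside the soil matrix,
  unlike urea broadcast onto the water), split between NH4 and DON
  (`nh4_frac` 0.8 for the low-C:N legume, 0.6 for straw). Incorporation
  also adds a small PN pulse. High-C:N straw additionally *immobilizes*
  mineral N while it decomposes: an extra NH4 removal rate
  `k_immob × exp(-k_min t)` proportional to the remaining residue. Green
  manure is incorporated at full flowering, about 30 days before
  transplanting, so most of its N (about 78% at `k_min = 0.05`/day) has
  already mineralized into the soil before the field is flooded.
* **Background fluxes.** Soil organic matter mineralization feeds the flood
  water at a constant `base_min = 0.15` kg N/ha/day while ponded, and
  rainfall carries atmospheric wet deposition at `rain_conc = 2.5` mg N/L
  (split 60/20/20 NH4/NO3/DON). Regional observations put rainwater TN at
  roughly 1.5–4 mg/L — some 25–40 kg N/ha/yr — so deposition is a
  first-order term in this system, and it is what couples nitrogen export to
  rainfall independently of treatment.

Runoff export assumes full mixing: an event removes the fraction
`Rf / Pd_pre` of every pool, equivalently `loss = conc × Rf × 10⁻²`
kg N/ha. The nitrogen budget (inputs − decay − runoff = Δstorage) is
reported per season and asserted below 10^-9 kg N/ha.

## 3. Model evaluation and calibration

Three standard indices compare simulated (`P`) to observed (`O`) series:
RMSE, Nash–Sutcliffe efficiency `E`, and the index of agreement `d`
(bounded in [0, 1]). Undefined cases (constant observations, zero potential
error) raise errors rather than returning sentinels.

"Trial and error" calibration is operationalized as deterministic
coordinate descent on successively refined grids: each parameter in turn
moves to the best of `n_grid` equally spaced candidates, sweeps repeat until
stable, then the range shrinks around the incumbent (`n_refine` levels,
shrink factor 0.5). The objective is the mean of per-series RMSEs, each
normalized by the observed standard deviation, over ponding depth, runoff,
and TN/DIN concentrations; weights are configurable. Simulated values are
extracted at the observation timestamps before computing metrics. In a
daily-step model the "day 0, before fertilization" field sample corresponds
to the previous end-of-day state, and is aligned accordingly. The protocol
mirrors field practice: parameters are fitted on the conventional (FR)
treatment and validated unchanged on the others via
`simulation_metrics()`.

Grid search is not a gradient method by intent: it is bounded, reproducible
(same spec and seed give identical fits), and robust to the discontinuous
response surface produced by threshold runoff.

## 4. Stochastic weather and year classification

Daily precipitation is generated by a two-state first-order Markov chain
(monthly transition probabilities `p_wd`, `p_ww`) with wet-day amounts drawn
from a monthly two-parameter Gamma distribution offset by the wet-day
threshold (0.1 mm; the threshold itself counts as wet). Parameters are
fitted per calendar month as empirical conditional frequencies and
method-of-moments Gamma estimates on threshold excesses (maximum likelihood
optional); months with fewer than five wet days, or with an undefined
transition frequency, fall back to the pooled fit and are flagged.
Temperatures are minimal plumbing — monthly normal draws used only for ET.
Generation is bit-reproducible given a seed.

Years are classified by the drought index `DI = (P − A)/σ`, where `P` is
the rainfall of the classification window and `A`, `σ` are the mean and
standard deviation over the classified set itself (no external
climatology). `DI > 0.35` is wet, `DI < −0.35` dry, boundaries inclusive in
normal. The window is the rice growing season by default — the loss-relevant
window — with a calendar-year option, since the defining phrase for the
yearly rainfall is ambiguous between the two.

## 5. Treatments and scenario analysis

The four treatments are FR (conventional fertilization, the winter-fallow
baseline), FRS (plus straw return), MR (green manure with a 40% fertilizer
cut) and MRS (green manure plus straw with the cut). FRS/MRS differ from
FR/MR only through the straw organic input. All treatments share the same
weather realization within a year (paired design), so per-year treatment
contrasts contain no weather noise; because the pool system is monotone in
its inputs, the orderings FR > FRS > MR > MRS for DIN and TN hold
deterministically year by year.

Group comparisons by year type use a seeded year-level paired bootstrap of
the within-year differences (B = 2000) with Holm correction at α = 0.05 —
distribution-free, reproducible, and named in the output.

## 6. The synthetic site: what it emulates, and what it does not

No field observations are distributed with the package, so
`make_site()` defines synthetic stations carrying the published crop
calendars, conventional N rates and split ratios (Gaoan 150 kg N/ha at 6:4;
Jingzhou 165 at 7:2:1; Nanjing 200 at 6:4; Chizhou 192 at 11:7:2 — for
double-cropping Gaoan only the early-rice season is represented). The
`default` profile mirrors Nanjing with fixed canonical parameters
(`perc_rate` 8 mm/day, `k_nh4` 0.35/day, `f_surf` 0.3); named stations draw
their hydraulic and rate parameters from plausible ranges under a seed.

The water-management and rainfall parameterization was chosen once, on
realism grounds, and frozen:

* bund height `pd_max` 100 mm with continuous-flooding irrigation
  (trigger 50 mm, refill 70 mm). A bund at the 250 mm top of the observed
  depth envelope would make storm overflow essentially impossible for a pond
  managed at 60–70 mm, leaving drainage as the only loss pathway and erasing
  the rainfall signal; 100 mm is a typical bund freeboard, and `pd_max` is a
  per-site calibration parameter in any case.
* mid-season drying at DAT 27–33, directly after the DAT-20 tillering
  top-dressing (a documented, deterministic N-export pathway), and the last
  10 days pre-harvest.
* monthly Gamma scales of 8–26 mm (summer-peaked, shape 0.65–0.70), giving
  ~1100–1700 mm/yr, 650–1000 mm growing-season totals, and occasional
  100+ mm storm days — Yangtze monsoon characteristics.

`generate_observations()` runs the simulator under the site truth and emits
a field campaign: daily ponding depth, per-event runoff, and TN/DIN/NH4
concentrations sampled the day before each fertilization and on days 1, 3,
5, 7 and 10 after it. Noise is multiplicative lognormal (mean-one; relative
sd 5% depth, 10% concentration, 10% runoff). All N forms of one day come
from one composite water sample, so the sampling error is shared within a
day — which is why form ratios such as NH4/DIN survive the noise — while
depth and runoff readings err independently. Lognormal noise cannot
produce negative observations.

What the generator does *not* emulate: analyzer-specific artifacts,
within-day concentration dynamics (the model is daily), spatial
heterogeneity between replicate plots, soil-profile N transport, and yield.
Passing the recovery tests therefore shows the estimation machinery is
self-consistent at field-realistic noise, not that the lumped-rate model is
structurally correct for any particular real site.

## 7. Numerical choices and edge cases

* Pool updates are exact exponential steps; no ODE solver error.
* Runoff export is computed as a mass fraction `min(1, Rf/Pd_pre)`, so a
  full drain empties the pools exactly (no floating-point negatives).
* ET and percolation are capped at available water; depth never goes
  negative.
* Concentrations are `NA` when the pond is empty; masses persist.
* Degenerate fits raise errors: all-dry records, constant observations,
  zero variance in wet-day amounts (represented as a near-degenerate Gamma
  preserving the mean when a month has constant amounts).
* All randomness flows from explicit integer seeds through `withr`, leaving
  the caller's RNG state untouched.

## 8. Problem sizes and known limitations

The bundled analyses use one season (~113 days) for calibration against
~150 observation points, 200 generated years for weather-recovery checks,
and 50 paired years × 4 treatments for scenarios; these sizes give stable
estimates while keeping any single run in seconds to tens of seconds.

Limitations worth knowing:

* Year-type contrasts are sample means over ~15 years per class; with
  event-driven losses their ordering (wet > normal > dry) is reproduced in
  the large majority of 50-year realizations but can invert for rare
  weather draws in which, e.g., the normal-class years happen to catch more
  fertilization-week storms than the wet-class years. This is sampling
  noise, not a model defect.
* Because deposition- and mineralization-driven exports are
  treatment-independent, *relative* reductions are diluted where rainfall
  is high; percent reductions here are conservative in wet years.
* The winter-fallow baseline is represented by FR/FRS (absence of the green
  manure input); no separate unfertilized fallow is simulated.
* Irrigation supply is unlimited; drought years constrain runoff, not
  irrigation.

## 9. A worked example

```{r example, fig.width = 7, fig.height = 4}
site <- make_site("default")
weather <- generate_weather(site$weather_params, n_years = 1, seed = 7,
                            start_year = 2023)
season <- simulate_season(weather, treatment_schedule(site, "FR"),
                          site$soil, site$policy, site$rates, site$latitude)
glance(season)
plot_season_nitrogen(season)
```

```{r scenario, fig.width = 7, fig.height = 4}
w10 <- generate_weather(site$weather_params, n_years = 10, seed = 7)
losses <- run_scenarios(site, w10)
classes <- drought_index(season_rainfall(w10, site$transplant, site$harvest))
summ <- summarize_by_year_type(losses, classes, n_boot = 500, seed = 1)
summ$by_group
autoplot(summ)
```
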
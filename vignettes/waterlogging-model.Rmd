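---
title: "Modelling excess-water stress in soybean: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling excess-water stress in soybean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soyflood)
```

## The problem

Most cropping-system models treat water stress as a one-sided problem:
too little water slows the crop down. Soybean, however, is also highly
sensitive to *excess* water. Flooding and perched water tables cut root-zone
oxygen, which depresses canopy photosynthesis, slows or redirects
phenological development, and — most distinctively for a legume — shuts
down symbiotic N~2~ fixation, the crop's dominant nitrogen source. The
damage depends strongly on *when* the water arrives: floods around early
flowering (R2) are far more damaging than floods of the same length at the
fourth-leaf stage (V4).

`soyflood` is a desk-scale, daily time-step soybean simulator built around
stage-dependent "oxygen deficit" stress multipliers for photosynthesis,
development and N fixation, layered on top of the classical supply/demand
drought stress, a tipping-bucket soil water balance with perched water-table
tracking, and a minimal but complete crop carbon/nitrogen economy. It ships
a stochastic weather generator and synthetic soil/cultivar fixtures so that
flooding experiments, parameter sensitivity analyses and climate-scenario
risk analyses run entirely offline.

## The stress framework

All moisture stresses are 0–1 multipliers defined by piecewise-linear
"x/y pairs" (`piecewise_multiplier()`), where x is a moisture predictor and
y the factor applied to a process rate. Predictors are anchored at field
capacity (x = 0, no stress) and saturation (x = 1, full stress):

* **Drought** (`drought_photo_stress()`): `min(1, supply/demand)`, where
  supply sums plant-available water over the unsaturated root zone
  (kl-limited per layer) and demand converts potential growth to water use
  through a transpiration-efficiency coefficient normalised by daytime
  vapour-pressure deficit.
* **`oxdef_photo`** — radiation-use-efficiency multiplier over the fraction
  of the root system below the water table. Default pairs
  `{(0,1), (0.8,1), (1,0.75)}`: no effect until 80% of the roots are
  submerged, then a 25% cut at full submergence (vegetative), consistent
  with published 48-h V4 flooding responses of 16–33%.
* **`oxdef_pheno`** — development-rate multiplier over the same predictor;
  default `{(0,1), (0.8,1), (1,0.4)}`, so a fully submerged vegetative crop
  accumulates thermal time at 40% of potential.
* **`oxdef_fix`** — fixation multiplier over the water-filled-pore-space
  excess fraction of the top 0.45 m (the nodule zone; the depth is user
  configurable). Default `{(0,1), (0.5,1), (1,0)}`: inert until the zone is
  halfway between field capacity and saturation, zero at saturation. The
  saturated anchor is *pinned*: no stage factor or sensitivity perturbation
  can lift it, because fixation stops in saturated soil.

**Stage severity.** Waterlogging is more damaging during reproductive
stages. A severity factor multiplies the stress depth `1 - y`, ramping
linearly from 1 before R1 to 1.2 at pod-fill onset for photosynthesis and
fixation. At full submergence this takes the photosynthesis multiplier from
0.75 (vegetative) to 0.70 (reproductive), matching the published 22–32%
reproductive-stage reduction range.

**Phenology at reproductive stages.** The development stall is *relieved*
(not amplified) after R1: `pheno_rep_relief = 0.4` scales the stall depth
down as the crop passes from R1 to R3. This was a deliberate design
departure from a uniform severity ramp. With a uniform ramp, a long
reproductive flood stalls the thermal-time clock, which merely postpones
the (thermal-time-anchored) pod-fill window instead of destroying it — in
simulation, 7-day R2 floods could then out-yield 2-day floods, the opposite
of every field observation. Physiologically, flooded reproductive soybeans
continue (and often hasten) development towards maturity while their
assimilation collapses; observed maturity delays from reproductive floods
are modest even when yield losses exceed 50%. The vegetative stall is kept
at full depth, which is what delays maturity after V4 floods.

**Post-flood recovery.** Floods ending before R1 leave no trace: the plant
recovers fully. Floods at or after R1 leave a persistent depression: until
maturity the photosynthesis and fixation multipliers are capped at
`1 - p × (1 - m)`, where `m` is the worst multiplier reached during the
flood and `p = recovery_persistence = 0.5`.

## Soil water: tipping bucket with a perched table

The profile is a stack of layers (`ll15 < dul < sat`), stepped daily:
ponded rain infiltrates top-down to saturation (runoff only beyond the
whole profile's pore space); water above `dul` cascades downward at up to
`ks` per layer, with bottom-layer outflow as deep drainage; remaining
excess then pools on the impeding bottom of the profile, so water tables
rise from the bottom up and recede from the top — the standard bucket idiom
for perched tables. The table is diagnosed as the top of the contiguous
saturated block (`sw >= sat - 1e-4`) anchored at the profile bottom;
saturated lenses above unsaturated soil do not count. Flood treatments
force the profile to saturation each treatment day (emulating rain added
until the table reaches the surface); evapotranspiration extracted on those
days is resupplied by the ponded water and logged as flood input, so the
water ledger closes to < 1e-3 mm over any season.

Three uptake rules follow the framework conventions: roots take neither
water nor mineral N from saturated layers; root elongation stops when
air-filled porosity at the root front falls below 3%; and, because
submerged roots sit in free water, the drought supply/demand ratio is
floored by the submerged root fraction (a flooded crop is oxygen-stressed,
never drought-stressed). Transpiration is additionally reduced by
`1 - 0.5 × frac_submerged`, representing the hypoxic loss of root hydraulic
conductance; this also lets repeated storm events stack a perched table
instead of having canopy water use erase it between events.

## Crop model

Phenology runs on thermal time (base 6 °C, optimum 30 °C) through anchored
stages (sowing 0, emergence 1, R1 3, R3 4, R5 5, maturity 6), with V-stages
counted by a 70 °Cd phyllochron. Growth is radiation-limited
(Beer's-law interception, RUE 0.80 g MJ⁻¹) and scaled by
`min(water, nitrogen)` stress. Daily N demand (2.5% of new vegetative
tissue, 4% of grain-phase tissue, plus slow replenishment of any
accumulated deficit) is met from soil mineral N first — uptake before
fixation — then by symbiotic fixation up to a stage-dependent capacity that
ramps from emergence to R3 and peaks through pod fill, scaled by
`oxdef_fix`.

Two integrating state variables convert daily stress into realistic
dynamics:

* **Tissue N sufficiency** — an exponential moving average
  (`alpha = 0.15`, a roughly week-long memory) of the daily
  supply/demand ratio. Growth responds to its square root (moderate
  dilution is cheap, deep starvation is crippling), and with a one-day lag,
  so a 48-h flood cuts growth by the photosynthesis factor (~25%) rather
  than by an instantaneous N collapse, while a 14-day flood starves the
  plant cumulatively.
* **Pod sink capacity** — grain capacity accrues in proportion to growth
  during the R1–R5 window (`pod_set_coeff = 0.73` kg sink per kg growth),
  and while tissue N sufficiency is below 0.55 in that window both the
  capacity and the pod-set potential are aborted at up to 35% d⁻¹ (scaled
  by starvation depth). Grain fill after R3 routes 66% of daily growth to
  grain, capped by this sink, plus a small (0.2% d⁻¹) retranslocation from
  vegetative biomass after R5.

The pod mechanism deserves a note, because an early design aimed to carry
flood-timing sensitivity entirely through window growth, stage severity,
recovery carry-over and the fixation peak. That failed structurally: the
recovery cap depends only on the *worst* multiplier reached (identical for
2- and 14-day floods), so both durations converged to the same post-flood
equilibrium and the steep observed duration response at R2 (2% yield loss
from extending a V4 flood 2→14 days vs more than 50% at R2) could not
emerge. Duration sensitivity requires a state that integrates flood length
irreversibly; flower/pod abortion under N starvation is that state, and is
well documented in flooded soybean.

## Weather generation and climate scenarios

The generator (`generate_synthetic_weather()`) uses sinusoidal annual
cycles for temperature (peak day 200) and radiation (peak at the solstice,
day 172 — the phase lag matters: with both peaks aligned, delayed pod fill
lands in a spuriously favourable radiation/thermal-time ratio and late
floods become harmless) with AR(1) noise, plus a two-state Markov rainfall
occurrence chain with exponential wet-day depths scaled to monthly target
totals. Long-run monthly means converge to within 10% of target over a few
decades.

Scenarios transform a series before simulation: `monthly_scale` multiplies
rain in chosen months (e.g. +25% in June, July, August);
`extreme_events` adds fixed 50-mm events on deterministic, evenly spaced
days — for `f` events in a month of `L` days, days `round(L·k/(f+1))`,
`k = 1..f` — *on top of* existing rain, keeping scenarios monotone in total
water. The built-in `risk_scenarios()` set contains the three single-month
+25% scenarios, the three-month +25% scenario, and the four event
frequencies (1–4 per month, June–August).

## Fixtures: what they emulate and what they do not

Three synthetic fixtures stand in for the field environments of the
published flooding experiments. Their hydraulic values are representative
textbook values for the named textures — not survey data — and their
climates are the generator's emulations, not reanalysis weather:

* **`clay_fixture()`** — a mid-South heavy clay: high field capacity, a
  modest air-capacity profile (~80 mm) that tightens with depth, and a
  slow-draining subsoil (deep drainage 2 mm d⁻¹), so stacked storm events
  perch a shallow table for days. MG 4, sown May 10.
* **`silt_loam_fixture()`** — a mid-South silt loam over a claypan: three
  times the air capacity, fast internal drainage, slow deep drainage. The
  same flood designs produce different (usually milder, threshold-like)
  penalties than the clay, which is the soil-contrast behaviour the model
  family reports.
* **`iowa_fixture()`** — a northern silty clay with a cooler, shorter
  season, an MG 3 cultivar, and a calendar-based periodic waterlogging
  design. Its nitrogen pools are sized so that unstressed fixation supplies
  roughly 47% (35–70% across weather years) of above-ground plant N.

Fixture monthly rainfall keeps early summer moderately dry and
July–August wet. That choice makes controls clean (neither droughted nor
naturally waterlogged in most years) so that treatment effects are
attributable; it also reproduces the reported scenario asymmetry — +25%
June rain is essentially harmless while the same relative increase in
July–August costs about 1–2%.

Because fixtures are synthetic, passing tests demonstrate that the *model
mechanisms* produce the documented stress responses, duration/timing
asymmetries and scenario rankings under controlled conditions; they do not
validate the simulator against any particular field dataset, and absolute
yields (≈2 500–5 000 kg ha⁻¹ in controls) are calibrated plausibility, not
predictions.

## Numerical choices and degenerate inputs

* Saturation comparisons use a volumetric tolerance of 1e-4; layer depths
  are half-open intervals `[top, bottom)` in mm, indexed top-down.
* Stress evaluation order each day: water balance → table/predictor
  diagnostics → phenology → root growth → drought → photosynthesis stress
  (with recovery cap) → N uptake/fixation (with fixation stress) → growth →
  pod set/abortion → grain fill. Stresses therefore see the morning soil
  state.
* Zero demand returns multiplier 1 (drought and N); `duration_days = 0`
  treatments and `kind = "none"` scenarios are exact no-ops; perturbing a
  stress function by 0 SD is the identity; the fixation saturated anchor is
  clamped to 0 under every perturbation, with a warning if a shift would
  break monotonicity.
* Yield is monotone non-increasing in flood duration at fixed stage up to a
  sub-percent jitter: shifting phenology by a day realigns the window with
  different weather days, which can move yield by a few tenths of a percent
  in either direction. Tests assert monotonicity with a 2%-of-control
  allowance on deterministic weather and strict inferiority of 14-day
  floods.

## Problem sizes

The shipped tests and the acceptance script use deliberately small, fixed
problem sizes chosen as the package's own reporting convention: 5 seeded
weather years for flood-timing comparisons and the fixation share, and 30
paired years per fixture (three fixtures) for the two rainfall-scenario
summaries. A full season is ~115–125 simulated days and runs in well under
a second.

## Known limitations

* No within-plant N remobilisation; grain N demand is met from current
  supply, so late-season N stress is slightly overstated.
* No leaf-senescence response to excess water, no soil temperature model,
  no matric-potential output, and a single mineral-N pool per layer with a
  fixed mineralization rate (deliberately insensitive to waterlogging).
* The water balance is a daily bucket: infiltration/redistribution within a
  day is instantaneous, and the perched-table position is a piecewise
  function of stored excess rather than a pressure solution.
* Cultivar presets differ only in thermal-time duration; maturity-group
  differences in stress tolerance are not represented.

## A worked example

```{r example, fig.width = 7, fig.height = 5}
cfg <- fixture_config("clay", n_years = 1, seed = 1)
control <- run_season(cfg)
summary(control)

fe <- run_flood_experiment(cfg, stages = c("V4", "R2"),
                           durations = c(2, 14))
fe
```

The factorial shows the headline asymmetry directly: extending a V4 flood
from 2 to 14 days moves yield by a percent or two, while the same
extension at R2 roughly halves it.
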
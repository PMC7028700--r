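# soyflood

Process-based simulation of waterlogging ("oxygen deficit") stress in
soybean.

Crop models routinely simulate drought but mostly ignore the other side of
the water axis: flooding and perched water tables, which cost soybean
growers substantial yield and are becoming more frequent as rainfall grows
more intense. `soyflood` is a self-contained, daily time-step soybean
cropping-system simulator for agronomists and modellers who want to study
how flood **timing** and **duration** translate into yield loss, and what
rainfall-intensification scenarios imply for risk — without any external
model installation or data download.

## The model in brief

Moisture stresses are 0–1 multipliers given as piecewise-linear x/y pairs,
anchored at field capacity (x = 0, no stress) and saturation (x = 1, full
stress):

* drought: `min(1, supply/demand)` from root-zone plant-available water vs
  VPD-normalised transpiration demand;
* `oxdef_photo(x)` on radiation-use efficiency, x = fraction of roots below
  the water table, default pairs {(0,1), (0.8,1), (1,0.75)};
* `oxdef_pheno(x)` on thermal-time accumulation, default
  {(0,1), (0.8,1), (1,0.4)};
* `oxdef_fix(x)` on symbiotic N fixation, x = water-filled-pore-space
  excess fraction of the top 0.45 m, default {(0,1), (0.5,1), (1,0)} with
  the saturated anchor pinned at 0.

A stage-severity factor deepens photosynthesis and fixation stress from R1
to pod fill (1 → 1.2 on the stress depth); floods at or after R1 leave a
persistent post-flood depression (`1 − 0.5 × (1 − worst multiplier)`),
whereas vegetative floods are fully recoverable. The soil is a layered
tipping bucket with ponded infiltration, per-layer drainage capacities and
a perched water table that rises from the impeding profile bottom. The crop
carries a full N economy (soil uptake before fixation, a stage-dependent
fixation capacity peaking during pod fill) and a pod-sink component (pod
set proportional to growth between R1 and R5, abortion under sustained N
starvation) that makes reproductive floods damaging in proportion to their
length.

Synthetic fixtures (`clay_fixture()`, `silt_loam_fixture()`,
`iowa_fixture()`) pair representative soil profiles with maturity-group
cultivar presets and a seeded stochastic weather generator, so every
experiment in the package runs offline and reproducibly.

## A worked example

```r
library(soyflood)

cfg <- fixture_config("clay", n_years = 1, seed = 1)
run_season(cfg)
#> Soybean season (waterlogging functions on)
#>   yield            4788 kg/ha
#>   biomass         13013 kg/ha
#>   N fixed         173.4 kg/ha (45% of plant N)
#>   N uptake        212.4 kg/ha
#>   maturity     1991-09-11
#>   max roots        1200 mm

run_flood_experiment(cfg, stages = c("V4", "R2"), durations = c(2, 14))
#> Flood experiment (4 treatments + control)
#>    stage duration_days yield penalty_pct
#>  control             0  4788         0.0
#>       V4             2  4832        -0.9
#>       V4            14  4627         3.4
#>       R2             2  3908        18.4
#>       R2            14  1921        59.9
```

The factorial reproduces the signature timing asymmetry: extending a flood
from 2 to 14 days at the fourth-leaf stage (V4) changes yield by a few
percent at most, while the same extension at early flowering (R2) cuts the
remaining yield by more than half. The negative V4 penalty in this weather
year is the flood acting as marginal irrigation.

Other entry points: `run_multi_year()` (annual-reset multi-year runs),
`run_sensitivity()` (±1/±2 SD perturbations of each stress function, with
the fixation saturated anchor held fixed), `run_risk_analysis()` with
`risk_scenarios()` (the eight built-in rainfall scenarios: single-month and
three-month +25% increases, and 50-mm extreme events one to four times per
month), and `plot()`/`summary()` methods on season results. A thin command
line lives in `inst/cli/soyflood` (subcommands `simulate`,
`flood-experiment`, `risk`, `sensitivity`, `evaluate`,
`fixtures generate`).

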
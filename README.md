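# reefresp

Swimming respirometry and hypoxia-tolerance analysis for larval coral reef
fish.

Coral reef fish larvae live two lives in quick succession: a pelagic phase
demanding extreme aerobic swimming performance, and reef life demanding
tolerance of nocturnal hypoxia. Quantifying that transition requires three
measurement pipelines that this package implements as tested, reusable R
code:

1. **Stepped-velocity swimming respirometry.** A larva swims in a sealed
   miniature flume while water velocity rises by one body length per second
   (BL s⁻¹) every 20 minutes until fatigue. The critical swimming speed is

   *U*<sub>crit</sub> = *V*<sub>f</sub> + (*T*/*t*)·*V*<sub>i</sub>,

   where *V*<sub>f</sub> is the last fully completed speed, *T* the time
   swum at the fatigue speed, *t* the step interval and *V*<sub>i</sub> the
   increment. During each sealed step the oxygen depletion slope *S*
   (mg O₂ L⁻¹ s⁻¹, ordinary least squares against time, background
   microbial respiration subtracted) gives the mass-specific oxygen uptake

   *Ṁ*O₂ (mg O₂ g⁻¹ h⁻¹) = |*S*| · *V*<sub>resp</sub> · 3600 / *M*,

   with *V*<sub>resp</sub> the chamber volume minus the fish and *M* the
   body mass. Fitting *Ṁ*O₂ against speed *u* with either
   *R*(*u*) = *a* + *b·u* or *R*(*u*) = *a* + *c·u*<sup>*b*</sup>
   (AIC-selected) yields the standard metabolic rate (SMR, the intercept at
   *u* = 0), the maximum metabolic rate (MMR, the largest observed step
   *Ṁ*O₂), absolute aerobic scope (AAS = MMR − SMR) and factorial aerobic
   scope (FAS = MMR/SMR). Across fish, allometric mass scaling
   *y* = *a*·*x*<sup>*b*</sup> is fitted by log–log least squares.

2. **Closed-chamber hypoxia trials.** A larva sealed in a 1.5 ml vial draws
   oxygen down until loss of equilibrium (LOE); the % air saturation at LOE
   is the tolerance endpoint, converted between % saturation, partial
   pressure (mm Hg) and dissolved concentration (mg O₂ L⁻¹) with seawater
   gas physics (Antoine vapor pressure, Garcia–Gordon solubility).

3. **Categorical-age statistics.** One-way linear models of each metric
   against age (days post hatch, dph), Tukey-adjusted pairwise contrasts,
   and compact letter displays.

Because raw trial traces are rarely shareable, the package ships a seeded
synthetic-data generator (`simulate_cohort()`) that emulates the full study
design — larval growth, metabolic allometry with exponent −0.8, speed-cost
curves, fatigue, microbial background respiration, optode sensor noise,
and age-dependent LOE thresholds — so every pipeline stage is testable
end-to-end against known truth.

## Worked example

```r
library(reefresp)

# oxygen unit conversions at tropical trial-water conditions
cond <- gas_conditions(temperature = 28, salinity = 33, pressure = 758)
oxygen_reading(c(42.0, 30.7, 23.8), cond)
#>   percent_air_saturation      po2 dissolved_o2
#> 1                   42.0 64.20881     2.728420
#> 2                   30.7 46.93358     1.994345
#> 3                   23.8 36.38499     1.546105

# a full simulated study: 77 larvae aged 1-9 dph, one 1 Hz trace each
cohort <- simulate_cohort(cohort_config(seed = 42))
swim   <- run_swim_analysis(cohort)
head(swim[, c("fish_id", "age_dph", "mass_mg", "ucrit_bl_s",
              "smr", "mmr", "fas", "model")], 5)
#>   fish_id age_dph   mass_mg ucrit_bl_s      smr      mmr      fas  model
#> 1 fish001       1 0.6605589   2.781667 3.418436 13.25384 3.877166 linear
#> 2 fish002       1 0.3700478   3.263333 9.611096 21.26613 2.212664  power
#> 3 fish003       1 0.5092998   2.953333 5.914364 23.68303 4.004324 linear
#> 4 fish004       1 0.5497826   3.057500 7.336930 14.54320 1.982192 linear
#> 5 fish005       1 0.5154742   3.771667 8.679165 18.85642 2.172607  power

scaling <- run_scaling(swim)
scaling$smr
#> Scaling fit: y = 4.736 * mass^-0.770 (r2 = 0.920, n = 77)
scaling$mmr
#> Scaling fit: y = 11.01 * mass^-0.807 (r2 = 0.911, n = 77)

hyp <- run_hypoxia_analysis(cohort$loe, cohort$conditions)
hyp$summary[, c("age_dph", "n", "mean_percent_sat", "mean_po2")]
#>   age_dph  n mean_percent_sat mean_po2
#> 1       4 13         41.25477 63.06952
#> 2       6 12         35.51396 54.29307
#> 3       9  9         23.51789 35.95371
hyp$comparison
#> One-way LM: F(2,31) = 26.99, p = 1.63e-07, r2 = 0.64
#> Letters: 4=a, 6=b, 9=c
```

Reading the output: mass-specific oxygen uptake falls steeply with size
(scaling exponents near −0.8 for both SMR and MMR), swimming speeds climb
from ~3 BL s⁻¹ at 1 dph towards ~9 BL s⁻¹ at settlement, factorial scope
sits near 2.2, and hypoxia tolerance improves with age — the mean LOE
threshold drops from ~41% air saturation at 4 dph to ~24% at 9 dph, with
all three ages statistically distinct (letters a/b/c).

The same functions accept data from disk: `run_swim_analysis(trace_dir,
metadata_csv)` reads the documented trace dialect
(`time_s,o2_percent_sat,temp_c,phase,speed_cm_s`), and
`run_hypoxia_analysis("loe.csv")` reads LOE trial tables. `write_cohort()`
emits a simulated study in exactly those formats.

## Documentation

The methods vignette (`vignettes/respirometry-methods.Rmd`) describes the
models, the tunable parameters and their defaults, the synthetic-data
generator's assumptions, numerical choices, and known limitations.
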
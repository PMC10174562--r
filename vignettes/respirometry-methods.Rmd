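---
title: "Methods: larval swimming respirometry, aerobic scope and hypoxia tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: larval swimming respirometry, aerobic scope and hypoxia tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefresp)
```

This vignette is the package's own account of the science it implements:
the measurement models, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the numerical decisions made where the methodology left room.

## 1. Oxygen units in seawater

All pipelines run on oxygen expressed as **% of air saturation**, the
native unit of optical oxygen meters, and convert to partial pressure
(PO₂, mm Hg) or dissolved concentration (DO, mg O₂ L⁻¹) when a rate or a
physiological threshold needs physical units.

The partial pressure of oxygen in air-equilibrated water is the dry-gas
fraction of barometric pressure times the oxygen mole fraction:

$$P_{O_2} = (P_{baro} - p_{H_2O}(T)) \cdot x_{O_2}.$$

Water vapor pressure uses the Antoine equation with coefficients
A = 8.07131, B = 1730.63, C = 233.426 (mm Hg, °C), valid over 0–100 °C.
At 28 °C and 758 mm Hg with the default $x_{O_2} = 0.2095$ this gives
`r round(po2_at_full_air_saturation(gas_conditions(28, 33, 758)), 2)`
mm Hg at full saturation.

Dissolved-oxygen solubility at 100% air saturation uses the
Garcia–Gordon (1992) fit to the Benson–Krause data (the community-standard
parameterisation for oceanographic work), evaluated in ml L⁻¹, converted
by 1.42905 mg per ml O₂, and corrected to the actual barometric pressure
by the dry-gas ratio $(P - p_{H_2O})/(760 - p_{H_2O})$. Percent
saturation maps to both units by plain proportionality, so round trips
close to machine precision — an invariant the test suite checks for
random conditions.

Pressure can be supplied in mm Hg or hPa (converted by 0.750062 on
ingest); both conventions appear in field calibration records.

One caveat worth knowing: published trial reports sometimes round the
saturation concentration and the converted thresholds independently, so a
printed DO value can disagree with the product of its own printed factors
by ~0.04 mg L⁻¹. This package always converts self-consistently; it does
not reproduce rounding artefacts.

## 2. Respirometry: from trace to ṀO₂

A trial trace is a 1 Hz series of time, O₂ (% air saturation),
temperature, a phase label (`habituation`, `measure`, `flush`,
`background_pre`, `background_post`) and the commanded swimming speed.

For each sealed `measure` window the depletion slope is the ordinary
least-squares slope of DO (mg L⁻¹, converted at the window's **mean
measured temperature**) against time in seconds. The whole window is used
by default; `trim_seconds` can drop leading mixing seconds, but the
default is 0 because the protocol description gives no trimming rule.

Microbial background respiration is fitted from the 10-minute
empty-chamber windows before and after the trial and **interpolated
linearly in trial time** between the two window midpoints. The protocol
measures both windows without stating how they combine; linear
interpolation accounts for microbial growth during the trial and reduces
to the mean at the midpoint. With only one window available the slope is
used as a constant.

Mass-specific uptake for a step is then

$$\dot M_{O_2} = |S - S_{bg}(t_{mid})| \cdot V_{eff} \cdot 3600 / M,$$

with $V_{eff}$ the chamber volume minus the fish's displacement volume
(mass at an assumed tissue density of 1.0 g ml⁻¹ — the conventional
assumption when only mass is recorded) and $M$ in grams. The factor 3600
converts the per-second slope to the hourly rate exactly once, here. If
the background estimate exceeds the measured slope the step's rate is set
to 0 and flagged `background_exceeds_slope` rather than reported
negative.

Quality control produces *flags*, never silent exclusions:
`below_90pct_sat` when any sample breaches the 90% floor used to protect
fish from hypoxia during trials, `low_r2` below a configurable threshold
(default 0.95 — depletion in a well-sealed miniature chamber is very
nearly linear, so a lower r² indicates mixing or leak problems), and
`short_window` under 30 samples. Exclusion decisions belong downstream.

## 3. Critical swimming speed

$U_{crit} = V_f + (T/t)\,V_i$ is computed exactly from the penultimate
speed, time-at-fatigue, interval and increment. Tie-break: fatigue exactly
at a step boundary counts as $T = 0$ of the next, never-started step, so
$U_{crit}$ equals the completed speed — the conservative reading.

The fatigue point of a trace comes from the `fatigue_time_s` annotation
when present (the simulator provides it); otherwise it is inferred from
the truncation of the final `measure` window. The structural inference is
correct whenever the final window was not itself cut short by the
saturation floor; the annotation removes even that ambiguity. Trials
whose fatigue falls in the first step (or during habituation) are flagged
and yield no $U_{crit}$ — newly hatched fish that only hold station at
the habituation speed need a special-case treatment that observers, not
algorithms, must supply.

The 1 Hz sampling resolves $T$ to one second, so end-to-end recovery of a
simulated fish's true $U_{crit}$ is accurate to $V_i/(60t)$ — far inside
the protocol's own resolution bound of one increment.

## 4. Aerobic scope and allometry

Per fish, uptake against speed is fitted with both a straight line
$R(u) = a + bu$ (OLS) and a power curve $R(u) = a + cu^b$ (nonlinear
least squares via `minpack.lm::nlsLM`). The power fit is initialised from
a log–log regression of $(R - \min R + \varepsilon)$ on $u$ with
$\varepsilon = 10^{-6}$, and convergence tolerances of $10^{-12}$
(ftol/ptol, ≤ 200 iterations). The model with the lower AIC is selected —
the same criterion the statistical workflow uses for its linear models,
applied here for consistency. Two guard rails:

* the power curve is only attempted with ≥ 4 distinct speeds, because its
  three mean parameters interpolate any 3 points exactly and the AIC
  comparison degenerates;
* if the nonlinear fit fails to converge the linear fit is used.

SMR is the intercept $a$ of the selected model — uptake extrapolated to
zero speed. A non-positive intercept is biologically impossible, so such
fish are excluded from uptake analysis (reason `negative_intercept`)
while keeping their $U_{crit}$. MMR is the **maximum observed step
uptake**, not the fitted curve's value at $U_{crit}$: the definition is
anchored to what was measured at the highest speeds before fatigue, and
using the observed maximum avoids leaking model error into the scope.
AAS = MMR − SMR and FAS = MMR/SMR; the factorial scope is the
fold-increase above rest, so values are ≥ 1 whenever MMR ≥ SMR.

Mass scaling $y = a x^b$ is fitted by least squares on
$\log y \sim \log x$. The log-log route weights relative (not absolute)
errors, which matches the multiplicative scatter of metabolic rates, and
makes the exponent scale-equivariant: multiplying all rates by a constant
changes $a$ only. A direct nonlinear fit of the same law weights large
fish more; over the ~20-fold mass range here the two differ by far less
than the sampling error of the exponent, so the simpler, closed-form
route is the default.

## 5. Hypoxia trials

Loss of equilibrium is an observer-recorded event carried in the input
data; nothing tries to detect it from the trace, because in the protocol
it is a behavioural judgement confirmed over 10–15 s. Records validate
that the threshold lies strictly inside (0, 100)% and attach PO₂ and DO
conversions. Group summaries report arithmetic means with the sample
(n − 1) standard deviation — the convention behind "mean ± SD" reporting
on small groups — and singleton groups carry an `NA` SD rather than a
misleading 0.

## 6. Categorical-age statistics

`fit_group_lm()` is the one-way fixed-effects cell-means model:
$F = MS_{between}/MS_{within}$ on $(k-1, n-k)$ degrees of freedom and
$r^2 = SS_{between}/SS_{total}$. The test suite checks it against a
brute-force sums-of-squares oracle to $10^{-10}$.

Pairwise contrasts test all mean differences on the pooled-variance t
statistic with $n - k$ df. The default adjustment is Tukey's HSD via the
studentized range distribution ($q = \sqrt{2}\,|t|$), which controls the
family-wise error at α across all pairs and reduces exactly to the plain
two-sided t test when $k = 2$; Holm is available as the conservative
step-down alternative. A seeded null simulation in the test suite
confirms the family-wise error stays at its nominal level.

The compact letter display uses the insert-and-absorb algorithm: start
with one letter containing all groups; for each significant pair,
duplicate every letter column containing both members, removing one
member from each copy; absorb columns whose membership is a subset of
another's; finally label columns in order of their first member. By
construction two groups share a letter **iff** their comparison is
non-significant, and non-transitive patterns (A ≠ C but A = B = C's
neighbour) yield multi-letter labels like `a / ab / b`, never an error.

`aic_select()` ranks candidates by $2k - 2\ln L$ with ties broken toward
fewer parameters. Note the statistical reality of that criterion: with
two superfluous parameters the overfitted model still wins whenever its
deviance improvement exceeds 4, i.e. with probability
$P(\chi^2_2 > 4) = e^{-2} \approx 13.5\%$. The tests assert that
theoretically derived rate, not an idealised one.

## 7. The synthetic-data generator

`simulate_cohort()` exists so that every stage — trace parsing, slope
fitting, background correction, fatigue extraction, model selection,
scaling, group statistics — can be tested end-to-end against known truth
with no data download. Its defaults are the study conditions, chosen once:

| Parameter | Default | Basis |
|---|---|---|
| ages, n per age | 1–9 dph; 9,8,9,9,8,9,8,9,8 (77 fish) | the study's residual df imply 77 fish at 8–10 per age |
| mass–age growth | mass = 0.422·age + 0.0328 mg | reported growth regression |
| mass residual | size-proportional, CV 0.33, truncated > 0.05 mg | growth variance scales with size, so hatchlings vary by ~0.15 mg and settlers by ~1.3 mg; reproduces the growth regression's moderate explanatory power (r² ≈ 0.65) without the slope bias an absolute-SD residual would pick up from truncation at small sizes |
| mass–length | length = 0.511·mass^(1/3) cm | isometric shape; gives ~0.8 cm at settlement size, ~0.4 cm near hatch |
| true SMR | 5·mass^(−0.8) mg O₂ g⁻¹ h⁻¹, lognormal scatter SD 0.15 | steep allometric exponent of the study; coefficient set so SMR spans ~1.7 (settlement) to ~9 (hatch) |
| swimming cost | c·u², c from FAS = 2.2 at the fatigue-step speed | quadratic hydrodynamic cost shape exercises the power-model pathway; the factorial scope anchor reproduces the reported cohort-mean FAS where MMR is actually measured |
| true U_crit | linear 2.5 → 9.4 BL s⁻¹ over 0–9 dph, CV 12% | reported endpoint means; CV between the reported group CVs |
| LOE thresholds | 42.0/30.7/23.8% at 4/6/9 dph, SD 4.6/7.1/3.7 | reported group means ± SD; interpolated (clamped) at other ages |
| background slope | pre-trial U(−10⁻⁵, −10⁻⁶) mg O₂ L⁻¹ s⁻¹; post = pre × U(1.2, 2) | a few percent of a typical fish signal, growing over the trial |
| sensor noise | i.i.d. Gaussian, SD 0.2% air sat | optode-class precision |
| flush | exponential relaxation, τ = 60 s | a 3-min flush restores > 95% of the deficit |

Traces integrate the piecewise oxygen dynamics with a midpoint rule that
is exact for a linearly drifting background, so a zero-noise trial is
recovered by the analysis pipeline to well under 0.5% — the oracle the
acceptance tests rely on. Sealed windows are truncated (with an early
flush) if oxygen would cross the 90% floor, as an operator would do; the
fish still swims to the scheduled end of the step, and the trace's
fatigue annotation records the true fatigue time.

The LOE simulator treats the vial as well mixed and by default records
the threshold crossing exactly (continuous logger reading): the
configured group means are the *observed* distribution being emulated, so
the recorder must not add bias on top of them. The 2–5 min visual-check
quantisation of a human observer is available
(`loe_check_interval_s`), and biases recorded values low by roughly the
drawdown rate times half the check interval — worth switching on when
studying protocol sensitivity, not when validating the pipeline. An
oxyconformity option (`conform_below_percent`) lets resting uptake
decline in proportion to ambient oxygen below a chosen level; it is off
by default because the emulated trials ran fish well above their critical
oxygen tension until shortly before LOE.

What the generator does **not** emulate — and therefore what passing
tests cannot certify about real data: optode drift and recalibration
error, temperature excursions at high flume speeds, autocorrelated
sensor noise (available as an option but off by default), incomplete
mixing in the vial, behavioural pacing (burst-and-coast swimming that
makes real speed–uptake points noisier than i.i.d.), and any
between-clutch structure. Slopes, scopes and letters that validate here
validate the *arithmetic*, not the field protocol.

## 8. Problem sizes and determinism

The test suite and the acceptance script run the full default study — 77
swim trials at 1 Hz (about 1.1 million samples) plus 34 LOE trials — in
a few seconds on one core; oracle suites use 1,000 regression windows and
1,000 null replicates. All randomness flows from a single integer seed:
the same seed reproduces cohorts, traces and output files bit-for-bit.

## 9. Known limitations

* The 0-dph special case (fish that fatigue at the habituation speed) is
  flagged, not estimated; computing a $U_{crit}$ for such fish requires a
  convention the protocol description does not supply.
* Fatigue inference from an un-annotated trace is ambiguous in the rare
  case where the final sealed window was cut by the saturation floor.
* The ANCOVA extension (age plus a mass covariate) covers the common
  reporting case; mixed models, model averaging and residual-diagnostic
  simulation are out of scope.
* No critical-oxygen-tension (P_crit) estimation: the hypoxia endpoint
  here is behavioural (LOE), not respirometric.
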
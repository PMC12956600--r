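---
title: "Methods: breath-by-breath CPET processing, efficiency metrics, and the synthetic ramp-test generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath-by-breath CPET processing, efficiency metrics, and the synthetic ramp-test generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpetr)
```

## What the package computes

`cpetr` analyses ramp-incremental cardiopulmonary exercise tests (CPET)
recorded breath by breath: oxygen uptake (VO~2~, mL/min), carbon dioxide
output (VCO~2~, mL/min), minute ventilation (VE, L/min BTPS), heart rate and
end-tidal pressures, against a work-rate profile that holds a start load
through a steady-state warm-up and then rises linearly until exhaustion.
From one test it derives the quantities exercise physiologists tabulate for
cohort comparisons:

* **VO~2peak~** — the maximum of the 30-s smoothed VO~2~ channel, absolute
  and per kilogram of body mass;
* **VO~2~ plateau** — whether the last-minute VO~2~ rise fell below half of
  the ramp-expected rise;
* **exhaustion** — the secondary criteria RER~max~ ≥ 1.13 (adults) and
  HR~max~ ≥ 95 % of 195 beats/min (children);
* **OUES** — the oxygen uptake efficiency slope, the coefficient *a* in the
  ordinary least-squares fit VO~2~ = a · log~10~(VE) + b over all exercise
  data;
* **OUEP** — the oxygen uptake efficiency plateau, the highest 90-s average
  of the per-breath efficiency OUE = VO~2~/VE (mL O~2~ per L ventilation);
* **VT1, VT2** — the ventilatory thresholds, located automatically on the
  ventilatory-equivalent panel;
* **O~2~/W** — exercise efficiency as the ramp-phase regression slope of
  VO~2~ on power;
* the derived ratios (VT/VO~2peak~, P~VT~/P~peak~, OUEP/VO~2peak~).

A linear-model layer compares cohorts (children 7–11 y, moderately trained
adults, well-trained adults) with sex and group as covariates and reports
Cohen's *d* with conventional band labels.

Because per-breath clinical recordings of this kind are rarely shareable,
the package carries a synthetic generator that produces complete ramp tests
with *planted* ground truth for every derived quantity. All tests of the
pipeline run against that generator.

## Processing conventions

**Smoothing.** All gas-exchange channels are smoothed with a moving average
over a *centred, time-based* 30-s window; every breath inside
[t − 15 s, t + 15 s] is weighted equally. Centred windows are the common
metabolic-cart convention and, unlike trailing windows, do not shift
threshold timing. Windows are truncated at the record boundaries rather
than padded, which has two consequences the rest of the pipeline accounts
for explicitly:

* near termination the smoothed channels bend toward the trailing mean, so
  the threshold detector and the O~2~/W regression exclude the final half
  window (15 s);
* the smoothed VO~2~ maximum sits slightly (≈ 1 %) below the instantaneous
  trajectory peak on a test without a plateau, which is within the
  tolerance of every recovery check and mirrors what a real smoothed
  record shows.

**Gridding.** Breath timestamps are irregular, so every windowed statistic
(per-minute plateau means, 90-s OUEP windows, threshold scans) is evaluated
on a 1-s linear-interpolation grid clipped to the observed record — no
extrapolation. Ties in maxima go to the earliest time.

**Units.** The canonical in-memory units are mL/min (VO~2~, VCO~2~), L/min
(VE), W, s, mmHg. The breath CSV loader converts unit-tagged columns
(`vo2_l_min`, `ve_ml_min`, …) on the way in, so a mixed-unit export cannot
silently introduce a factor-of-1000 error.

**Quality screening.** `qc_screen()` flags sustained RER outside
[0.6, 1.6] (> 30 s), single-breath VE excursions beyond 3× the local
running median, and inter-breath gaps above 10 s. The first two carry
"exclude" severity; gaps only warn. These rules are this package's own
conventions — real laboratories exclude tests for many reasons no fixed
rule captures — and all thresholds are arguments.

## Metric definitions and the choices behind them

**OUES scope.** "All exercise data" is read as warm-up through termination;
`compute_oues(scope = "ramp")` restricts to the ramp for sensitivity
analyses. The fit is ordinary least squares of VO~2~ on log~10~(VE); the
slope is reported in mL/min per log~10~(L/min) and also per kilogram.

**OUEP.** The "highest 90-s average of consecutive OUE values" is
well-defined only on a regular grid, so windows [s, s + 90] are evaluated
at every 1-s offset over the whole test. A 90-s *average* of a curved
efficiency profile is necessarily a little below the instantaneous maximum
(≈ 1 % under the default conditions); the recovery tests budget for this.

**Plateau.** The observed rise is the mean VO~2~ of the final 60 s minus
the mean of the preceding 60 s; the expected rise is 10 mL/min/W times the
ramp rate. A plateau requires the observed rise to be *strictly below* 50 %
of expected — the boundary case is not a plateau. Ramps shorter than two
minutes return a not-evaluable result instead of an error.

**Exhaustion.** Both criteria are closed (≥) exactly at 1.13 and at
0.95 × 195 = 185.25 beats/min; the unit tests pin both boundaries. For
children only the heart-rate criterion applies, for adults only the RER
criterion. Participants failing their criterion keep every submaximal
metric and are excluded only from peak-referenced outcomes.

**O~2~/W.** The tabulated unit (mL/min/W) admits two readings; the package
uses the ramp-phase OLS slope of smoothed VO~2~ on power, trimming 15 s at
each end of the ramp (smoothing boundary effects), with the peak-ratio
alternative behind `method = "peak_ratio"`. On a first-order-lag system the
slope estimator under-reads the true gain by roughly τ/T (lag time constant
over ramp duration), about 2 % under the default conditions.

## Automated threshold detection

In most studies, ventilatory thresholds are set by a two-rater consensus
over the classic panel: VE/VO~2~ and VE/VCO~2~ against
time, the V-slope plot (VCO~2~ vs VO~2~), and the end-tidal pressures.
Reproducibility demands an algorithm, so `detect_vt()` automates exactly
that panel with two-segment piecewise-linear least squares:

1. **VT2** is the breakpoint where VE/VCO~2~ begins its steeper sustained
   rise, fitted over data from the right edge of the VE/VO~2~ nadir basin
   onward (the last time the equivalent sits within 5 % of its range above
   its minimum — robust to noise in the flat pre-VT1 stretch).
2. **VT1** is the breakpoint where VE/VO~2~ leaves its nadir, fitted over
   ramp data before the detected VT2.
3. VT2 is refitted over data after the detected VT1.

The sequencing matters because each equivalent carries *both* transitions,
and a single two-segment model cannot represent a three-segment channel.
Every accepted breakpoint is then re-localised inside a ±60 s window by a
scan that fits both a sharp hinge and a smoothing-rounded hinge (a centred
30-s boxcar turns a piecewise-linear corner into a known quadratic
rounding) and keeps whichever basis fits better. The local window removes
the leverage of far-field curvature; the rounded basis keeps the estimate
unbiased when one arm of the corner is short, as happens when the
respiratory-compensation point falls close to termination.

A breakpoint is accepted only if the hinge model beats a single line by an
F-ratio of at least 4 (configurable) with the correct slope-change sign;
otherwise a not-found result is returned and downstream fields stay `NA`.
Breakpoints may lie in the central 5–95 % of the ramp — slightly wider than
the 10–90 % sometimes used, because VT2 typically falls around 85–95 % of
ramp time and a narrower window would discard physiologic cases. The
V-slope breakpoint (for VT1) and the onset of PetCO~2~ decline (for VT2)
are computed as advisory cross-checks and reported alongside, never
overriding the equivalents. Rater-set times can be imported with
`summarize_test(vt_manual = )`, tagged `"manual-import"`.

Known limitation: a VT2 planted within about half a smoothing window of
termination is fundamentally unresolvable from the smoothed record, and
detection errors grow near the admissible-window edge; under default noise
the cohort-pooled VO~2~@VT2 RMSE stays below 3 mL/kg/min, but individual
late-threshold tests can miss by much more.

## The synthetic ramp-test generator

`simulate_test()` builds one test from a `physio_profile()` of planted
parameters. The noise-free construction:

* **Work rate** follows the protocol: start load through the warm-up, then
  a linear ramp. Protocols are the five (start load, rate) pairs
  (7, 7), (10, 10), (20, 15), (50, 20), (50, 30) (W, W/min), selected per
  participant so the predicted ramp duration lands in the 8–10 min target
  band (`select_ramp_protocol()`).
* **VO~2~** is the first-order lag (τ = 30 s by default; the literature
  ranges roughly 20–45 s) of resting VO~2~ plus 10 mL/min/W of demand,
  capped at the planted peak. Termination is the moment the trajectory
  reaches the cap or, when a plateau is planted, the later moment at which
  the last-minute rise has decayed to the planted fraction (< 0.5) of the
  ramp-expected rise — the ramp simply continues past the cap, which is
  how plateaus arise physiologically.
* **VE** is built from a designed ventilatory-equivalent curve
  eq(t) = 1000·VE/VO~2~: exactly piecewise linear in time, declining
  gently (1.5 units) to its nadir at the planted VT1 time, rising to a
  solved end value with a doubling of slope at the planted VT2 time. The
  nadir value is 1000/OUEP, planting the efficiency plateau, and the end
  value is solved by root-finding so that the whole-test OLS slope of
  VO~2~ on log~10~(VE) equals the planted OUES *exactly* (to solver
  tolerance ≈ 10⁻¹²). The OUES intercept is therefore a derived quantity,
  reported in the ground-truth record rather than planted.
* **VCO~2~** comes from a monotone piecewise-linear RER trajectory rising
  from 0.85 to the planted RER~max~ at termination, with knots at VT1 and
  VT2; the slope drop at VT2 gives VE/VCO~2~ its upward hinge there.
  PetO~2~ rises from VT1, PetCO~2~ falls from VT2, HR is linear in the
  VO~2~ fraction up to the planted HR~max~.
* **Breath timing** follows a linear 15 → 50 breaths/min rest-to-peak
  model with 10 % log-normal interval jitter; **measurement noise** is
  multiplicative log-normal per channel (default SD 0.05 for the gas
  channels, 0.02 for HR, 0.01 for end-tidal pressures — moderate
  metabolic-cart noise).

Identical inputs and seed reproduce a series bit for bit; cohort sub-seeds
are counter-based so a cohort extends without reshuffling.

**What the generator deliberately does not emulate.** The planted OUES
values follow the published group means (≈ 0.96–1.56 L/min at peak VO~2~ of
1.5–3.5 L/min). An exact log-linear VE–VO~2~ relation at those slopes
forces log~10~(VE) to span ΔVO~2~/OUES, i.e. a much wider ventilation range
than real carts record — peak VE (and hence the equivalents and the OUE
values at VT2) are unrealistically large, most visibly in the adult
groups. This is a deliberate trade: the efficiency slope is the principal
recovery surface, and the construction makes the *fitted quantity* the
ground truth while keeping threshold timing, RER bounds, peaks, plateaus
and OUEP exactly plantable. Consequently, passing recovery tests
demonstrate that the pipeline's estimators return what was planted under
realistic noise and breath timing; they do not certify behaviour on real
gas-exchange data, whose equivalents move in a narrower band. Phase-I
(cardiodynamic) kinetics, sensor artifacts (beyond the fault-injection
used in QC tests) and sex-specific sub-distributions are also not
modelled; sex enters as a label and covariate only, calibrated at the
group level.

**Cohort calibration.** `group_spec()` anchors each cohort's
anthropometrics, relative VO~2peak~, OUES, OUEP and threshold fractions at
the corresponding published group means and SDs (truncated-normal draws at
±3 SD with physiological floors; children sample OUES on the per-kilogram
scale, which reproduces both the relative and absolute group means).
Quantities the tables do not report use field-typical values chosen once:
resting VO~2~ 6 mL/kg/min in children and 3.5 in adults; HR~max~ ≈ 197/190/192
(SD 6–8) beats/min; RER~max~ ≈ 1.06 (children) and 1.21 (SD 0.05, floor
1.02) in adults, which reproduces the observed handful of adults below the
1.13 criterion; plateau prevalence 0.25 in children versus ≈ 0.6 in
adults, matching the reported rarity of pediatric plateaus. With the five
fixed protocols, adult draws predicted above ≈ 350 W cannot finish inside
12 min even on the steepest ramp; children's ramps stay within 6–12 min
and adult tails may reach ≈ 13–14 min.

## Cohort statistics

Outcomes are analysed with `lm(outcome ~ sex + group)`, reference levels
female and children, so coefficients read directly as the MTA−children,
WTA−children and male−female contrasts; confidence intervals are Wald with
t critical values at the residual degrees of freedom. Cohen's *d* uses raw
group means over the pooled sample SD (n − 1 throughout) — computable for
every pairwise contrast and the textbook default — with a model-based
alternative (`method = "model"`) behind a flag. Band labels on |d| use
half-open intervals [0, 0.2), [0.2, 0.5), [0.5, 0.8), [0.8, ∞), assigning
each boundary to the higher band, because the conventional verbal ranges
overlap at their edges. No multiple-testing correction is applied, and the
reports say so. Under permuted group labels the model's type-I error at
α = 0.05 is checked to stay within [0.03, 0.07] across 2000 refits.

## Problem sizes and determinism

The test-suite runs use the three default cohorts (18/18/19), a 50-profile
zero-noise sweep (17/17/16), 110 default-noise recovery replicates, 2000
permutation refits for error calibration, and oracle comparisons on series
up to 1000 breaths — sizes chosen so the whole suite and the acceptance
script each complete in a few minutes on one CPU while keeping Monte-Carlo
error well inside the tolerances they check. Every stochastic step is
seeded; `run_pipeline()` writes a provenance file from which a run can be
reproduced bit for bit.

## Known limitations

* The generator's adult ventilation magnitudes are non-physiological by
  construction (see above); treat absolute VE, VE-derived equivalents away
  from VT1, and OUE at VT2 as internal quantities, not as realistic data.
* OUE read *at* a detected threshold comes off the smoothed curve; at the
  VT1 corner the 30-s window mixes the post-threshold rise into the value,
  so it is not comparable to an instantaneous planted value where the
  equivalent curve bends sharply.
* Automated detection replaces, but cannot reproduce, the judgment of two
  experienced raters; on real data the F-gate will reject genuinely
  ambiguous tests rather than guess.
* Thresholds very close to termination (within ~half a smoothing window)
  are unresolvable in principle from a smoothed record.
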
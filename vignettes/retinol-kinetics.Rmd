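---
title: "Retinol tracer kinetics and beta-carotene bioefficacy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinol tracer kinetics and beta-carotene bioefficacy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retikin)
```

## The model and its assumptions

`retikin` analyzes plasma appearance curves of two retinol tracers after a
single oral co-dose: retinol derived from labeled retinyl acetate (the
reference arm, "C10") and retinol derived from labeled β-carotene (the
"C5" arm). Both arms share a six-component linear structure: a gut
compartment from which unabsorbed tracer is lost, an enterocyte
compartment, a pure transport delay standing in for chylomicron
production/metabolism and remnant uptake, a hepatic processing
compartment secreting retinol into plasma, the plasma retinol pool bound
to RBP, and one exchanging extravascular storage pool that is the sole
site of irreversible loss.

Assumptions worth making explicit:

* **Linearity and time invariance.** All transfers are first order; the
  tracee system is at steady state over the two-week window, so tracer
  kinetics are dose-invariant and the fraction-of-dose (FD) scale is the
  natural unit.
* **Fixed absorption for the reference arm.** Retinol absorption is
  pinned at 75%: the unabsorbed loss is `L01 = L21/3` exactly. (Reports
  of this constraint print the coefficient as 0.333; the package uses
  the exact third, which makes the absorbed fraction exactly 0.75 — the
  value every downstream identity assumes.)
* **Shared plasma handling.** Once retinol is in plasma on RBP, its
  kinetics do not depend on which dose it came from: the plasma/stores
  exchange and loss coefficients are common to both arms. This is what
  makes the terminal portions of the two curves parallel and the AUC
  ratio a clean bioefficacy measure.
* **Single lumped storage pool.** Liver and extrahepatic stores are not
  distinguished; residence-time results refer to the lumped pool.
* **Pure delay semantics.** The delay elements release their input
  exactly `DT` days later, with no dispersion. Delay times are reported
  without a spread parameter, so a zero-dispersion transport delay is
  the reference contract; the solver integrates the downstream states
  with the delayed inflow as an explicit forcing function (the
  gut/enterocyte pair has a closed-form bi-exponential solution, so no
  delay-differential machinery is required).

## Fraction-of-dose preprocessing and quality control

`fd_from_concentration()` converts plasma tracer concentrations to FD
using the plasma-volume rule (0.0435 L/kg body weight) and subtracts an
analytical background, by default the pre-dose (t = 0) sample of the same
analyte. Negative FDs are deliberately preserved — they are the signature
of background over-subtraction and one of the screening rules.

`screen_subject()` applies six exclusion rules in order: missing critical
samples (defaults: 6 h, 12 h, 2 d, 14 d), negative FD after background
subtraction, a significantly positive log-linear terminal slope (window:
days 2, 7, 14), convergence or divergence of the two curves, and an
abnormally high reference-curve peak (default bound: FD 0.30, roughly
1.5× the highest peak the model produces at typical coefficients).

Two calibration choices depart from naive significance testing and are
worth understanding:

* With only three terminal samples, a slope-vs-2-standard-errors rule has
  a single residual degree of freedom and a false-positive rate near
  30%. Slope rules therefore also require a magnitude floor
  (`slope_min = 0.05`/d) chosen above the steepest positive drift
  (+0.015/d) the model produces anywhere in the plausible parameter
  range.
* The model itself predicts a drifting isotope ratio between days 2 and
  7 while the slower β-carotene arm finishes delivering (the fitted
  hepatic rate in that arm is roughly half the reference arm's), so
  convergence/divergence is judged on the slope of the log isotope ratio
  between the **last two** terminal samples (days 7 → 14), where
  parallelism is strict (clean population range ±0.074/d). The floor is
  `ratio_slope_min = 0.15`/d; the C5 curve lies well below the C10
  curve, so a rising ratio means the curves approach (converge), a
  falling ratio that they separate (diverge).

All thresholds live in `qc_config()` and are configurable.

## Fitting

`fit_retinol_arm()` minimizes the weighted residual sum
`sum((y_i - f_i)^2 / (0.05 y_i)^2)` — a proportional error model with a
fractional standard deviation (FSD) of 0.05 per observation, using the
observed values in the weights with a variance floor at 1% of the curve
maximum so near-zero observations cannot dominate. The t = 0 sample is
excluded (the model fixes FD(0) = 0), as are nonpositive observations.
Seven parameters are free (`L21, L52, DT3, L54, L65, L56, L106`),
log-transformed to enforce positivity, with the delay bounded in
[0, 1 d]. `fit_carotene_arm()` then frees `P11, L1512, DT13, L1514` with
everything shared fixed at the retinol-arm estimates; simultaneous joint
fitting of both arms is deliberately out of scope.

Numerical choices:

* **Optimizer.** Levenberg–Marquardt (`minpack.lm`) with finite-difference
  Jacobians; convergence at a relative SSR change of 1e-8.
* **Consensus multi-start.** The objective surface has a long shallow
  valley along which `L65` and `L56` inflate together with little SSR
  penalty. A single start stalls in it for a sizable minority of
  subjects, so each fit runs a deterministic ladder of starting points
  (the supplied init, the reference cohort means, a slowed-exchange
  copy, ×3 and /3 rescalings) and stops as soon as the two best starts
  agree within 5% in SSR, keeping the best. Typical subjects cost two
  starts.
* **Physiological bounds as an identifiability guard.** Rates far below
  the study's time resolution are inestimable from a 14-day curve; the
  box bounds place floors (e.g. `L106 ≥ 1e-3`/d) at which such fits pin.
  A fit with a rate pinned at a bound is flagged `degenerate` and the
  pipeline excludes that subject from cohort summaries (its derived
  quantities, such as the storage residence time `1/L106`, would be
  meaningless). Delay times and the optional direct enterocyte→plasma
  routes may legitimately sit at zero and are exempt.
* **Uncertainty.** Parameter FSDs (SE/estimate) come from the scaled
  inverse of the weighted normal-equations matrix in log space (where
  the log-scale SE *is* the fractional SE). Parameters with FSD > 0.5
  are reported as poorly identified.

## Steady state and derived kinetics

With the fitted coefficients and the plasma pool
`M5 = mean plasma retinol × plasma volume` (arithmetic mean of the
study-period samples), flux balance on the storage compartment gives
`M6 = L65·M5/(L56 + L106)`, `DR = L106·M6`, and the catabolic rates
`FCR65 = DR/M6` (identically `L106`) and `FCR55 = DR/M5`. Residence
times come from the negative inverse of the 2×2 exchange matrix;
`TSYS = T55 + T65` holds by construction. Recycling:
`v5 = T55/t½(5) − 1`, `tt5 = T65/v5`. `days_of_stores = M6/DR`, and
`dietary_input_U1 = DR/0.75` is reported as a steady-state extrapolation
(absorbed input must balance disposal), not a fitted quantity.

`TTP50%` is the time at which half of the **absorbed** tracer has made
its *first* arrival in plasma: the cumulative inflow from the absorptive
pathway (hepatic secretion plus the direct route), excluding recycled
returns from stores, normalized by the absorbed fraction. Instantaneous
plasma content never reaches half the absorbed dose in this model class,
so cumulative first-pass arrival is the only self-consistent reading of
"time for 50% to reach plasma"; the choice is configurable in spirit but
hard-wired as the package's definition. The root is found on a dense
grid (step 0.002 d, adaptively extended horizon) by linear interpolation,
accurate well below the 0.01 h reporting tolerance.

## Bioefficacy

Three estimators, all dimensionless fractions of the reference dose's
response:

1. **Model-based (AUC 0→∞).** The AUC of an FD curve equals the tracer's
   oral plasma residence time: absorbed fraction × per-entry plasma
   residence time from the residence-time matrix. With shared exchange
   coefficients the ratio collapses analytically to
   `(1/(1+P11))/0.75`, but the implementation computes it through the
   general residence-time machinery of each arm; the closed form serves
   as a test oracle.
2. **Graphical (truncated trapezoid).** Raw observed points, linear
   trapezoids, no smoothing, integrated to the end of the study (14 d by
   default). Because the curves are parallel over the terminal phase,
   truncation biases numerator and denominator similarly; on simulated
   subjects the graphical estimate sits within ~10% of the model-based
   one and converges to it as the truncation time grows.
3. **Single-sample isotope ratio.** `fd_C5(t)/fd_C10(t)` at a single
   draw, by default day 2, using the observed noisy values — the
   field-deployable shortcut. On synthetic cohorts the day-2 ratio
   *overestimates* the model-based bioefficacy on average (16% vs 12.5%
   in the README's demo run): at day 2 the slower carotene arm is still
   finishing delivery, so the ratio has not yet settled to its parallel
   value. Real cohorts have been reported with the day-2 ratio slightly
   *below* the AUC-based estimate; the discrepancy in direction is a
   known limitation of the synthetic model (see below) and the reason
   the package treats the day-2 ratio as an index to be calibrated, not
   an unbiased estimator.

The µg:µg retinol-activity-equivalent string (`rae_ratio_text()`) is a
presentation convenience using molecular weights 546.8 (β-carotene) and
286.5 (retinol) and the 2:1 maximal cleavage stoichiometry; no kinetic
quantity depends on it.

## The synthetic cohort

`population_config()` encodes the emulated design: n = 30 subjects,
samples at 0, 2, 4, 6, 8, 10, 12 h and 1, 2, 7, 14 d, doses of 2.954
µmol labeled retinyl acetate and 3.237/0.366/0.055 µmol labeled
carotene isomers, body weight 65.2 ± 10 kg, plasma retinol 1.53 ± 0.27
µmol/L truncated to 1.13–2.32, and kinetic parameters dispersed around
the reference cohort means/SDs. Choices:

* **Lognormal, moment-matched, independent.** Several parameters have
  CV > 1 (`L21`: 24.2 ± 39.0), which rules out normal draws; each
  parameter is lognormal with `σ² = ln(1+cv²)`, `µ = ln m − σ²/2`.
  Between-parameter correlations in real cohorts are unknown and are
  omitted — the main visible consequence is an occasional implausibly
  fast-absorbing subject.
* **5% proportional noise.** Each positive FD observation is multiplied
  by mean-1 lognormal noise with CV 0.05, matching the error model the
  weighting assumes; t = 0 stays exactly zero.
* **Clean subjects pass screening by construction.** The reference
  cohort statistics describe subjects *retained* by exactly this kind of
  screen, so `generate_cohort()` redraws clean subjects until their
  curves pass `screen_subject()` (~6% rejection, almost entirely natural
  peaks above the 0.30 bound from the independence simplification).
  Anomalous subjects are clean draws deterministically perturbed by
  `inject_anomaly()` so that exactly the requested reason code fires.

**What passing tests do and do not show.** The generator reproduces the
design's sampling schedule, population dispersion and proportional noise
— not the analytical reality of mass-spectrometry data. In particular,
real early-time reference-arm samples are tiny concentrations dominated
by *absolute* background-subtraction error, far above 5% relative. Under
clean 5% proportional noise the early-phase parameters (`L21`, `L52`,
`L1512`) come out *moderately* identified (median FSD ≈ 0.1–0.2, the
largest in the model but below the 0.5 flag), whereas real-data analyses
report them as frankly unidentifiable. Recovery results on synthetic
cohorts therefore bound what the method can do under idealized noise;
they do not certify early-phase parameter identifiability on real data.

## Problem sizes used in the test suite

Simulation-based tests run at the sizes a desk check needs, chosen once:
the full-recovery test fits all 30 subjects of one generated cohort; the
noise-replicate study uses 50 replicates at the cohort-mean parameters;
oracle comparisons integrate to 2000 d; the conservation property uses
100 random parameter draws; the screening fixture uses 45 subjects with
the canonical 1/3/3/3/1/4 anomaly mix.

## Known limitations

* Independent lognormal population sampling exaggerates extreme
  absorption phenotypes; cohort medians are robust to this, means less
  so.
* Per-subject exchange parameters are not identifiable for fast-exchange
  subjects at this schedule and noise level; the ML optimum can sit far
  up the (L65, L56) valley. The FSD flags mark most such cases and
  cohort medians absorb the rest, but individual `T55`/`v5` values for
  flagged subjects should not be interpreted.
* The day-2 isotope ratio's bias direction differs from published
  real-data experience (see above).
* Nonlinear (saturable) absorption or bioconversion, retinoic acid
  metabolite tracking, and multi-pool extravascular topologies are out
  of scope.
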
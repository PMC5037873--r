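# retikin

Model-based compartmental analysis of plasma retinol tracer kinetics and
relative β-carotene bioefficacy.

## The problem

In a dual-tracer vitamin A study, each participant swallows a single oral
dose of stable-isotope-labeled retinyl acetate together with labeled
β-carotene, and plasma is sampled over two weeks (0–12 h, then 1, 2, 7 and
14 d). Each sample yields two *fraction-of-dose* (FD) curves — retinol
derived from the retinyl acetate reference dose and retinol derived from
the β-carotene dose:

    FD(t) = (tracer concentration − background) × plasma volume / dose,
    plasma volume (L) = 0.0435 × body weight (kg).

`retikin` fits these curves to a six-component linear compartmental model
with transport delays and derives, per subject, the steady-state vitamin A
pools, the disposal rate, recycling parameters, and the relative
β-carotene bioefficacy. It is aimed at researchers analyzing such
dual-isotope studies or planning them via simulation: a synthetic-cohort
generator reproduces the study design end to end, so the whole pipeline is
testable without access to subject-level data.

## The model

Each tracer arm follows the same topology (per-day fractional transfer
coefficients L(I,J), compartments numbered 1–6 for the retinol arm, 11–16
for the β-carotene arm):

    gut (1) ──L21──▶ enterocyte (2) ──L32──▶ [delay DT3] ──▶ liver (4)
     │                     │                                     │ L54
     ▼ L01 = L21/3         └──────────L52──────────┐             ▼
    unabsorbed (25%)                               └──▶ plasma (5) ◀─┐
                                                        │ L65        │ L56
                                                        ▼            │
                                                       stores (6) ───┘
                                                        │ L106
                                                        ▼ irreversible loss

Retinol absorption is fixed at 75% (L01 = L21/3). In the β-carotene arm
the non-converted share of the dose leaves from compartment 11 as
L(0,11) = P(11)·L(12,11), so the absorbed-and-converted fraction is
1/(1 + P11); the plasma/stores exchange coefficients are shared between
arms (L(16,15) = L(6,5), L(15,16) = L(5,6), L(20,16) = L(10,6)).

Estimation is weighted nonlinear least squares (Levenberg–Marquardt in log
space, proportional error with a fractional standard deviation of 0.05):
the retinol arm is fitted first, then the β-carotene arm with the shared
coefficients fixed. Derived quantities use closed forms: steady-state
stores M6 = L65·M5/(L56 + L106) anchored on the plasma pool M5, disposal
rate DR = L106·M6, residence times from the negative inverse of the
exchange matrix, recycling number v(5) = T(5,5)/t½(5) − 1, and
model-based bioefficacy as the ratio of the two arms' oral plasma
residence times T(15,11)/T(5,1) (the AUC(0→∞) ratio). A graphical
truncated trapezoidal AUC ratio and a single-sample day-2 isotope ratio
are computed alongside.

## Worked example

```r
library(retikin)

p <- reference_mean_params()              # cohort-mean coefficients
simulate_fd(p, "C10", c(2, 6, 12, 24, 48) / 24)$fd
#> [1] 0.0019 0.1073 0.1904 0.0834 0.0244

ks <- kinetic_summary(p, M5 = 4.3)        # 4.3 umol plasma retinol pool
```

which prints, at the cohort-mean coefficients: stores `M6 = 103.3` µmol,
disposal rate `DR = 6.19` µmol/d, fractional catabolic rate
`FCR(6,5) = 0.0599` /d, plasma half-life `3.02` h, mean time to plasma
`TTP50% = 10.1` h, recycling number `v5 = 4.51`, recycling time
`tt5 = 3.70` d and `16.7` days of stores. The FD curve peaks (~0.19 of
the dose) around 10–12 h and bends near day 2 as tracer recycles back
from stores. Bioefficacy at the cohort-mean `P11 = 10.9`:

```r
model_based_bioefficacy(p)                #> 0.112  (i.e. 11.2%)
rae_ratio_text(model_based_bioefficacy(p))#> "8.5:1.0 ug"
```

A full synthetic study — generate, screen, fit, summarize:

```r
co <- generate_cohort(population_config(n_subjects = 30, seed = 42))
write_cohort(co, "demo")
rep <- run_pipeline(run_config(subjects_csv = "demo/subjects.csv",
                               curves_csv = "demo/curves.csv",
                               out_dir = "demo/out"))
```

This run keeps all 30 subjects at screening, flags 2 fits as degenerate
(their terminal samples carry no storage-loss information), and reports
cohort means ± SDs over the remaining 28: `M6 = 134 ± 83` µmol,
`DR = 7.4 ± 5.5` µmol/d, `FCR(6,5) = 0.057 ± 0.023` /d, `t½(5) = 3.2 ±
1.6` h, `T(6,5) = 22.6 ± 15.2` d, `tt5 = 4.6 ± 2.1` d, model-based
bioefficacy `12.5% ± 5.1%` and graphical bioefficacy `13.0% ± 5.7%` —
the same ranges the method reports on real cohorts of this design.
Outputs land in `demo/out/`: `qc.csv`, `params.csv`, `summary.csv`,
`bioefficacy.csv` and `report.json`.

A thin command-line wrapper is installed at `inst/cli/retikin`
(`retikin generate|qc|run --config config.json [--seed N] [--out DIR]`).

## Layout

- `R/params.R`, `R/simulate.R` — model definition and FD simulation
  (closed-form upstream chain + adaptive stiff integration).
- `R/preprocess.R` — FD conversion, dose arithmetic, six-rule QC screen.
- `R/fit.R` — two-stage weighted NLS with consensus multi-start.
- `R/summary.R`, `R/bioefficacy.R` — steady state, residence times,
  recycling, TTP50%, three bioefficacy estimators.
- `R/synthetic.R` — population sampling, noise model, anomaly injection.
- `R/pipeline.R` — orchestration, CSV/JSON IO.
- `vignettes/retinol-kinetics.Rmd` — the methods vignette (model,
  assumptions, tuning parameters, limitations).
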
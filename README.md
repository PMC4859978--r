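# radbed

Radiobiological dose-response modelling of tumour control for fractionated
radiotherapy cohorts, built around the linear-quadratic (LQ) and
linear-quadratic-linear (LQ-L) biologically effective dose (BED) models.

## The problem

Stage I non-small-cell lung cancer (NSCLC) is treated both with
conventionally fractionated radiotherapy (CF: many fractions of 1.2–6 Gy) and
with stereotactic hypofractionated schedules (HF: 1–10 fractions above 6 Gy).
Whether a single radiobiological model can describe local tumour control
across this whole fractionation range — and what alpha/beta ratio and
high-dose behaviour that model should have — matters for every isoeffect
calculation used to design hypofractionated schedules. `radbed` is for
radiotherapy physicists and modellers who want to fit, compare and invert
these dose-response models on cohort-level outcome data.

The package ships a curated table of 34 published 3-year local-control (LC)
data points (2319 patients from 31 studies; 8 CF, 26 HF) with BED reported at
two dose points, the isocenter and the PTV edge, and provides a binomial
cohort simulator with the same schema for parameter-recovery studies.

## The models

Dose delivered in `n` fractions of `d` Gy is converted to a biologically
effective dose. Under the LQ model

    BED_LQ = n d (1 + d / (α/β)),

and under the LQ-L model the per-fraction effect continues linearly above a
fraction-dose threshold `D_t`:

    BED_LQL = n [ D_t (1 + D_t/(α/β)) + (1 + 2 D_t/(α/β)) (d − D_t) ],   d ≥ D_t,

matching the LQ branch in value and slope at `d = D_t`. Tumour control
probability is logistic in BED,

    TCP(B) = 1 / (1 + exp(−(B − TCD50)/k)),

where `TCD50` is the BED giving 50% control and `k` (Gy) sets the slope; the
normalised slope at the 50% level is `γ50 = TCD50 / (4k)`. Curves are fitted
by weighted nonlinear least squares on the cohort LC proportions (weights
default to cohort patient counts), with 68% profile-likelihood confidence
intervals, Wald p-values, AIC ranking and nested LQ vs LQ-L likelihood-ratio
tests. The BED models invert in closed form, which gives exact isoeffect
calculations (the dose per fraction needed to reach a target BED) and the
spread in prescribed fraction dose across competing model assumptions.

## Worked example

```r
library(radbed)

fit <- fit_tcp(nsclc_cohort(), variant = "lq", dose_point = "isocenter")
fit
#> Logistic TCP fit: LQ (alpha/beta = 10 Gy), isocenter, all subset
#> 34 data points, n_patients weights
#>       estimate std.error ci68_low ci68_high p.value
#> tcd50   52.227    12.586   25.532    65.542       0
#> k       39.060     9.899   27.489    60.533       0
#> gamma50 0.334 (SE 0.162)   RSS 20.6   logLik 29.28   AIC -52.55
```

A BED of about 52 Gy (alpha/beta = 10 Gy, isocenter) gives 50% three-year
local control, and the shallow slope (`k` near 39 Gy, γ50 ≈ 0.33) reflects
the large dispersion of the collected cohorts: control improves by roughly a
third of a percent per percent dose increase at the steepest point. Both
parameters are significant, but the 68% profile intervals are wide.

The rank correlation between local control and BED10 is stronger at the
isocenter than at the PTV edge:

```r
bed_correlation_scan(nsclc_cohort(), alpha_beta = 10, subsets = "all")
#>   alpha_beta dose_point subset  n   rho  p_value
#> 1         10 isocenter  all    34 0.719  1.7e-06
#> 2         10 ptv_edge   all    34 0.641  4.4e-05
```

And the closed-form isoeffect inversion quantifies how much competing BED
models (LQ with alpha/beta 8, 10, 15 Gy; LQ-L with alpha/beta 10 Gy,
D_t = 11 Gy) disagree about the single-fraction dose needed for a target BED:

```r
model_discrepancy(c(100, 200), n_fractions = 1)
#> [1] 10.46554 30.08175
```

10.5 Gy of disagreement at a 100 Gy target and 30.1 Gy at 200 Gy — model
choice matters enormously for single-fraction prescriptions, while for three
or more fractions the spread shrinks below a few Gy.

`run_full_analysis()` executes every fit variant at both dose points, the
likelihood-ratio tests, the alpha/beta correlation scan, cohort summaries and
the isoeffect table in one call, optionally writing CSVs plus a JSON manifest.

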
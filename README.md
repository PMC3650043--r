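# recurrisk

Risk equations and microsimulation for **first and second cardiovascular
events in type 2 diabetes**.

People with type 2 diabetes face elevated risk of acute myocardial infarction
(AMI), heart failure (HF), stroke and non-acute ischaemic heart disease
(NAIHD) — and once a first event has occurred, the risk of a second event of
the same type is much higher and shaped differently in time. Health-economic
simulation models need equations for *both* transitions. This package
implements a published set of eight Weibull proportional-hazards risk
equations (four event types × first/second event) estimated from a national
diabetes register, in the Prentice–Williams–Peterson (PWP) gap-time
formulation, together with the machinery to use, test and re-estimate them:

* **Risk engine** — linear predictors, hazards, cumulative hazards, interval
  risks, hazard ratios and cumulative-hazard curves for the shipped equation
  library or any user-supplied YAML config.
* **Synthetic cohorts** — a baseline-cohort generator matched to the
  register's published baseline table (per-sex moment-matched truncated
  normals, optional Gaussian copula, exclusive albuminuria categories) plus
  annual random-walk covariate drift.
* **Microsimulation** — patient-level first/second event simulation with
  delayed entry, cross-process history flags and exact inverse-transform
  event times; exports standard counting-process data.
* **Estimation** — maximum-likelihood Weibull PH fitting (`weibull_ph`) with
  left truncation and time-varying covariates, cross-checked against
  independent survival libraries.
* **Validation** — Harrell's C (with delayed-entry pair logic), expected
  event counts from martingale residuals, and a modified Hosmer–Lemeshow
  calibration test over risk deciles.
* **CLI** — `predict`, `make-cohort`, `simulate`, `fit` and `validate`
  subcommands with provenance-stamped artifacts (`inst/cli/recurrisk`).

The audience is modellers building diabetes health-economic simulation models
and methodologists studying recurrent-event risk equations.

## The model

Each equation is a Weibull proportional-hazards model. For a patient with
covariate vector `x`, the hazard at time `t` is

    h(t | x) = exp(LP(t, x)) · p · t^(p−1)

where `p` is the Weibull shape and the linear predictor

    LP(t, x) = c + Σ_k β_k (x_k − m_k) + splines + interactions + time terms

includes mean-centred continuous covariates (centering constants `m_k`),
linear splines (e.g. HbA1c with a knot at 7 % NGSP), covariate×covariate
interactions and covariate×time interactions (linear in `t` or step at a
threshold). The cumulative hazard over an interval `[t0, t1]` is

    H(t0, t1 | x) = ∫ h(t | x) dt ,   risk = 1 − exp(−H).

**Time scales (PWP gap time):** first-event equations run on years since
diabetes diagnosis (with delayed entry at the baseline diabetes duration) and
have `p > 1` (rising hazard); second-event equations run on years since the
first event ("gap time"), with covariates frozen at the first event, and have
`p < 1` (falling hazard — highest right after the first event).

Mean-centering constants are published only for the two AMI equations; the
other six ship with explicit `center: null` placeholders. Hazard ratios and
shape properties never need centering; absolute risks for those equations
require `set_centering()` (your own reference means) or
`synthetic_centering()` (pooled baseline-table means, for demonstrations).

## Worked example

```r
library(recurrisk)
lib <- ndr_equations()
patient <- example_profile()   # male, diagnosed at 48, duration 10 y, HbA1c 8 %,
                               # SBP 150, LDL 2.0, TC/HDL 4.3, macroalbuminuria

# five-year risk of a first AMI between years 10 and 15 since diagnosis
100 * interval_risk(lib[["ami_first"]], patient, 10, 15)
#> [1] 7.319814

# risk of a second AMI in the 5 years after a first AMI in year 10
100 * interval_risk(lib[["ami_second"]], patient, 0, 5)
#> [1] 29.10122

hazard_ratio(lib[["ami_first"]], "systolic_bp", 10)   # per 10 mmHg
#> [1] 1.082204

lib[["ami_first"]]
#> <risk_equation> AMI, first event (time scale: since diagnosis)
#>   constant -7.8187, Weibull shape 2.0537
#>   female                       -0.2318
#>   age_at_diagnosis             +0.0541  (centred at 56.02)
#>   ...
```

Simulate a cohort, refit, and validate:

```r
cohort <- generate_baseline(cohort_spec(n = 20000, seed = 1))
sim    <- simulate_cohort(cohort, synthetic_centering(lib), horizon = 10, seed = 1)
cp     <- export_counting_process(sim, "ami", "first")
fit    <- weibull_ph(survival::Surv(entry, exit, event) ~ female + smoker +
                     macroalbuminuria, collapse_counting_process(cp))
validate_equation(synthetic_centering(lib)[["ami_first"]], cp)
```

Or from the shell:

```sh
inst/cli/recurrisk predict --equation ami:first \
  --profile inst/extdata/worked_example_profile.csv --from 10 --to 15
```

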
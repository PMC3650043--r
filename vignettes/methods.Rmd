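---
title: "Methods: risk equations, simulation and estimation in recurrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk equations, simulation and estimation in recurrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model, the numerical methods and the
design decisions behind the package, in enough detail to audit or
re-implement them. No numerical results are quoted here beyond what the test
suite and `scripts/acceptance.R` compute at run time.

## 1. The model

Each of the eight equations (AMI, heart failure, stroke and non-acute
ischaemic heart disease; first and second events) is a Weibull
proportional-hazards model

$$h(t \mid x) = \exp\{\mathrm{LP}(t, x)\}\, p\, t^{p-1},$$

with shape $p$ and linear predictor

$$\mathrm{LP}(t, x) = c + \sum_k \beta_k (x_k - m_k)
  + \text{splines} + \text{interactions} + \text{time terms}.$$

* **Time scales.** First-event equations use years since diabetes diagnosis;
  a patient diagnosed $d_0$ years before baseline enters observation at
  $t = d_0$ (left truncation / delayed entry). Second-event equations use
  years since the first event of the same type (gap time), the
  Prentice–Williams–Peterson gap-time convention: the clock restarts at the
  first event and the baseline hazard is stratified by event order.
  Covariates in second-event equations are frozen at their values at the
  first event, and `duration_first_event` (diabetes duration at the first
  event, years) enters as a covariate.
* **Shape pattern.** All first-event shapes exceed 1 (hazard rising with
  diabetes duration); all second-event shapes are below 1 (hazard highest
  immediately after the first event and declining).
* **Covariates and units.** Continuous: age at diagnosis (years), diabetes
  duration (years), HbA1c (% NGSP), systolic/diastolic BP (mmHg), LDL
  (mmol/L), total/HDL cholesterol ratio, BMI (kg/m²). Indicators (0/1): sex,
  smoking, macro-/microalbuminuria (mutually exclusive), pre-diagnosis event
  history per event type, and dynamic post-diagnosis flags (`*_post`) that
  flip when a first event of another type occurs during follow-up.
* **Functional forms.** Linear splines split a covariate at a knot into
  `min(x, knot)` and `max(x - knot, 0)` (knots: HbA1c 7, systolic BP 140,
  diastolic BP 80). Covariate×time terms are linear in $t$ or steps at a
  threshold (1 or 3 years on the gap scale). Interactions multiply the
  *centred* covariate values.
* **Centering.** Continuous covariates are mean-centred so that the constant
  $c$ is the log baseline-hazard scale at the reference profile. Centering
  constants are shipped where published (the AMI equations); elsewhere the
  config stores explicit `center: null` placeholders and the engine raises a
  configuration error if an absolute risk is requested before
  `set_centering()` or `synthetic_centering()` supplies them. Hazard ratios
  and shapes are centering-invariant.

Risk over an interval for a patient event-free at $t_0$ with covariates held
at profile values:

$$\Pr(\text{event in } (t_0, t_1]) = 1 - \exp\{-H(t_0, t_1)\},\qquad
  H = \int_{t_0}^{t_1} h(t \mid x)\,dt.$$

## 2. Numerical evaluation of cumulative hazards

The linear predictor decomposes as $\mathrm{LP}(t) = b + s\,t + \text{steps}$.
The integral is split at step thresholds; on each piece:

* if $s = 0$ the piece is closed-form: $e^{b'}(t_1^p - t_0^p)$;
* otherwise we substitute $u = t^p$, which removes the $t^{p-1}$ factor (and
  with it the integrable singularity at $t = 0$ when $p < 1$), leaving the
  smooth integrand $\exp(b' + s\,u^{1/p})$, integrated by 40-node
  Gauss–Legendre quadrature (nodes cached). Agreement with adaptive
  quadrature is at machine precision for the shipped equations' parameter
  ranges; the test suite checks $10^{-6}$ relative agreement and $10^{-8}$
  additivity.

Event-time sampling inverts $H(a, t) = E$, closed-form when the linear
predictor is time-constant and by vectorised bisection on the monotone map
$t \mapsto H(a,t)$ otherwise (60 halvings, interval width $< 10^{-12}$).

## 3. Synthetic cohort generator

`cohort_spec()` / `generate_baseline()` emulate the *marginal structure* of
the source register's published baseline table, not real patients: per-sex
means and SDs of the continuous covariates, per-sex smoking and albuminuria
prevalences, and the sex split. Choices:

* **Moment-matched truncated normals.** Each continuous covariate is drawn
  from a normal truncated to plausibility bounds, with the underlying
  $(\mu, \sigma)$ solved (Nelder–Mead on the truncated-moment equations) so
  the *post-truncation* mean and SD equal the published targets. Naive
  truncation would, e.g., inflate diabetes duration (target mean ≈ 9 y,
  SD ≈ 7 y against a bound at 0) by more than a year.
* **Correlation.** Independent by default (the baseline table publishes only
  marginals); a Gaussian copula over the continuous covariates is available
  (`correlation =`). Inverse-CDF sampling makes the copula's rank
  correlations exact.
* **Albuminuria** is one three-level categorical (none/micro/macro) sampled
  from a single uniform, so categories are exclusive by construction.
* **What is not emulated:** joint covariate distributions, measurement
  error, register missingness, secular trends, and mortality.

`annual_covariate_update()` applies optional per-year Gaussian random-walk
drift to time-dependent continuous covariates (clipped to bounds); sex, age
at diagnosis and indicators are immutable. Default is zero drift.

## 4. Microsimulation

`simulate_cohort()` runs the four first-event processes in parallel on the
diagnosis time scale, coupled only through the dynamic `*_post` flags, then
(optionally) one second-event process per type on the gap scale.

* **Exact annual sampling.** Within each year the conditional survival is
  inverted against a fresh Exp(1) draw; by memorylessness, fresh draws per
  year sample the same process as a single draw while letting covariates
  refresh annually.
* **Within-year coupling.** When several processes draw candidate events in
  the same year, the earliest commits, flags flip at that instant, and the
  remaining processes re-draw from the commit time under the updated flags —
  valid because, conditional on survival to the commit time, the future is
  independent of the discarded draw.
* **Second events** are sampled in one shot on the gap scale (no annual
  refresh: covariates are frozen at the first event by model convention).
* **Censoring:** administrative at the horizon plus optional exponential
  withdrawal (`dropout_rate`).

`export_counting_process()` emits `(patient_id, entry, exit, event,
covariates)` intervals: annual cuts (matching the annual covariate refresh)
*plus* cuts at history-flag flip times, so the linear predictor is exactly
constant within every record — the property the likelihood below assumes.
`collapse_counting_process()` merges contiguous identical-covariate records;
the Weibull likelihood is invariant to this.

## 5. Estimation

`weibull_ph()` maximises the counting-process log-likelihood

$$\ell(\beta, p) = \sum_i d_i\{\log p + (p-1)\log b_i + \eta_i\}
 - \sum_i e^{\eta_i}\,(b_i^p - a_i^p),$$

over intervals $[a_i, b_i]$ with event flags $d_i$ and $\eta_i = x_i'\beta$
constant within an interval. This handles right censoring, delayed entry and
time-varying covariates in one form. The shape is parameterised as
$\log p$; optimisation is BFGS with the analytic gradient and a numeric
Hessian for standard errors. Starting values: zero coefficients with the
exponential-model MLE for the intercept. The fit is refused (with the
offending columns named) if the design is rank deficient. PWP strata are fit
as separate calls per event order on each order's own time scale.

The implementation is cross-checked in the test suite against
`flexsurv::flexsurvreg(dist = "weibullPH")` (same parameterisation) and
`survival::survreg` (AFT parameterisation, mapped by $p = 1/\text{scale}$,
$\beta_{PH} = -\beta_{AFT}\,p$).

## 6. Validation statistics

* **Harrell's C** (`harrell_c`): a pair is usable when the shorter follow-up
  ends in an event *and* the other subject was already at risk at that time
  (the second condition matters under delayed entry); score ties count ½;
  tied event/censoring times are excluded. The standard error is a
  Noether-type asymptotic form built from per-subject concordance
  components; the convention is recorded in the output.
* **Expected events** (`expected_events`): observed count minus martingale
  residual, i.e. the model cumulative hazard over the subject's at-risk
  interval.
* **Modified Hosmer–Lemeshow** (`modified_hl_test`):
  $X^2 = \sum_g (O_g - E_g)^2 / E_g$ over groups formed by deciles of a risk
  score (stable tie-breaking). Degrees of freedom default to
  `n_groups − 2`, the convention when the model was fitted to the same data;
  for an external/fixed model pass `df = n_groups` (since
  $\operatorname{Var}(O_g - E_g) \approx E_g$ under the model, each group
  contributes a full $\chi^2_1$). The choice is reported in the result.
* **`validate_equation`** collapses counting-process data to one record per
  subject and scores each subject by model risk over a *common fixed horizon
  from entry*, never over the subject's own observed follow-up — a score
  that depends on the realised follow-up length leaks outcome information
  and destroys both discrimination and the calibration test's null
  behaviour.

## 7. Problem sizes and costs

Defaults were chosen so that a laptop-scale run is comfortable: baseline
generation and a 10-year simulation of a 20 000-patient cohort take a few
seconds; a full 13-parameter fit to the exported (collapsed)
counting-process data takes ~2–3 s; the 50-replicate recovery study in the
test suite runs in under ten minutes. These sizes are package choices for
testing, not claims about the source register.

## 8. Limitations

* Absolute risks outside the AMI equations depend on user-supplied centering
  constants; `synthetic_centering()` is a demonstration stand-in.
* No mortality process: follow-up ends by event, withdrawal or horizon, so
  simulated incidences are cause-specific under censoring, not competing-risk
  cumulative incidences.
* The cohort generator reproduces marginals (and, optionally, a specified
  copula), not the register's joint distribution.
* Second events end a patient's process; third and later events are out of
  scope, as are costs, utilities and treatment effects.
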
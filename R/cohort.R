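# Synthetic baseline cohorts with the marginal structure of the training
# sample's baseline table: per-sex means/SDs for continuous covariates,
# per-sex smoking and albuminuria prevalences. Continuous covariates are drawn
# from truncated normals whose post-truncation mean and SD are moment-matched
# to the targets (otherwise heavily truncated covariates such as diabetes
# duration would miss their published mean by more than a year).

.table1_defaults <- list(
  n_male = 12578, n_female = 9197,
  male = list(
    mean = c(age_at_diagnosis = 55.36, diabetes_duration = 8.92, hba1c = 7.34,
             bmi = 28.84, systolic_bp = 141.47, diastolic_bp = 78.85,
             tc_hdl = 4.23, ldl = 2.86),
    sd = c(age_at_diagnosis = 9.28, diabetes_duration = 7.14, hba1c = 1.18,
           bmi = 4.44, systolic_bp = 17.51, diastolic_bp = 9.40,
           tc_hdl = 1.29, ldl = 0.88),
    smoker = 0.1507, macroalbuminuria = 0.0709, microalbuminuria = 0.2016),
  female = list(
    mean = c(age_at_diagnosis = 57.15, diabetes_duration = 9.02, hba1c = 7.37,
             bmi = 29.67, systolic_bp = 143.76, diastolic_bp = 77.11,
             tc_hdl = 3.95, ldl = 3.00),
    sd = c(age_at_diagnosis = 9.55, diabetes_duration = 7.17, hba1c = 1.18,
           bmi = 5.55, systolic_bp = 18.66, diastolic_bp = 9.38,
           tc_hdl = 1.25, ldl = 0.93),
    smoker = 0.1411, macroalbuminuria = 0.0403, microalbuminuria = 0.1380)
)

.table1_pooled_means <- function() {
  d <- .table1_defaults
  w <- d$n_male / (d$n_male + d$n_female)
  as.list(w * d$male$mean + (1 - w) * d$female$mean)
}

#' Specify a synthetic baseline cohort
#'
#' Defaults reproduce the training-sample baseline table: per-sex means and
#' SDs of the continuous covariates and per-sex smoking/albuminuria
#' prevalences. Pre-diagnosis event-history prevalences default to 0 and are
#' configurable.
#'
#' @param n Number of patients.
#' @param prop_female Proportion female (default from the table's sex split).
#' @param male,female Per-sex parameter lists with elements `mean` and `sd`
#'   (named numeric vectors over the continuous covariates) and scalar
#'   prevalences `smoker`, `macroalbuminuria`, `microalbuminuria`.
#' @param history Named prevalences of pre-diagnosis event history
#'   (`ami`, `hf`, `stroke`, `naihd`); default all 0.
#' @param correlation Optional correlation matrix over the continuous
#'   covariates (Gaussian copula); default independent.
#' @param bounds Named list of truncation bounds overriding the defaults.
#' @param seed Random seed used by [generate_baseline()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, prop_female = NULL, male = NULL, female = NULL,
                        history = c(ami = 0, hf = 0, stroke = 0, naihd = 0),
                        correlation = NULL, bounds = list(), seed = 1L) {
  d <- .table1_defaults
  spec <- list(
    n = as.integer(n),
    prop_female = prop_female %||% (d$n_female / (d$n_male + d$n_female)),
    male = utils::modifyList(d$male, male %||% list()),
    female = utils::modifyList(d$female, female %||% list()),
    history = history,
    correlation = correlation,
    bounds = utils::modifyList(.covariate_bounds, bounds),
    seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n < 1) stop("cohort spec: n must be >= 1")
  probs <- c(spec$prop_female, spec$history,
             vapply(list(spec$male, spec$female), function(s)
               c(s$smoker, s$macroalbuminuria, s$microalbuminuria), numeric(3)))
  if (any(probs < 0 | probs > 1)) stop("cohort spec: probabilities must lie in [0, 1]")
  for (s in list(spec$male, spec$female)) {
    if (any(s$sd <= 0)) stop("cohort spec: SDs must be positive")
    if (s$macroalbuminuria + s$microalbuminuria > 1)
      stop("cohort spec: macro- plus microalbuminuria prevalence exceeds 1")
  }
  if (!is.null(spec$correlation)) {
    R <- spec$correlation
    if (!isSymmetric(R) || any(diag(R) != 1))
      stop("cohort spec: correlation must be a symmetric matrix with unit diagonal")
  }
  invisible(spec)
}

# (mu, sigma) of the underlying normal such that the [a, b]-truncated normal
# has the target mean and SD
.truncnorm_match <- function(m, s, a, b) {
  moments <- function(mu, sig) {
    al <- (a - mu) / sig; be <- (b - mu) / sig
    Z <- stats::pnorm(be) - stats::pnorm(al)
    dal <- stats::dnorm(al); dbe <- stats::dnorm(be)
    mean <- mu + sig * (dal - dbe) / Z
    v <- sig^2 * (1 + (al * dal - be * dbe) / Z - ((dal - dbe) / Z)^2)
    c(mean, if (is.finite(v) && v > 0) sqrt(v) else NA_real_)
  }
  obj <- function(par) {
    mm <- moments(par[1], exp(par[2]))
    if (any(!is.finite(mm))) return(1e10)
    (mm[1] - m)^2 / s^2 + (mm[2] / s - 1)^2
  }
  fit <- stats::optim(c(m, log(s)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# inverse-CDF draw from the matched truncated normal given uniforms
.truncnorm_draw <- function(u, m, s, a, b) {
  par <- .truncnorm_match(m, s, a, b)
  plo <- stats::pnorm(a, par[1], par[2])
  phi <- stats::pnorm(b, par[1], par[2])
  stats::qnorm(plo + u * (phi - plo), par[1], par[2])
}

#' Generate a synthetic baseline cohort
#'
#' Draws `spec$n` patient profiles: sex by Bernoulli, continuous covariates
#' from moment-matched truncated normals (through a Gaussian copula when a
#' correlation matrix is supplied), smoking by per-sex Bernoulli, albuminuria
#' as a single three-level categorical (none/micro/macro) so the categories
#' are mutually exclusive, and pre-diagnosis history flags by Bernoulli.
#' Reproducible for a fixed `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of patient profiles (see [validate_profiles()]), with
#'   a `patient_id` column and all dynamic `_post` flags initialised to 0.
#' @export
generate_baseline <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n
  female <- stats::rbinom(n, 1, spec$prop_female)
  covs <- names(spec$male$mean)
  k <- length(covs)
  # uniforms shared across sexes, per covariate (copula-correlated if asked)
  if (is.null(spec$correlation)) {
    U <- matrix(stats::runif(n * k), n, k, dimnames = list(NULL, covs))
  } else {
    R <- spec$correlation[covs, covs]
    Z <- matrix(stats::rnorm(n * k), n, k) %*% chol(R)
    U <- stats::pnorm(Z)
    colnames(U) <- covs
  }
  X <- matrix(NA_real_, n, k, dimnames = list(NULL, covs))
  for (sex in 0:1) {
    idx <- which(female == sex)
    if (!length(idx)) next
    par <- if (sex == 1) spec$female else spec$male
    for (v in covs)
      X[idx, v] <- .truncnorm_draw(U[idx, v], par$mean[[v]], par$sd[[v]],
                                   spec$bounds[[v]][1], spec$bounds[[v]][2])
  }
  p_macro <- ifelse(female == 1, spec$female$macroalbuminuria, spec$male$macroalbuminuria)
  p_micro <- ifelse(female == 1, spec$female$microalbuminuria, spec$male$microalbuminuria)
  u_alb <- stats::runif(n)
  macro <- as.integer(u_alb < p_macro)
  micro <- as.integer(u_alb >= p_macro & u_alb < p_macro + p_micro)
  p_smoke <- ifelse(female == 1, spec$female$smoker, spec$male$smoker)
  smoker <- stats::rbinom(n, 1, p_smoke)
  out <- data.frame(patient_id = seq_len(n), female = female)
  for (v in covs) out[[v]] <- X[, v]
  out$smoker <- smoker
  out$macroalbuminuria <- macro
  out$microalbuminuria <- micro
  for (ev in .recurrisk_events) {
    out[[paste0(ev, "_history")]] <- stats::rbinom(n, 1, spec$history[[ev]])
    out[[paste0(ev, "_post")]] <- 0
  }
  validate_profiles(out, spec$bounds)
  out
}

#' Annual covariate drift
#'
#' Applies one year of random-walk drift to time-dependent continuous
#' covariates (the equations treat most clinical covariates as annually
#' updated values). The default drift is zero, i.e. the identity. Sex and age
#' at diagnosis are immutable; indicators are never drifted.
#'
#' @param profiles Data frame of profiles.
#' @param drift Named list: covariate name -> `list(sd = , mean = 0)` giving
#'   the per-year random-walk increment distribution.
#' @param bounds Named truncation bounds; drifted values are clipped into
#'   them.
#' @return The updated profiles.
#' @export
annual_covariate_update <- function(profiles, drift = list(),
                                    bounds = .covariate_bounds) {
  if (!length(drift)) return(profiles)
  immutable <- c("female", "age_at_diagnosis", .binary_covariates)
  bad <- intersect(names(drift), immutable)
  if (length(bad))
    stop(sprintf("drift not allowed for immutable/indicator covariates: %s",
                 paste(bad, collapse = ", ")))
  n <- nrow(profiles)
  for (v in names(drift)) {
    if (!v %in% names(profiles))
      stop(sprintf("drift names unknown covariate '%s'", v))
    d <- drift[[v]]
    x <- profiles[[v]] + stats::rnorm(n, d$mean %||% 0, d$sd)
    if (!is.null(bounds[[v]]))
      x <- pmin(pmax(x, bounds[[v]][1]), bounds[[v]][2])
    profiles[[v]] <- x
  }
  profiles
}

#' Read a cohort spec from YAML
#'
#' @param path YAML file with keys matching the arguments of [cohort_spec()].
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort spec not found: %s", path))
  raw <- yaml::read_yaml(path)
  # a bare `n:` key parses as YAML 1.1 boolean FALSE; accept either spelling
  if (is.null(raw$n) && !is.null(raw[["FALSE"]])) raw$n <- raw[["FALSE"]]
  if (is.null(raw$n)) stop("cohort spec: missing 'n'")
  fix_sex <- function(s) {
    if (is.null(s)) return(NULL)
    if (!is.null(s$mean)) s$mean <- unlist(s$mean)
    if (!is.null(s$sd)) s$sd <- unlist(s$sd)
    s
  }
  cohort_spec(n = raw$n,
              prop_female = raw$prop_female,
              male = fix_sex(raw$male), female = fix_sex(raw$female),
              history = if (is.null(raw$history))
                c(ami = 0, hf = 0, stroke = 0, naihd = 0) else unlist(raw$history),
              correlation = if (is.null(raw$correlation)) NULL
                else matrix(unlist(raw$correlation$values),
                            length(raw$correlation$covariates),
                            dimnames = rep(list(raw$correlation$covariates), 2)),
              bounds = lapply(raw$bounds %||% list(), unlist),
              seed = raw$seed %||% 1L)
}
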
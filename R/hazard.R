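# Hazard, cumulative hazard and interval risk for a risk_equation.
#
# With the linear predictor decomposed as LP(t) = base + slope*t + steps, the
# cumulative hazard over [t0, t1] is
#   H = int exp(LP(t)) * p * t^(p-1) dt.
# Step terms split the interval at their thresholds; on each piece LP is
# base' + slope*t. With slope == 0 the piece integrates in closed form,
# exp(base') * (b^p - a^p); otherwise we substitute u = t^p (which removes the
# t^(p-1) singularity at 0 for p < 1) and apply Gauss-Legendre quadrature to
# the smooth integrand exp(base' + slope * u^(1/p)).

.gl_nodes_cache <- new.env(parent = emptyenv())

.gl_nodes <- function(k = 40) {
  key <- as.character(k)
  if (is.null(.gl_nodes_cache[[key]]))
    .gl_nodes_cache[[key]] <- pracma::gaussLegendre(k, -1, 1)
  .gl_nodes_cache[[key]]
}

# vectorised piece integral over [lo, hi] (vectors), LP = base + slope * t
.cumhaz_piece <- function(base, slope, p, lo, hi) {
  out <- numeric(length(base))
  ok <- hi > lo
  if (!any(ok)) return(out)
  if (all(slope == 0)) {
    out[ok] <- exp(base[ok]) * (hi[ok]^p - lo[ok]^p)
    return(out)
  }
  gl <- .gl_nodes(40)
  ulo <- lo[ok]^p
  uhi <- hi[ok]^p
  mid <- (uhi + ulo) / 2
  half <- (uhi - ulo) / 2
  acc <- numeric(sum(ok))
  b <- base[ok]; s <- slope[ok]
  for (k in seq_along(gl$x)) {
    u <- mid + half * gl$x[k]
    acc <- acc + gl$w[k] * exp(b + s * u^(1 / p))
  }
  out[ok] <- acc * half
  out
}

# vectorised cumulative hazard from lp components; t0/t1 recycled to n
cumhaz_comp <- function(comp, t0, t1) {
  n <- length(comp$base)
  t0 <- rep_len(t0, n)
  t1 <- rep_len(t1, n)
  if (any(t0 < 0) || any(t1 < t0))
    stop("domain error: need 0 <= t0 <= t1")
  p <- comp$shape
  thr <- sort(unique(vapply(comp$steps, `[[`, 0, "threshold")))
  seg <- c(0, thr, Inf)
  H <- numeric(n)
  for (j in seq_len(length(seg) - 1L)) {
    lo <- pmax(t0, seg[j])
    hi <- pmin(t1, seg[j + 1L])
    act <- hi > lo
    if (!any(act)) next
    base <- comp$base
    for (st in comp$steps)
      if (st$threshold <= seg[j]) base <- base + st$amount
    H <- H + .cumhaz_piece(base, comp$slope, p, lo, hi)
  }
  H
}

#' Cumulative hazard over an interval
#'
#' Integrated hazard of a risk equation over `[t0, t1]` on the equation's own
#' time scale, for one or more patient profiles. Step-form time interactions
#' are handled by exact piecewise closed forms split at their thresholds;
#' continuous covariate-by-time terms are integrated by Gauss-Legendre
#' quadrature after the substitution `u = t^shape`.
#'
#' @inheritParams linear_predictor
#' @param t0,t1 Interval bounds in years, `0 <= t0 <= t1`. Scalars or vectors
#'   recycled against the profile rows.
#' @return Numeric vector of nonnegative cumulative hazards.
#' @export
cumulative_hazard <- function(eq, profiles, t0, t1) {
  cumhaz_comp(lp_components(eq, profiles), t0, t1)
}

#' Probability of an event within an interval
#'
#' `1 - exp(-H)` where `H` is [cumulative_hazard()] over `[t0, t1]`,
#' i.e. the probability of at least one event in the interval for a patient
#' event-free at `t0`, covariates held at their profile values.
#'
#' @inheritParams cumulative_hazard
#' @return Numeric vector of probabilities in `[0, 1)`.
#' @export
interval_risk <- function(eq, profiles, t0, t1) {
  1 - exp(-cumulative_hazard(eq, profiles, t0, t1))
}

#' Instantaneous hazard rate
#'
#' `exp(LP(t)) * p * t^(p-1)`, in events per person-year. For second-event
#' equations (`p < 1`) the hazard is unbounded at gap time 0, so evaluation at
#' `t = 0` is disallowed there.
#'
#' @inheritParams linear_predictor
#' @param t Time(s) in years on the equation's time scale. A vector is allowed
#'   when `profiles` has a single row (and vice versa).
#' @return Numeric vector of hazard rates.
#' @export
hazard_rate <- function(eq, profiles, t) {
  comp <- lp_components(eq, profiles)
  n <- max(length(comp$base), length(t))
  if (!length(comp$base) %in% c(1L, n) || !length(t) %in% c(1L, n))
    stop("profiles and t have incompatible lengths")
  t <- rep_len(t, n)
  if (any(t < 0)) stop("domain error: t must be nonnegative")
  if (eq$shape < 1 && any(t == 0))
    stop("domain error: hazard is unbounded at t = 0 when shape < 1")
  base <- rep_len(comp$base, n)
  slope <- rep_len(comp$slope, n)
  lp <- base + slope * t
  for (st in comp$steps) lp <- lp + rep_len(st$amount, n) * (t > st$threshold)
  exp(lp) * eq$shape * t^(eq$shape - 1)
}

#' Hazard ratio for a covariate contrast
#'
#' For a covariate entering only as a plain proportional term the ratio is
#' `exp(coef * delta)` and needs no reference. A covariate involved in a
#' spline, interaction or covariate-by-time term has no single hazard ratio;
#' for those a reference profile and time must be supplied, and the ratio of
#' the two hazards is returned.
#'
#' @inheritParams linear_predictor
#' @param covariate Covariate name.
#' @param delta Difference in covariate units (e.g. `10` for a 10-mmHg
#'   systolic BP contrast, `1` for an indicator).
#' @param at Optional one-row reference profile, required for
#'   spline/interaction/time-interaction covariates.
#' @param t Optional reference time (same requirement).
#' @return A positive scalar.
#' @export
hazard_ratio <- function(eq, covariate, delta, at = NULL, t = NULL) {
  if (!covariate %in% equation_covariates(eq))
    stop(sprintf("covariate '%s' is not in equation %s_%s",
                 covariate, eq$event, eq$order))
  if (delta == 0) return(1)
  in_plain <- vapply(eq$terms, function(tm) tm$covariate == covariate, TRUE)
  elsewhere <-
    any(vapply(eq$splines, function(s) s$covariate == covariate, TRUE)) ||
    any(vapply(eq$interactions, function(ia) covariate %in% ia$covariates, TRUE)) ||
    any(vapply(eq$time_terms,
               function(tt) identical(tt$covariate, covariate), TRUE))
  if (!elsewhere && any(in_plain)) {
    coef <- eq$terms[[which(in_plain)[1]]]$coef
    return(exp(coef * delta))
  }
  if (is.null(at) || is.null(t))
    stop(sprintf(paste0("reference required: covariate '%s' has spline, ",
                        "interaction or time-interaction terms; supply 'at' ",
                        "(reference profile) and 't'"), covariate))
  shifted <- at
  shifted[[covariate]] <- shifted[[covariate]] + delta
  hazard_rate(eq, shifted, t) / hazard_rate(eq, at, t)
}

#' Cumulative hazard curve
#'
#' Evaluates the cumulative hazard from `t0` on a regular grid up to `t1`,
#' e.g. to draw predicted cumulative-hazard curves for first and second
#' events.
#'
#' @inheritParams cumulative_hazard
#' @param step Grid spacing in years (> 0).
#' @return A data frame with columns `time` and `cumhaz`; the final row equals
#'   `cumulative_hazard(eq, profiles, t0, t1)`.
#' @export
cumulative_hazard_curve <- function(eq, profiles, t0, t1, step = 0.25) {
  stopifnot(nrow(profiles) == 1, step > 0)
  grid <- unique(c(seq(t0, t1, by = step), t1))
  comp <- lp_components(eq, profiles)
  H <- vapply(grid, function(tt) cumhaz_comp(comp, t0, tt), 0)
  data.frame(time = grid, cumhaz = H)
}

# Solve H(a, t) = target on [a, b] for selected profile rows (used by the
# microsimulator; caller guarantees H(a, b) >= target). Closed form when the
# linear predictor is constant in time, otherwise vectorised bisection on the
# monotone map t -> H(a, t).
solve_event_time <- function(comp, idx, a, b, target) {
  p <- comp$shape
  m <- length(idx)
  a <- rep_len(a, m); b <- rep_len(b, m)
  target <- rep_len(target, m)
  simple <- length(comp$steps) == 0 && all(comp$slope[idx] == 0)
  if (simple) {
    base <- comp$base[idx]
    return((a^p + target / exp(base))^(1 / p))
  }
  sub <- list(base = comp$base[idx], slope = comp$slope[idx],
              steps = lapply(comp$steps, function(st)
                list(threshold = st$threshold, amount = st$amount[idx])),
              shape = p)
  lo <- a
  hi <- b
  for (it in 1:60) {
    if (max(hi - lo) < 1e-12) break
    mid <- (lo + hi) / 2
    under <- cumhaz_comp(sub, a, mid) < target
    lo[under] <- mid[under]
    hi[!under] <- mid[!under]
  }
  (lo + hi) / 2
}
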
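# A risk_equation is one event-specific Weibull proportional-hazards equation:
# hazard h(t) = exp(LP(t)) * p * t^(p-1) on its own time scale (years since
# diagnosis for first events, years since the first event for second events).
# LP(t) = constant + sum of coefficient * centred covariate / spline piece /
# interaction, plus covariate-by-time terms (linear in t, or step indicators
# t > threshold).

#' Construct a risk equation
#'
#' @param event Event type: one of `"ami"`, `"hf"`, `"stroke"`, `"naihd"`.
#' @param order `"first"` or `"second"` (the PWP gap-time stratum).
#' @param constant Intercept of the linear predictor (log-hazard scale).
#' @param shape Weibull shape parameter `p` (> 0). Hazard increases with time
#'   when `p > 1` and decreases when `p < 1`.
#' @param terms List of plain terms, each `list(covariate=, coef=, center=)`;
#'   `center` is required (possibly `NA` as a placeholder) for continuous
#'   covariates and absent/ignored for indicators.
#' @param splines List of linear-spline terms, each
#'   `list(covariate=, knot=, coef_low=, coef_high=, center_low=, center_high=)`.
#'   The basis is `min(x, knot)` / `max(x - knot, 0)`, continuous at the knot.
#' @param interactions List of covariate-by-covariate products, each
#'   `list(covariates = c(a, b), coef=)`. Continuous components are centred at
#'   their main-effect centering constant when one is defined.
#' @param time_terms List of covariate-by-time terms, each
#'   `list(covariate=, coef=, form=, threshold=)`. `form = "linear"` adds
#'   `coef * x * t` to the linear predictor; `form = "step"` adds
#'   `coef * x * (t > threshold)`. `covariate = NA` means a bare time term
#'   (`x = 1`).
#' @param time_scale `"since_diagnosis"` or `"since_first_event"`.
#' @param strict If `TRUE` (default), enforce the shape-by-order pattern of
#'   the published equations (first events `p > 1`, second events `p < 1`).
#'   Set to `FALSE` for equations estimated from other data.
#' @return An object of class `risk_equation`.
#' @export
risk_equation <- function(event, order, constant, shape,
                          terms = list(), splines = list(),
                          interactions = list(), time_terms = list(),
                          time_scale = if (order == "first")
                            "since_diagnosis" else "since_first_event",
                          strict = TRUE) {
  event <- match.arg(event, .recurrisk_events)
  order <- match.arg(order, c("first", "second"))
  time_scale <- match.arg(time_scale, c("since_diagnosis", "since_first_event"))
  if (!is.finite(constant)) stop("constant must be finite")
  if (!is.finite(shape) || shape <= 0) stop("shape must be a positive number")
  if (strict) {
    if (order == "first" && shape <= 1)
      stop("first-event equations have shape > 1; use strict = FALSE to override")
    if (order == "second" && shape >= 1)
      stop("second-event equations have shape < 1; use strict = FALSE to override")
  }
  canon_term <- function(tm) {
    if (is.null(tm$covariate) || !nzchar(tm$covariate))
      stop("term without a covariate name")
    if (!is.finite(tm$coef)) stop(sprintf("non-finite coefficient for '%s'", tm$covariate))
    center <- if (is.null(tm$center)) NA_real_ else as.numeric(tm$center)
    if (is_binary_covariate(tm$covariate)) center <- 0
    list(covariate = tm$covariate, coef = as.numeric(tm$coef), center = center)
  }
  terms <- lapply(terms, canon_term)
  splines <- lapply(splines, function(s) {
    if (!is.finite(s$knot)) stop(sprintf("spline knot for '%s' must be finite", s$covariate))
    list(covariate = s$covariate, knot = as.numeric(s$knot),
         coef_low = as.numeric(s$coef_low), coef_high = as.numeric(s$coef_high),
         center_low = if (is.null(s$center_low)) NA_real_ else as.numeric(s$center_low),
         center_high = if (is.null(s$center_high)) NA_real_ else as.numeric(s$center_high))
  })
  interactions <- lapply(interactions, function(ia) {
    if (length(ia$covariates) != 2) stop("interaction must name exactly two covariates")
    list(covariates = as.character(ia$covariates), coef = as.numeric(ia$coef))
  })
  time_terms <- lapply(time_terms, function(tt) {
    form <- match.arg(tt$form, c("linear", "step"))
    thr <- if (is.null(tt$threshold)) NA_real_ else as.numeric(tt$threshold)
    if (form == "step" && (!is.finite(thr) || thr <= 0))
      stop("step-form time terms need a positive threshold (years)")
    cov <- if (is.null(tt$covariate) || is.na(tt$covariate)) NA_character_ else tt$covariate
    list(covariate = cov, coef = as.numeric(tt$coef), form = form, threshold = thr)
  })
  structure(
    list(event = event, order = order, time_scale = time_scale,
         constant = as.numeric(constant), shape = as.numeric(shape),
         terms = terms, splines = splines, interactions = interactions,
         time_terms = time_terms),
    class = "risk_equation")
}

#' @export
print.risk_equation <- function(x, ...) {
  cat(sprintf("<risk_equation> %s, %s event (time scale: %s)\n",
              toupper(x$event), x$order, gsub("_", " ", x$time_scale)))
  cat(sprintf("  constant %.4f, Weibull shape %.4f\n", x$constant, x$shape))
  for (tm in x$terms)
    cat(sprintf("  %-28s %+.4f%s\n", tm$covariate, tm$coef,
                if (is.na(tm$center)) "  [centering not set]"
                else if (tm$center != 0) sprintf("  (centred at %.4g)", tm$center)
                else ""))
  for (s in x$splines)
    cat(sprintf("  %s spline at %g: %+0.4f (<=) / %+0.4f (>)%s\n",
                s$covariate, s$knot, s$coef_low, s$coef_high,
                if (is.na(s$center_low)) "  [centering not set]" else ""))
  for (ia in x$interactions)
    cat(sprintf("  %s x %s %+0.4f\n", ia$covariates[1], ia$covariates[2], ia$coef))
  for (tt in x$time_terms)
    cat(sprintf("  %s x time%s %+0.4f\n",
                if (is.na(tt$covariate)) "(baseline)" else tt$covariate,
                if (tt$form == "step") sprintf(" > %g y", tt$threshold) else "",
                tt$coef))
  invisible(x)
}

# All covariate names an equation references.
equation_covariates <- function(eq) {
  unique(c(
    vapply(eq$terms, `[[`, "", "covariate"),
    vapply(eq$splines, `[[`, "", "covariate"),
    unlist(lapply(eq$interactions, `[[`, "covariates")),
    stats::na.omit(vapply(eq$time_terms, `[[`, "", "covariate"))
  ))
}

.get_column <- function(eq, profiles, v) {
  if (!v %in% names(profiles))
    stop(sprintf("incomplete profile: equation %s_%s needs covariate '%s'",
                 eq$event, eq$order, v))
  x <- profiles[[v]]
  if (any(!is.finite(x)))
    stop(sprintf("non-finite values in covariate '%s'", v))
  x
}

.need_center <- function(eq, v, center) {
  if (is.na(center))
    stop(sprintf(paste0("centering constant for continuous covariate '%s' is ",
                        "not set in equation %s_%s; supply it with set_centering()"),
                 v, eq$event, eq$order))
  center
}

# Centred value of a covariate as it enters interaction terms: indicators
# unchanged, continuous covariates centred at their main-effect constant when
# one is defined in the same equation.
.interaction_value <- function(eq, profiles, v) {
  x <- .get_column(eq, profiles, v)
  if (is_binary_covariate(v)) return(x)
  for (tm in eq$terms)
    if (tm$covariate == v) return(x - .need_center(eq, v, tm$center))
  x
}

#' Spline basis transform
#'
#' Splits a covariate value into the two pieces of a linear spline with a
#' single knot: `low = min(x, knot)` and `high = max(x - knot, 0)`. The
#' transform is continuous in `x` and `low + high = x`.
#'
#' @param x Covariate value(s).
#' @param knot Knot location, in the same units as `x`.
#' @return A list with numeric components `low` and `high`.
#' @export
spline_transform <- function(x, knot) {
  stopifnot(all(is.finite(x)), is.finite(knot))
  list(low = pmin(x, knot), high = pmax(x - knot, 0))
}

# Decompose LP(t) = base + slope * t + sum(step amounts * (t > threshold)),
# vectorised over profile rows. Everything downstream (linear predictor,
# hazards, cumulative hazards, simulation) is built on this.
lp_components <- function(eq, profiles) {
  stopifnot(inherits(eq, "risk_equation"), is.data.frame(profiles))
  n <- nrow(profiles)
  base <- rep(eq$constant, n)
  for (tm in eq$terms) {
    x <- .get_column(eq, profiles, tm$covariate)
    ctr <- if (is_binary_covariate(tm$covariate)) 0
           else .need_center(eq, tm$covariate, tm$center)
    base <- base + tm$coef * (x - ctr)
  }
  for (s in eq$splines) {
    x <- .get_column(eq, profiles, s$covariate)
    pieces <- spline_transform(x, s$knot)
    cl <- .need_center(eq, s$covariate, s$center_low)
    ch <- .need_center(eq, s$covariate, s$center_high)
    base <- base + s$coef_low * (pieces$low - cl) + s$coef_high * (pieces$high - ch)
  }
  for (ia in eq$interactions) {
    base <- base + ia$coef *
      .interaction_value(eq, profiles, ia$covariates[1]) *
      .interaction_value(eq, profiles, ia$covariates[2])
  }
  slope <- numeric(n)
  steps <- list()
  for (tt in eq$time_terms) {
    x <- if (is.na(tt$covariate)) rep(1, n) else .get_column(eq, profiles, tt$covariate)
    if (tt$form == "linear") {
      slope <- slope + tt$coef * x
    } else {
      steps[[length(steps) + 1L]] <- list(threshold = tt$threshold,
                                          amount = tt$coef * x)
    }
  }
  list(base = base, slope = slope, steps = steps, shape = eq$shape)
}

#' Linear predictor of a risk equation
#'
#' Evaluates the log-hazard offset `LP(t)` for one or more patient profiles at
#' time `t` on the equation's own time scale (years since diagnosis for first
#' events, years since the first event for second events).
#'
#' @param eq A [risk_equation()].
#' @param profiles Data frame of patient profiles (see [validate_profiles()]).
#' @param t Time in years on the equation's time scale (scalar, `>= 0`).
#' @return Numeric vector, one value per profile row.
#' @export
linear_predictor <- function(eq, profiles, t = 0) {
  stopifnot(length(t) == 1, is.finite(t), t >= 0)
  comp <- lp_components(eq, profiles)
  lp_at(comp, t)
}

lp_at <- function(comp, t) {
  lp <- comp$base + comp$slope * t
  for (st in comp$steps) lp <- lp + st$amount * (t > st$threshold)
  lp
}
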
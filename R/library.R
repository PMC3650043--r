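# The equation library: the eight (event, order) Weibull PH equations plus
# provenance metadata, serialisable to/from YAML.

#' Construct an equation library
#'
#' @param equations Named list of [risk_equation()] objects; names must be
#'   `<event>_<order>` and cover all eight (event, order) combinations.
#' @param version,source Provenance strings carried into every artifact
#'   written from this library.
#' @param strict Passed through to completeness checking: if `TRUE` (default)
#'   all eight equations must be present.
#' @return An object of class `equation_library`.
#' @export
equation_library <- function(equations, version = "unversioned",
                             source = "", strict = TRUE) {
  expected <- as.vector(outer(.recurrisk_events, c("first", "second"),
                              paste, sep = "_"))
  if (strict && !setequal(names(equations), expected))
    stop(sprintf("library must contain exactly the 8 equations: %s",
                 paste(sort(expected), collapse = ", ")))
  for (nm in names(equations)) {
    eq <- equations[[nm]]
    if (!inherits(eq, "risk_equation"))
      stop(sprintf("'%s' is not a risk_equation", nm))
    if (nm != paste(eq$event, eq$order, sep = "_"))
      stop(sprintf("equation '%s' is keyed inconsistently (%s_%s)",
                   nm, eq$event, eq$order))
  }
  structure(list(equations = equations, version = version, source = source),
            class = "equation_library")
}

#' @export
print.equation_library <- function(x, ...) {
  cat(sprintf("<equation_library> version %s, %d equations\n",
              x$version, length(x$equations)))
  for (nm in names(x$equations)) {
    eq <- x$equations[[nm]]
    cat(sprintf("  %-14s shape %.4f, constant %+.4f%s\n", nm, eq$shape,
                eq$constant,
                if (has_complete_centering(eq)) "" else "  [centering incomplete]"))
  }
  invisible(x)
}

#' @export
`[[.equation_library` <- function(x, i) {
  eq <- x$equations[[i]]
  if (is.null(eq)) stop(sprintf("no equation '%s' in library", i))
  eq
}

#' Retrieve one equation by event and order
#'
#' @param lib An [equation_library()].
#' @param event Event type (`"ami"`, `"hf"`, `"stroke"`, `"naihd"`).
#' @param order `"first"` or `"second"`.
#' @return A [risk_equation()].
#' @export
get_equation <- function(lib, event, order) {
  lib[[paste(match.arg(event, .recurrisk_events),
             match.arg(order, c("first", "second")), sep = "_")]]
}

has_complete_centering <- function(eq) {
  ok <- TRUE
  for (tm in eq$terms) ok <- ok && !is.na(tm$center)
  for (s in eq$splines) ok <- ok && !is.na(s$center_low) && !is.na(s$center_high)
  ok
}

.num_or_null <- function(x) if (is.null(x) || is.na(x)) NULL else as.numeric(x)

eq_to_list <- function(eq) {
  list(
    event = eq$event, order = eq$order, time_scale = eq$time_scale,
    constant = eq$constant, shape = eq$shape,
    terms = lapply(eq$terms, function(tm) {
      out <- list(covariate = tm$covariate, coef = tm$coef)
      if (!is_binary_covariate(tm$covariate)) out$center <- .num_or_null(tm$center)
      out
    }),
    splines = lapply(eq$splines, function(s)
      list(covariate = s$covariate, knot = s$knot,
           coef_low = s$coef_low, coef_high = s$coef_high,
           center_low = .num_or_null(s$center_low),
           center_high = .num_or_null(s$center_high))),
    interactions = lapply(eq$interactions, function(ia)
      list(covariates = ia$covariates, coef = ia$coef)),
    time_terms = lapply(eq$time_terms, function(tt) {
      out <- list(covariate = if (is.na(tt$covariate)) NULL else tt$covariate,
                  coef = tt$coef, form = tt$form)
      if (tt$form == "step") out$threshold <- tt$threshold
      out
    })
  )
}

eq_from_list <- function(nm, x, strict = TRUE) {
  for (f in c("event", "order", "constant", "shape"))
    if (is.null(x[[f]]))
      stop(sprintf("equation config '%s': missing field '%s'", nm, f))
  if (!is.numeric(x$shape) || x$shape <= 0)
    stop(sprintf("equation config '%s': shape must be positive", nm))
  known <- c(.binary_covariates, .continuous_covariates)
  covs <- c(vapply(x$terms, function(tm) tm$covariate %||% "", ""),
            vapply(x$splines, function(s) s$covariate %||% "", ""),
            unlist(lapply(x$interactions, `[[`, "covariates")),
            unlist(lapply(x$time_terms, `[[`, "covariate")))
  bad <- setdiff(covs, c(known, ""))
  if (length(bad))
    stop(sprintf("equation config '%s': unknown covariate name(s): %s",
                 nm, paste(bad, collapse = ", ")))
  risk_equation(event = x$event, order = x$order, constant = x$constant,
                shape = x$shape, terms = x$terms %||% list(),
                splines = x$splines %||% list(),
                interactions = x$interactions %||% list(),
                time_terms = x$time_terms %||% list(),
                time_scale = x$time_scale %||%
                  if (x$order == "first") "since_diagnosis" else "since_first_event",
                strict = strict)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an equation library from a YAML config file
#'
#' The schema has top-level keys `version`, `source` and `equations`, the
#' latter a map `<event>_<order>` to objects with `event`, `order`,
#' `constant`, `shape`, `terms[]`, `splines[]`, `interactions[]`,
#' `time_terms[]` and per-term centering constants (`center: null` marks a
#' centering placeholder that must be supplied before absolute risks can be
#' computed; see [set_centering()]).
#'
#' @param path Path to the YAML file.
#' @param strict Enforce the first-event `shape > 1` / second-event
#'   `shape < 1` pattern (default `TRUE`).
#' @return An [equation_library()].
#' @export
read_equation_library <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop(sprintf("equation config not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$equations)) stop("equation config: missing 'equations' map")
  eqs <- mapply(eq_from_list, names(raw$equations), raw$equations,
                MoreArgs = list(strict = strict), SIMPLIFY = FALSE)
  equation_library(eqs, version = raw$version %||% "unversioned",
                   source = raw$source %||% "", strict = strict)
}

#' Write an equation library to YAML
#'
#' The output is canonical (fixed key order), so save/load/save round trips
#' are byte-identical.
#'
#' @param lib An [equation_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_equation_library <- function(lib, path) {
  stopifnot(inherits(lib, "equation_library"))
  out <- list(version = lib$version, source = lib$source,
              equations = lapply(lib$equations, eq_to_list))
  writeLines(yaml::as.yaml(out, precision = 15), path)
  invisible(path)
}

#' The published equation library
#'
#' Loads the eight first/second-event cardiovascular risk equations for type 2
#' diabetes shipped with the package (AMI, heart failure, stroke and non-acute
#' ischaemic heart disease; Weibull proportional hazards in the
#' Prentice-Williams-Peterson gap-time formulation). Centering constants are
#' included where published (the AMI equations); the remaining equations carry
#' centering placeholders -- hazard ratios work everywhere, but absolute risks
#' for those equations require [set_centering()] or [synthetic_centering()].
#'
#' @return An [equation_library()].
#' @export
ndr_equations <- function() {
  read_equation_library(system.file("extdata", "equations_ndr2013.yaml",
                                    package = "recurrisk", mustWork = TRUE))
}

#' Set centering constants
#'
#' Supplies mean-centering constants for continuous covariates. For spline
#' covariates a single reference mean `m` is split into the two pieces,
#' `min(m, knot)` and `max(m - knot, 0)`.
#'
#' @param x A [risk_equation()] or [equation_library()].
#' @param values For an equation: named numeric vector/list of covariate
#'   means. For a library: named list (by equation key) of such vectors.
#' @return The object with centering filled in.
#' @export
set_centering <- function(x, values) UseMethod("set_centering")

#' @export
set_centering.risk_equation <- function(x, values) {
  values <- as.list(values)
  for (i in seq_along(x$terms)) {
    v <- x$terms[[i]]$covariate
    if (!is.null(values[[v]]) && !is_binary_covariate(v))
      x$terms[[i]]$center <- as.numeric(values[[v]])
  }
  for (i in seq_along(x$splines)) {
    v <- x$splines[[i]]$covariate
    if (!is.null(values[[v]])) {
      m <- as.numeric(values[[v]])
      x$splines[[i]]$center_low <- min(m, x$splines[[i]]$knot)
      x$splines[[i]]$center_high <- max(m - x$splines[[i]]$knot, 0)
    }
  }
  x
}

#' @export
set_centering.equation_library <- function(x, values) {
  for (nm in names(values)) {
    if (is.null(x$equations[[nm]]))
      stop(sprintf("no equation '%s' in library", nm))
    x$equations[[nm]] <- set_centering(x$equations[[nm]], values[[nm]])
  }
  x
}

#' Fill missing centering constants with synthetic reference means
#'
#' The original mean-centering constants are published only for the AMI
#' equations. This helper fills every remaining placeholder with a synthetic
#' stand-in: the pooled training-sample baseline mean of the covariate (from
#' the cohort-generator defaults), or 10 years for diabetes duration at the
#' first event. Hazard ratios are unaffected by centering; absolute risks
#' computed with synthetic centering are demonstrations, not reproductions of
#' the published ones.
#'
#' @param lib An [equation_library()].
#' @return The library with all centering placeholders filled.
#' @export
synthetic_centering <- function(lib) {
  means <- .table1_pooled_means()
  means$duration_first_event <- 10
  for (nm in names(lib$equations)) {
    eq <- lib$equations[[nm]]
    need <- list()
    for (tm in eq$terms)
      if (is.na(tm$center) && !is_binary_covariate(tm$covariate))
        need[[tm$covariate]] <- means[[tm$covariate]]
    for (s in eq$splines)
      if (is.na(s$center_low) || is.na(s$center_high))
        need[[s$covariate]] <- means[[s$covariate]]
    if (length(need))
      lib$equations[[nm]] <- set_centering(eq, need)
  }
  lib
}
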
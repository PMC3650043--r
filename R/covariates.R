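# Covariate registry shared by the equation library, the cohort generator and
# the microsimulator. Indicator covariates are never centred; continuous
# covariates require a centering constant before absolute hazards can be
# evaluated.

.recurrisk_events <- c("ami", "hf", "stroke", "naihd")

.binary_covariates <- c(
  "female", "smoker", "macroalbuminuria", "microalbuminuria",
  "ami_history", "hf_history", "stroke_history", "naihd_history",
  "ami_post", "hf_post", "stroke_post", "naihd_post"
)

.continuous_covariates <- c(
  "age_at_diagnosis", "diabetes_duration", "hba1c", "systolic_bp",
  "diastolic_bp", "ldl", "tc_hdl", "bmi", "duration_first_event"
)

# plausibility bounds (warn, not fail); also the truncation bounds used by the
# cohort generator
.covariate_bounds <- list(
  age_at_diagnosis = c(30, 75),
  diabetes_duration = c(0, 50),
  hba1c = c(3.5, 20),
  systolic_bp = c(80, 250),
  diastolic_bp = c(40, 140),
  ldl = c(0.3, 10),
  tc_hdl = c(1.5, 15),
  bmi = c(15, 65),
  duration_first_event = c(0, 55)
)

is_binary_covariate <- function(x) x %in% .binary_covariates

#' Validate a table of patient covariate profiles
#'
#' Checks that indicator covariates are coded 0/1, that macro- and
#' microalbuminuria are mutually exclusive, and that continuous covariates lie
#' within plausible physiologic ranges (out-of-range values raise a warning,
#' not an error).
#'
#' @param profiles A data frame with one row per patient. Recognised columns:
#'   `female`, `age_at_diagnosis`, `diabetes_duration`, `hba1c`,
#'   `systolic_bp`, `diastolic_bp`, `ldl`, `tc_hdl`, `bmi`, `smoker`,
#'   `macroalbuminuria`, `microalbuminuria`, pre-diagnosis history flags
#'   (`ami_history`, `hf_history`, `stroke_history`, `naihd_history`),
#'   post-diagnosis dynamic flags (`ami_post`, `hf_post`, `stroke_post`,
#'   `naihd_post`) and, for second-event equations, `duration_first_event`
#'   (diabetes duration at the first event, years).
#' @param bounds Named list of `c(lower, upper)` plausibility bounds,
#'   overriding the defaults per covariate.
#' @return `profiles`, invisibly, after validation.
#' @export
validate_profiles <- function(profiles, bounds = list()) {
  stopifnot(is.data.frame(profiles))
  b <- utils::modifyList(.covariate_bounds, bounds)
  for (v in intersect(.binary_covariates, names(profiles))) {
    x <- profiles[[v]]
    if (!all(x %in% c(0, 1)))
      stop(sprintf("indicator covariate '%s' must be coded 0/1", v))
  }
  if (all(c("macroalbuminuria", "microalbuminuria") %in% names(profiles))) {
    if (any(profiles$macroalbuminuria == 1 & profiles$microalbuminuria == 1))
      stop("macroalbuminuria and microalbuminuria cannot both be 1")
  }
  for (v in intersect(names(b), names(profiles))) {
    x <- profiles[[v]]
    bad <- is.finite(x) & (x < b[[v]][1] | x > b[[v]][2])
    if (any(bad))
      warning(sprintf("%d value(s) of '%s' outside plausible range [%g, %g]",
                      sum(bad), v, b[[v]][1], b[[v]][2]))
  }
  invisible(profiles)
}

#' Read patient profiles from CSV
#'
#' @param path Path to a CSV file with one row per patient and the column
#'   names documented in [validate_profiles()].
#' @return A validated data frame of profiles.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop(sprintf("profile file not found: %s", path))
  profiles <- utils::read.csv(path)
  validate_profiles(profiles)
  profiles
}

#' Bundled worked-example patient profile
#'
#' A single illustrative patient used throughout the documentation: a
#' non-smoking male aged 58 with 10 years of diabetes duration (diagnosed at
#' 48), HbA1c 8.0% NGSP, systolic BP 150 mmHg, LDL 2.0 mmol/L, total-to-HDL
#' cholesterol ratio 4.3, macroalbuminuria, and no cardiovascular history.
#' For second-event equations his first event is assumed to occur in the 10th
#' year after diagnosis (`duration_first_event = 10`).
#'
#' @return A one-row data frame of covariates.
#' @export
example_profile <- function() {
  data.frame(
    female = 0, age_at_diagnosis = 48, diabetes_duration = 10,
    hba1c = 8.0, systolic_bp = 150, diastolic_bp = 80,
    ldl = 2.0, tc_hdl = 4.3, bmi = 28,
    smoker = 0, macroalbuminuria = 1, microalbuminuria = 0,
    ami_history = 0, hf_history = 0, stroke_history = 0, naihd_history = 0,
    ami_post = 0, hf_post = 0, stroke_post = 0, naihd_post = 0,
    duration_first_event = 10
  )
}
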
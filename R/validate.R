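# Discrimination and calibration machinery: Harrell's C for censored data,
# Gronnesby-Borgan expected event counts (observed minus martingale residual
# = model cumulative hazard over the at-risk interval), and the modified
# Hosmer-Lemeshow chi-square over deciles of predicted risk.

#' Harrell's concordance index for censored data
#'
#' A pair (i, j) is usable when the shorter follow-up ends in an event and the
#' other subject was already at risk at that moment (relevant under delayed
#' entry); it is concordant when the subject with the higher risk score fails
#' first, and score ties count 1/2. The confidence interval uses a
#' Noether-type asymptotic variance built from per-subject concordance
#' components (the method is recorded in the output since conventions differ).
#'
#' @param scores Per-subject risk scores (higher = higher predicted risk).
#' @param times Follow-up times.
#' @param events Event indicators (0/1).
#' @param conf_level Confidence level (default 0.95).
#' @param entry Optional left-truncation (entry) times on the same scale as
#'   `times`; default 0 (everyone at risk from the origin).
#' @return A list of class `harrell_c`: `c_index`, `se`, `ci`, `n_pairs`,
#'   `ci_method`.
#' @export
harrell_c <- function(scores, times, events, conf_level = 0.95, entry = 0) {
  n <- length(scores)
  stopifnot(length(times) == n, length(events) == n, all(events %in% c(0, 1)))
  entry <- rep_len(entry, n)
  if (any(entry >= times)) stop("entry times must precede follow-up times")
  conc <- numeric(n)   # concordant + 0.5 * tied, per subject
  comp <- numeric(n)   # comparable pairs involving subject
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    j <- which(times > times[i] & entry < times[i])
    if (!length(j)) next
    w <- (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    conc[i] <- conc[i] + sum(w)
    conc[j] <- conc[j] + w
    comp[i] <- comp[i] + length(j)
    comp[j] <- comp[j] + 1
  }
  P <- sum(comp) / 2
  if (P < 1) stop("no comparable pairs: concordance is undefined")
  C <- sum(conc) / 2 / P
  phi <- conc - C * comp   # per-subject influence on the numerator
  se <- sqrt(sum(phi^2)) / P
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(c_index = C, se = se,
                 ci = c(max(0, C - q * se), min(1, C + q * se)),
                 n_pairs = P, conf_level = conf_level,
                 ci_method = "Noether-type asymptotic variance over pairs"),
            class = "harrell_c")
}

#' @export
print.harrell_c <- function(x, ...) {
  cat(sprintf("Harrell's C = %.4f (%.0f%% CI %.4f-%.4f), %d comparable pairs\n",
              x$c_index, 100 * x$conf_level, x$ci[1], x$ci[2], x$n_pairs))
  invisible(x)
}

#' Model-expected event counts (Gronnesby-Borgan)
#'
#' The expected number of events for subject i is the observed count minus the
#' martingale residual, i.e. the model cumulative hazard over the subject's
#' at-risk interval. For a well-calibrated model the expected counts sum to
#' approximately the observed counts.
#'
#' @param eq A [risk_equation()] (centering complete).
#' @param profiles Data frame of covariates, one row per subject.
#' @param entry,exit At-risk interval bounds on the equation's time scale.
#' @return Numeric vector of expected counts (`>= 0`).
#' @export
expected_events <- function(eq, profiles, entry, exit) {
  cumulative_hazard(eq, profiles, entry, exit)
}

#' Modified Hosmer-Lemeshow calibration test
#'
#' Groups subjects by quantiles of predicted risk score (default deciles; ties
#' broken by a stable sort on position), compares observed and expected event
#' counts per group with `X2 = sum (O_g - E_g)^2 / E_g`, and refers the
#' statistic to a chi-square distribution. The default degrees of freedom are
#' `n_groups - 2`, appropriate when the evaluated model was fitted to the same
#' data; when the model is external or fixed (no parameters estimated from
#' these data), pass `df = n_groups`. The df convention used is reported in
#' the result.
#'
#' @param scores Predicted risk scores used for grouping.
#' @param observed Observed event counts per subject.
#' @param expected Expected event counts per subject (see [expected_events()]).
#' @param n_groups Number of score groups (default 10, minimum 3).
#' @param df Degrees of freedom for the reference chi-square (default
#'   `n_groups - 2`).
#' @return A list of class `hl_test`: `statistic`, `df`, `p_value`, `table`
#'   (per-group n, observed, expected).
#' @export
modified_hl_test <- function(scores, observed, expected, n_groups = 10,
                             df = n_groups - 2) {
  n <- length(scores)
  stopifnot(length(observed) == n, length(expected) == n, n_groups >= 3)
  ord <- order(scores)                      # stable: ties keep input order
  grp_sorted <- ceiling(seq_len(n) * n_groups / n)
  grp <- integer(n); grp[ord] <- grp_sorted
  O <- tapply(observed, grp, sum)
  E <- tapply(expected, grp, sum)
  ng <- tapply(observed, grp, length)
  if (any(E <= 0))
    stop("group(s) with nonpositive expected count; reduce n_groups")
  x2 <- sum((O - E)^2 / E)
  structure(list(statistic = x2, df = df,
                 p_value = stats::pchisq(x2, df, lower.tail = FALSE),
                 table = data.frame(group = as.integer(names(O)), n = as.vector(ng),
                                    observed = as.vector(O), expected = as.vector(E))),
            class = "hl_test")
}

#' @export
print.hl_test <- function(x, ...) {
  cat(sprintf("Modified Hosmer-Lemeshow X2 = %.3f on %d df, p = %.4f\n",
              x$statistic, x$df, x$p_value))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Validate a risk equation on counting-process data
#'
#' Collapses a counting-process dataset to one record per subject (total
#' at-risk interval, any event), scores each subject by the model risk over a
#' common fixed horizon from the subject's entry (so the score depends only on
#' covariates and entry, never on observed follow-up), and reports Harrell's C
#' with CI, the observed/expected decile table and the modified
#' Hosmer-Lemeshow test. Expected counts use each subject's actual at-risk
#' interval.
#'
#' @param eq A [risk_equation()] (centering complete).
#' @param data Counting-process data frame (see [read_counting_process()]);
#'   covariate columns must include everything the equation references.
#' @param n_groups,df Passed to [modified_hl_test()].
#' @param score_horizon Horizon (years from entry) of the ranking score;
#'   default the longest observed follow-up.
#' @return A list of class `validation_report`.
#' @export
validate_equation <- function(eq, data, n_groups = 10, df = n_groups - 2,
                              score_horizon = NULL) {
  data <- validate_counting_process(data)
  ids <- unique(data$patient_id)
  first_row <- match(ids, data$patient_id)
  entry <- as.numeric(tapply(data$entry, data$patient_id, min)[as.character(ids)])
  exit <- as.numeric(tapply(data$exit, data$patient_id, max)[as.character(ids)])
  observed <- tapply(data$event, data$patient_id, sum)[as.character(ids)]
  profiles <- data[first_row, , drop = FALSE]   # baseline covariate values
  if (is.null(score_horizon)) score_horizon <- max(exit - entry)
  expected <- expected_events(eq, profiles, entry, exit)
  score <- 1 - exp(-cumulative_hazard(eq, profiles, entry,
                                      entry + score_horizon))
  C <- harrell_c(score, exit, as.numeric(observed > 0), entry = entry)
  hl <- modified_hl_test(score, as.numeric(observed), expected,
                         n_groups = n_groups, df = df)
  structure(list(c_index = C, hl = hl,
                 totals = c(observed = sum(observed), expected = sum(expected)),
                 n = length(ids)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d subjects; observed %d vs expected %.1f events\n",
              x$n, x$totals[["observed"]], x$totals[["expected"]]))
  print(x$c_index)
  print(x$hl)
  invisible(x)
}
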
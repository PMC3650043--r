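# Patient-level microsimulation of first and second cardiovascular events
# under an equation library.
#
# Structure: the four event types run as parallel first-event processes on the
# time-since-diagnosis scale (delayed entry at the baseline diabetes
# duration), coupled only through the dynamic history flags (*_post), which
# flip to 1 at the moment a first event of that type occurs. A first event of
# type X starts the type-X second-event clock at gap time 0; second events are
# drawn from the gap-time equations with covariates frozen at their values at
# the first event. Event times are sampled exactly by inverse transform of the
# conditional Weibull survival within annual intervals (fresh Exp(1) draws per
# year are valid by memorylessness), so there is no discretisation bias while
# covariates still refresh annually.

#' Simulate first and second events for a cohort
#'
#' @param cohort Data frame of baseline profiles (see [generate_baseline()]),
#'   with `patient_id` and `diabetes_duration` columns.
#' @param library An [equation_library()]; centering must be complete for the
#'   equations in scope (see [synthetic_centering()]).
#' @param horizon Follow-up in years from baseline (> 0).
#' @param seed Integer seed; identical inputs and seed give identical results.
#' @param events Event types to simulate (default all four).
#' @param orders `"first"`, or `c("first", "second")` (default).
#' @param drift Annual covariate drift spec, as in [annual_covariate_update()];
#'   default none (covariates constant).
#' @param dropout_rate Optional exponential withdrawal rate per year in
#'   addition to administrative censoring at `horizon` (default 0).
#' @return An object of class `cvd_simulation` with elements `events` (one row
#'   per event: `patient_id`, `event`, `order`, `time` since diagnosis,
#'   `gap_time`), `censor` (per-patient entry and censoring times),
#'   `summary` (counts and person-years per process), and the inputs needed to
#'   export counting-process data.
#' @export
simulate_cohort <- function(cohort, library, horizon, seed,
                            events = .recurrisk_events,
                            orders = c("first", "second"),
                            drift = list(), dropout_rate = 0) {
  stopifnot(inherits(library, "equation_library") || is.list(library),
            horizon > 0, nrow(cohort) >= 1)
  events <- match.arg(events, .recurrisk_events, several.ok = TRUE)
  orders <- match.arg(orders, c("first", "second"), several.ok = TRUE)
  if (!"patient_id" %in% names(cohort)) cohort$patient_id <- seq_len(nrow(cohort))
  if (!"diabetes_duration" %in% names(cohort))
    stop("cohort needs a 'diabetes_duration' column (years since diagnosis at baseline)")
  set.seed(seed)
  n <- nrow(cohort)
  d0 <- cohort$diabetes_duration
  censor <- rep(horizon, n)                       # calendar years from baseline
  if (dropout_rate > 0)
    censor <- pmin(censor, stats::rexp(n, dropout_rate))

  flags <- sapply(.recurrisk_events, function(ev) {
    col <- paste0(ev, "_post")
    if (col %in% names(cohort)) as.numeric(cohort[[col]]) else numeric(n)
  })
  first_time <- matrix(NA_real_, n, length(.recurrisk_events),
                       dimnames = list(NULL, .recurrisk_events))
  cov_now <- cohort
  cov_history <- if (length(drift)) vector("list", ceiling(horizon)) else NULL

  year_starts <- seq(0, horizon - 1e-12, by = 1)
  for (y in year_starts) {
    yr_end <- pmin(y + 1, censor)
    if (length(drift)) cov_history[[floor(y) + 1L]] <- cov_now
    pending <- which(yr_end > y &
                       rowSums(is.na(first_time[, events, drop = FALSE])) > 0)
    cur <- rep(y, n)
    while (length(pending)) {
      cand_pat <- integer(0); cand_ev <- character(0); cand_t <- numeric(0)
      for (ev in events) {
        act <- pending[is.na(first_time[pending, ev])]
        if (!length(act)) next
        prof <- cov_now[act, , drop = FALSE]
        for (e2 in .recurrisk_events)
          prof[[paste0(e2, "_post")]] <- flags[act, e2]
        comp <- lp_components(library[[paste0(ev, "_first")]], prof)
        a <- d0[act] + cur[act]
        b <- d0[act] + yr_end[act]
        dH <- cumhaz_comp(comp, a, b)
        rem <- stats::rexp(length(act))
        hit <- which(rem < dH)
        if (!length(hit)) next
        tt <- solve_event_time(comp, hit, a[hit], b[hit], rem[hit])
        cand_pat <- c(cand_pat, act[hit])
        cand_ev <- c(cand_ev, rep(ev, length(hit)))
        cand_t <- c(cand_t, tt)
      }
      if (!length(cand_pat)) break
      # earliest candidate per patient; losers re-draw from the commit time
      ord <- order(cand_pat, cand_t)
      keep <- ord[!duplicated(cand_pat[ord])]
      pat <- cand_pat[keep]; ev <- cand_ev[keep]; tt <- cand_t[keep]
      for (k in seq_along(pat)) {
        first_time[pat[k], ev[k]] <- tt[k]
        flags[pat[k], ev[k]] <- 1
      }
      cur[pat] <- tt - d0[pat]
      pending <- pat[rowSums(is.na(first_time[pat, events, drop = FALSE])) > 0]
    }
    if (length(drift)) cov_now <- annual_covariate_update(cov_now, drift)
  }

  ev_rows <- list()
  for (ev in events) {
    got <- which(!is.na(first_time[, ev]))
    if (length(got))
      ev_rows[[paste0(ev, "_first")]] <- data.frame(
        patient_id = cohort$patient_id[got], event = ev, order = "first",
        time = first_time[got, ev], gap_time = NA_real_)
  }

  second_profiles <- list()
  if ("second" %in% orders) {
    for (ev in events) {
      got <- which(!is.na(first_time[, ev]))
      if (!length(got)) next
      t1 <- first_time[got, ev]                  # time since diagnosis
      gap_max <- censor[got] - (t1 - d0[got])    # remaining follow-up
      yr_idx <- pmin(pmax(floor(t1 - d0[got]), 0), ceiling(horizon) - 1) + 1L
      prof <- if (length(drift)) {
        do.call(rbind, lapply(seq_along(got), function(k)
          cov_history[[yr_idx[k]]][got[k], , drop = FALSE]))
      } else cohort[got, , drop = FALSE]
      for (e2 in .recurrisk_events) {
        ft <- first_time[got, e2]
        col <- paste0(e2, "_post")
        base <- if (col %in% names(prof)) prof[[col]] == 1 else FALSE
        prof[[col]] <- as.numeric((!is.na(ft) & ft < t1) | base)
      }
      prof$duration_first_event <- t1
      comp <- lp_components(library[[paste0(ev, "_second")]], prof)
      ok <- which(gap_max > 0)
      if (!length(ok)) { second_profiles[[ev]] <- prof; next }
      dH <- cumhaz_comp(comp, rep(0, nrow(prof)), pmax(gap_max, 0))[ok]
      rem <- stats::rexp(length(ok))
      hit <- which(rem < dH)
      if (length(hit)) {
        g <- solve_event_time(comp, ok[hit], 0, gap_max[ok[hit]], rem[hit])
        ev_rows[[paste0(ev, "_second")]] <- data.frame(
          patient_id = cohort$patient_id[got[ok[hit]]], event = ev,
          order = "second", time = t1[ok[hit]] + g, gap_time = g)
      }
      second_profiles[[ev]] <- prof
    }
  }

  events_df <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(patient_id = integer(0), event = character(0),
               order = character(0), time = numeric(0), gap_time = numeric(0))
  rownames(events_df) <- NULL
  events_df <- events_df[order(events_df$patient_id, events_df$time), ,
                         drop = FALSE]

  res <- structure(list(
    events = events_df,
    censor = data.frame(patient_id = cohort$patient_id, entry = d0,
                        censor_time = censor),
    cohort = cohort, first_time = first_time,
    second_profiles = second_profiles,
    cov_history = cov_history, drift = drift,
    horizon = horizon, seed = seed,
    events_in_scope = events, orders = orders), class = "cvd_simulation")
  res$summary <- simulation_summary(res)
  res
}

#' Simulate a single patient
#'
#' Convenience wrapper around [simulate_cohort()] for one profile.
#'
#' @param profile One-row data frame of covariates (must include
#'   `diabetes_duration`).
#' @inheritParams simulate_cohort
#' @return A `cvd_simulation` for a cohort of size 1.
#' @export
simulate_patient <- function(profile, library, horizon, seed,
                             events = .recurrisk_events,
                             orders = c("first", "second")) {
  stopifnot(nrow(profile) == 1)
  simulate_cohort(profile, library, horizon, seed, events = events,
                  orders = orders)
}

simulation_summary <- function(res) {
  out <- list()
  n <- nrow(res$cohort)
  d0 <- res$censor$entry
  for (ev in res$events_in_scope) {
    ft <- res$first_time[, ev]
    exposure <- pmin(res$censor$censor_time, ifelse(is.na(ft), Inf, ft - d0))
    nev <- sum(!is.na(ft) & (ft - d0) <= res$censor$censor_time)
    out[[paste0(ev, "_first")]] <- data.frame(
      event = ev, order = "first", events = nev,
      person_years = sum(exposure))
    if ("second" %in% res$orders) {
      got <- which(!is.na(ft))
      if (length(got)) {
        gmax <- res$censor$censor_time[got] - (ft[got] - d0[got])
        sec <- res$events[res$events$event == ev & res$events$order == "second", ]
        gobs <- rep(NA_real_, length(got))
        m <- match(res$cohort$patient_id[got], sec$patient_id)
        gobs <- ifelse(is.na(m), pmax(gmax, 0), sec$gap_time[m])
        out[[paste0(ev, "_second")]] <- data.frame(
          event = ev, order = "second", events = nrow(sec),
          person_years = sum(gobs))
      }
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' @export
print.cvd_simulation <- function(x, ...) {
  cat(sprintf("<cvd_simulation> %d patients, %g-year horizon, seed %d\n",
              nrow(x$cohort), x$horizon, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export a counting-process dataset from a simulation
#'
#' Produces the long-format survival data for one (event type, order) process:
#' half-open annual intervals `[entry, exit)` on the process's own time scale
#' (since diagnosis for first events with delayed entry at baseline duration;
#' gap time from 0 for second events), the event flag on the terminal interval
#' only, and the covariate values in force during each interval (annual
#' values; dynamic history flags as of the interval start). Rows are sorted by
#' patient then entry.
#'
#' @param result A `cvd_simulation`.
#' @param event Event type.
#' @param order `"first"` or `"second"`.
#' @return A data frame with columns `patient_id`, `entry`, `exit`, `event`
#'   and the covariates.
#' @export
export_counting_process <- function(result, event, order = "first") {
  stopifnot(inherits(result, "cvd_simulation"))
  event <- match.arg(event, .recurrisk_events)
  order <- match.arg(order, c("first", "second"))
  if (!event %in% result$events_in_scope ||
      !order %in% result$orders)
    stop(sprintf("process %s_%s was not simulated", event, order))
  d0 <- result$censor$entry
  censor <- result$censor$censor_time
  ft <- result$first_time[, event]
  if (order == "first") {
    stop_cal <- pmin(censor, ifelse(is.na(ft), Inf, ft - d0))
    keep <- which(stop_cal > 0)
    m <- pmax(1L, ceiling(stop_cal[keep] - 1e-12))
    idx <- rep(keep, m)                    # cohort row per interval
    a <- sequence(m) - 1                   # annual interval starts
    # additional cuts where another event flips a dynamic history flag, so
    # the linear predictor is exactly constant within every record
    for (e2 in setdiff(.recurrisk_events, event)) {
      tf <- result$first_time[keep, e2] - d0[keep]
      sel <- which(!is.na(tf) & tf > 0 & tf < stop_cal[keep] & tf %% 1 != 0)
      if (length(sel)) {
        idx <- c(idx, keep[sel])
        a <- c(a, tf[sel])
      }
    }
    dup <- duplicated(cbind(idx, a))
    idx <- idx[!dup]; a <- a[!dup]
    ord0 <- order(idx, a)
    idx <- idx[ord0]; a <- a[ord0]
    L <- length(idx)
    last <- c(idx[-1] != idx[-L], TRUE)
    b <- c(a[-1], 0)
    b[last] <- stop_cal[idx[last]]
    yr <- floor(a) + 1                     # covariate year in force
    prof <- if (is.null(result$cov_history)) {
      result$cohort[idx, , drop = FALSE]
    } else {
      p <- result$cohort[idx, , drop = FALSE]
      for (y in seq_along(result$cov_history)) {
        in_y <- which(yr == y)
        if (length(in_y))
          p[in_y, ] <- result$cov_history[[y]][idx[in_y], , drop = FALSE]
      }
      p
    }
    for (e2 in .recurrisk_events) {
      f2 <- result$first_time[idx, e2]
      col <- paste0(e2, "_post")
      base <- if (col %in% names(prof)) prof[[col]] == 1 else FALSE
      prof[[col]] <- as.numeric((!is.na(f2) & f2 - d0[idx] <= a) | base)
    }
    out <- cbind(
      data.frame(patient_id = result$cohort$patient_id[idx],
                 entry = d0[idx] + a, exit = d0[idx] + b,
                 event = as.integer(last & !is.na(ft[idx]))),
      prof[, setdiff(names(prof), "patient_id"), drop = FALSE])
  } else {
    prof_all <- result$second_profiles[[event]]
    if (is.null(prof_all)) stop(sprintf("no second-%s profiles in result", event))
    got <- which(!is.na(ft))
    sec <- result$events[result$events$event == event &
                           result$events$order == "second", ]
    mt <- match(result$cohort$patient_id[got], sec$patient_id)
    gstop <- ifelse(is.na(mt), censor[got] - (ft[got] - d0[got]), sec$gap_time[mt])
    keep <- which(gstop > 0)
    m <- pmax(1L, ceiling(gstop[keep] - 1e-12))
    idx <- rep(keep, m)                    # index into got/prof_all
    j <- sequence(m)
    a <- j - 1
    b <- pmin(j, gstop[idx])
    last <- j == rep(m, m)
    out <- cbind(
      data.frame(patient_id = result$cohort$patient_id[got[idx]],
                 entry = a, exit = b,
                 event = as.integer(last & !is.na(mt[idx]))),
      prof_all[idx, setdiff(names(prof_all), "patient_id"), drop = FALSE])
  }
  if (!nrow(out))
    stop(sprintf("no at-risk intervals for process %s_%s", event, order))
  rownames(out) <- NULL
  out[order(out$patient_id, out$entry), , drop = FALSE]
}

#' Write a counting-process dataset to CSV
#'
#' Times are written with 6-decimal fixed formatting.
#'
#' @param data Data frame from [export_counting_process()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counting_process <- function(data, path) {
  for (v in c("entry", "exit"))
    data[[v]] <- sprintf("%.6f", data[[v]])
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
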
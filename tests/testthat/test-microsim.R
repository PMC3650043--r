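# Minimal covariate-free equations make closed-form oracles available for the
# simulator: with constant hazard lambda the first-event gap from entry is
# exponential regardless of delayed entry.
flat_lib <- function(log_rate_first, log_rate_second = -30) {
  list(ami_first = flat_hazard_equation(log_rate_first, shape = 1),
       ami_second = risk_equation("ami", "second", constant = log_rate_second,
                                  shape = 1, strict = FALSE))
}
tiny_cohort <- function(n, d0 = 0) data.frame(patient_id = seq_len(n),
                                              diabetes_duration = d0)

test_that("a vanishing hazard produces no events and full exposure", {
  res <- simulate_cohort(tiny_cohort(300), flat_lib(-30), horizon = 10,
                         seed = 1, events = "ami")
  expect_equal(nrow(res$events), 0)
  smry <- res$summary
  expect_equal(smry$events[smry$order == "first"], 0)
  expect_equal(smry$person_years[smry$order == "first"], 300 * 10)
  cp <- export_counting_process(res, "ami", "first")
  expect_equal(sum(cp$event), 0)
  expect_equal(sum(cp$exit - cp$entry), 300 * 10)
})

test_that("constant hazards reproduce the exponential distribution", {
  lambda <- 0.5
  n <- 4000
  res <- simulate_cohort(tiny_cohort(n, d0 = 2), flat_lib(log(lambda)),
                         horizon = 40, seed = 21, events = "ami",
                         orders = "first")
  ev <- res$events
  # nearly every patient has an event within 40 years (P(miss) = e^-20)
  expect_equal(nrow(ev), n)
  gaps <- ev$time - 2                # time since entry at duration 2
  expect_true(all(gaps > 0))
  # mean 1/lambda = 2, within 4 Monte Carlo SEs (SD is also 2)
  expect_lt(abs(mean(gaps) - 2), 4 * 2 / sqrt(n))
  # memorylessness across the annual refresh boundary:
  # P(T > 3 | T > 1) should equal P(T > 2)
  p_cond <- mean(gaps > 3) / mean(gaps > 1)
  expect_lt(abs(p_cond - exp(-2 * lambda)), 0.03)
})

test_that("simulated first-event risk matches the analytic interval risk", {
  lambda <- 0.15
  n <- 4000
  res <- simulate_cohort(tiny_cohort(n), flat_lib(log(lambda)), horizon = 5,
                         seed = 33, events = "ami", orders = "first")
  p_true <- 1 - exp(-lambda * 5)
  p_hat <- nrow(res$events) / n
  expect_lt(abs(p_hat - p_true), 4 * sqrt(p_true * (1 - p_true) / n))
})

test_that("counting-process export has annual intervals and terminal flags", {
  res <- simulate_cohort(tiny_cohort(500, d0 = 3), flat_lib(log(0.3)),
                         horizon = 6, seed = 5, events = "ami")
  cp <- export_counting_process(res, "ami", "first")
  expect_true(all(cp$exit > cp$entry))
  expect_true(all(cp$exit - cp$entry <= 1 + 1e-12))
  # intervals are contiguous within patient and start at delayed entry
  for (id in unique(cp$patient_id)[1:20]) {
    rows <- cp[cp$patient_id == id, ]
    expect_equal(rows$entry[1], 3)
    if (nrow(rows) > 1)
      expect_equal(rows$entry[-1], rows$exit[-nrow(rows)])
    expect_true(all(rows$event[-nrow(rows)] == 0))
  }
  expect_equal(sum(cp$event), nrow(res$events))
  # exits of event rows match the recorded event times exactly
  hit <- cp[cp$event == 1, ]
  m <- match(hit$patient_id, res$events$patient_id)
  expect_equal(hit$exit, res$events$time[m])
})

test_that("counting-process files round-trip through CSV", {
  res <- simulate_cohort(generate_baseline(cohort_spec(n = 400, seed = 2)),
                         ndr_lib_centered, horizon = 8, seed = 8,
                         events = "ami")
  cp <- export_counting_process(res, "ami", "first")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_counting_process(cp, tmp)
  cp2 <- read_counting_process(tmp)
  expect_equal(cp2$entry, cp$entry, tolerance = 1e-6)
  expect_equal(cp2$exit, cp$exit, tolerance = 1e-6)
  expect_identical(cp2$event, as.integer(cp$event))
  expect_equal(cp2$hba1c, cp$hba1c, tolerance = 1e-8)
})

test_that("simulations are reproducible and extend consistently in horizon", {
  coh <- generate_baseline(cohort_spec(n = 800, seed = 4))
  a <- simulate_cohort(coh, ndr_lib_centered, horizon = 10, seed = 17)
  b <- simulate_cohort(coh, ndr_lib_centered, horizon = 10, seed = 17)
  expect_identical(a$events, b$events)
  # first events observed under a 5-year horizon recur under a 10-year one
  s5 <- simulate_cohort(coh, ndr_lib_centered, horizon = 5, seed = 17,
                        orders = "first")
  s10 <- simulate_cohort(coh, ndr_lib_centered, horizon = 10, seed = 17,
                         orders = "first")
  key <- function(e) paste(e$patient_id, e$event, signif(e$time, 12))
  expect_true(all(key(s5$events) %in% key(s10$events)))
  expect_gte(nrow(s10$events), nrow(s5$events))
})

test_that("second events occur strictly after the first, on the gap scale", {
  coh <- generate_baseline(cohort_spec(n = 3000, seed = 6))
  res <- simulate_cohort(coh, ndr_lib_centered, horizon = 12, seed = 7)
  sec <- res$events[res$events$order == "second", ]
  expect_gt(nrow(sec), 0)
  expect_true(all(sec$gap_time > 0))
  for (k in seq_len(min(nrow(sec), 50))) {
    ft <- res$events[res$events$patient_id == sec$patient_id[k] &
                       res$events$event == sec$event[k] &
                       res$events$order == "first", "time"]
    expect_equal(sec$time[k], ft + sec$gap_time[k])
  }
  # gap-scale counting process starts at 0 and freezes duration_first_event
  cp2 <- export_counting_process(res, "ami", "second")
  expect_true(all(cp2$entry >= 0))
  firsts <- res$events[res$events$event == "ami" & res$events$order == "first", ]
  m <- match(cp2$patient_id, firsts$patient_id)
  expect_equal(cp2$duration_first_event, firsts$time[m])
})

test_that("history flags flip after a first event of another type", {
  coh <- generate_baseline(cohort_spec(n = 3000, seed = 10))
  res <- simulate_cohort(coh, ndr_lib_centered, horizon = 12, seed = 11)
  cp <- export_counting_process(res, "hf", "first")
  firsts_ami <- res$events[res$events$event == "ami" &
                             res$events$order == "first", ]
  m <- match(cp$patient_id, firsts_ami$patient_id)
  had_ami <- !is.na(m) & firsts_ami$time[m] <= cp$entry
  expect_true(all(cp$ami_post[had_ami] == 1))
  expect_true(all(cp$ami_post[is.na(m)] == 0))
})

test_that("exposure accounting matches the exported risk sets", {
  coh <- generate_baseline(cohort_spec(n = 600, seed = 14))
  res <- simulate_cohort(coh, ndr_lib_centered, horizon = 10, seed = 15,
                         dropout_rate = 0.05)
  expect_true(all(res$censor$censor_time <= 10))
  expect_true(any(res$censor$censor_time < 10))   # some withdrawals
  for (ev in c("ami", "stroke")) {
    cp <- export_counting_process(res, ev, "first")
    smry <- res$summary
    expect_equal(sum(cp$exit - cp$entry),
                 smry$person_years[smry$event == ev & smry$order == "first"],
                 tolerance = 1e-10)
  }
})
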
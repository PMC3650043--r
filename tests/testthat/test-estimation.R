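fixture <- read.csv(system.file("extdata", "estimation_fixture.csv",
                                package = "recurrisk"))

test_that("the log-likelihood matches its closed form on single intervals", {
  X <- matrix(1, 1, 1)
  p <- 1.7; b0 <- -0.8; t1 <- 3.2
  # censored: -H(t) = -exp(b0) t^p
  expect_equal(wph_loglik(b0, log(p), 0, t1, 0, X), -exp(b0) * t1^p)
  # event: log h(t) - H(t)
  expect_equal(wph_loglik(b0, log(p), 0, t1, 1, X),
               log(p) + (p - 1) * log(t1) + b0 - exp(b0) * t1^p)
  # delayed entry removes the hazard mass before entry
  expect_equal(wph_loglik(b0, log(p), 1.1, t1, 0, X),
               -exp(b0) * (t1^p - 1.1^p))
})

test_that("splitting an interval at annual boundaries leaves the likelihood unchanged", {
  X1 <- matrix(c(1, 0.4), 1, 2)
  beta <- c(-1.1, 0.6); lp <- log(1.4)
  whole <- wph_loglik(beta, lp, 0.3, 4.7, 1, X1)
  cuts <- c(0.3, 1, 2, 3, 4, 4.7)
  Xs <- X1[rep(1, 5), , drop = FALSE]
  split <- wph_loglik(beta, lp, cuts[-6], cuts[-1], c(0, 0, 0, 0, 1), Xs)
  expect_equal(split, whole, tolerance = 1e-12)
})

test_that("the analytic gradient matches central finite differences", {
  d <- fixture
  X <- cbind(1, x1 = d$x1, x2 = d$x2)
  par <- c(-0.9, 0.5, -0.3, log(1.4))
  g <- recurrisk:::wph_gradient(par[1:3], par[4], d$entry, d$exit, d$event, X)
  eps <- 1e-6
  g_num <- vapply(1:4, function(i) {
    up <- par; up[i] <- up[i] + eps
    dn <- par; dn[i] <- dn[i] - eps
    (wph_loglik(up[1:3], up[4], d$entry, d$exit, d$event, X) -
       wph_loglik(dn[1:3], dn[4], d$entry, d$exit, d$event, X)) / (2 * eps)
  }, 0)
  expect_equal(unname(g), g_num, tolerance = 1e-6)
})

test_that("fits agree with flexsurv and survreg on the bundled fixture", {
  skip_if_not_installed("flexsurv")
  d <- fixture
  fit <- weibull_ph(survival::Surv(exit, event) ~ x1 + x2, d)
  expect_true(fit$convergence)
  fs <- flexsurv::flexsurvreg(survival::Surv(exit, event) ~ x1 + x2,
                              data = d, dist = "weibullPH")
  cf <- coef(fs)   # log(shape), log(scale) = intercept, covariates
  expect_equal(fit$coefficients[["(Intercept)"]], cf[["scale"]], tolerance = 1e-4)
  expect_equal(fit$coefficients[["x1"]], cf[["x1"]], tolerance = 1e-4)
  expect_equal(fit$coefficients[["x2"]], cf[["x2"]], tolerance = 1e-4)
  expect_equal(fit$coefficients[["log_shape"]], cf[["shape"]], tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(fs)), tolerance = 1e-6)
  # accelerated-failure-time parameterisation of survreg maps onto ours
  sr <- survival::survreg(survival::Surv(exit, event) ~ x1 + x2, data = d,
                          dist = "weibull")
  p_sr <- 1 / sr$scale
  expect_equal(fit$shape, p_sr, tolerance = 1e-4)
  expect_equal(fit$coefficients[["x1"]], -coef(sr)[["x1"]] * p_sr, tolerance = 1e-4)
  expect_equal(fit$coefficients[["(Intercept)"]],
               -coef(sr)[["(Intercept)"]] * p_sr, tolerance = 1e-4)
  # standard errors agree with the oracle's
  expect_equal(sqrt(diag(fit$vcov))[["x1"]], fs$res["x1", "se"], tolerance = 1e-3)
})

test_that("right-censored and counting-process responses give the same fit", {
  d <- fixture
  f1 <- weibull_ph(survival::Surv(exit, event) ~ x1 + x2, d)
  f2 <- weibull_ph(survival::Surv(entry, exit, event) ~ x1 + x2, d)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})

test_that("fitting simulated registry data recovers the generating equation", {
  spec <- cohort_spec(n = 20000, seed = 101,
                      history = c(ami = 0.05, hf = 0, stroke = 0, naihd = 0))
  coh <- generate_baseline(spec)
  res <- simulate_cohort(coh, ndr_lib_centered, horizon = 10, seed = 101,
                         events = c("ami", "hf"), orders = "first")
  cp <- export_counting_process(res, "ami", "first")
  cp$age_c <- cp$age_at_diagnosis - 56.02
  cp$hba1c_c <- cp$hba1c - 7.27
  cp$sbp_c <- cp$systolic_bp - 140.92
  cp$ldl_c <- cp$ldl - 2.77
  cp$tchdl_c <- cp$tc_hdl - 3.89
  cp <- collapse_counting_process(cp)
  fit <- weibull_ph(
    survival::Surv(entry, exit, event) ~ female + age_c + hba1c_c + sbp_c +
      ldl_c + tchdl_c + macroalbuminuria + microalbuminuria + smoker +
      ami_history + hf_post, cp)
  expect_true(fit$convergence)
  truth <- c("(Intercept)" = -7.8187, female = -0.2318, age_c = 0.0541,
             hba1c_c = 0.0829, sbp_c = 0.0079, ldl_c = 0.1161,
             tchdl_c = 0.1712, macroalbuminuria = 0.5719,
             microalbuminuria = 0.2176, smoker = 0.4938,
             ami_history = 0.7469, hf_post = 0.6151,
             log_shape = log(2.0537))
  est <- fit$coefficients[names(truth)]
  # joint Wald test of H0: beta = truth, chi^2 on 13 df at the 0.1 % level
  delta <- est - truth
  wald <- drop(t(delta) %*% solve(fit$vcov[names(truth), names(truth)]) %*% delta)
  expect_lt(wald, stats::qchisq(0.999, length(truth)))
  # headline parameters individually within 3 standard errors
  se <- sqrt(diag(fit$vcov))[names(truth)]
  expect_lt(abs(est[["log_shape"]] - log(2.0537)), 3 * se[["log_shape"]])
  expect_lt(abs(est[["female"]] + 0.2318), 3 * se[["female"]])
})

test_that("degenerate designs and data problems raise named errors", {
  d <- fixture
  d$x3 <- 2 * d$x1
  expect_error(weibull_ph(survival::Surv(exit, event) ~ x1 + x2 + x3, d),
               "rank deficient.*x3")
  d0 <- fixture; d0$event <- 0
  expect_error(weibull_ph(survival::Surv(exit, event) ~ x1, d0), "no events")
  db <- fixture; db$exit[1] <- 0; db$event[1] <- 1
  expect_error(weibull_ph(survival::Surv(exit, event) ~ x1, db),
               "entry < exit")
})

test_that("collapsing contiguous identical-covariate intervals preserves the likelihood", {
  coh <- generate_baseline(cohort_spec(n = 1500, seed = 31))
  res <- simulate_cohort(coh, ndr_lib_centered, horizon = 8, seed = 31,
                         events = "ami", orders = "first")
  cp <- export_counting_process(res, "ami", "first")
  cc <- collapse_counting_process(cp)
  expect_lt(nrow(cc), nrow(cp) / 2)
  expect_equal(sum(cc$event), sum(cp$event))
  expect_equal(sum(cc$exit - cc$entry), sum(cp$exit - cp$entry), tolerance = 1e-10)
  f <- survival::Surv(entry, exit, event) ~ female + smoker + hba1c
  fit_full <- weibull_ph(f, cp)
  fit_coll <- weibull_ph(f, cc)
  expect_equal(fit_coll$loglik, fit_full$loglik, tolerance = 1e-8)
  expect_equal(fit_coll$coefficients, fit_full$coefficients, tolerance = 1e-6)
})

test_that("counting-process input is canonicalised and overlap is reported", {
  res <- simulate_cohort(tiny <- data.frame(patient_id = 1:50,
                                            diabetes_duration = 4),
                         list(ami_first = flat_hazard_equation(log(0.3))),
                         horizon = 5, seed = 2, events = "ami",
                         orders = "first")
  cp <- export_counting_process(res, "ami", "first")
  tmp <- withr::local_tempfile(fileext = ".csv")
  shuffled <- cp[sample(nrow(cp)), ]
  write_counting_process(shuffled, tmp)
  back <- read_counting_process(tmp)
  expect_false(is.unsorted(back$patient_id))
  expect_equal(back[c("patient_id", "entry", "exit", "event")],
               cp[c("patient_id", "entry", "exit", "event")],
               tolerance = 1e-6, ignore_attr = TRUE)
  bad <- cp
  bad$entry[2] <- bad$entry[2] - 0.5     # overlaps the previous interval
  expect_error(validate_counting_process(bad), "overlapping intervals")
  expect_error(read_counting_process(withr::local_tempfile()), "not found")
})

test_that("backward selection removes noise terms and keeps real ones", {
  set.seed(8)
  n <- 2000
  x_real <- rbinom(n, 1, 0.5)
  x_noise <- rnorm(n)
  t_ev <- (rexp(n) / exp(-1 + 0.8 * x_real))^(1 / 1.5)
  d <- data.frame(exit = pmin(t_ev, 5), event = as.integer(t_ev <= 5),
                  x_real, x_noise)
  fit <- backward_select(survival::Surv(exit, event) ~ x_real + x_noise, d)
  kept <- attr(stats::terms(fit$formula), "term.labels")
  expect_identical(kept, "x_real")
})

test_that("a fit converts to a risk equation with identical predictions", {
  d <- fixture
  names(d)[names(d) == "x1"] <- "hba1c"
  names(d)[names(d) == "x2"] <- "smoker"
  fit <- weibull_ph(survival::Surv(exit, event) ~ hba1c + smoker, d)
  eq <- as_risk_equation(fit, "ami", "first")
  nd <- data.frame(hba1c = c(0.2, -1), smoker = c(1, 0))
  expect_equal(linear_predictor(eq, nd), unname(predict(fit, nd, type = "lp")))
  expect_equal(cumulative_hazard(eq, nd, 1, 4),
               unname(predict(fit, nd, type = "cumhaz", t0 = 1, t1 = 4)),
               tolerance = 1e-8)
  # round trip through the YAML library format
  lib <- equation_library(list(ami_first = eq), version = "fit-v1",
                          strict = FALSE)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_equation_library(lib, tmp)
  eq2 <- read_equation_library(tmp, strict = FALSE)[["ami_first"]]
  expect_equal(linear_predictor(eq2, nd), linear_predictor(eq, nd))
  # fits with engineered columns cannot be exported as equations
  fit2 <- weibull_ph(survival::Surv(exit, event) ~ I(hba1c^2), d)
  expect_error(as_risk_equation(fit2, "ami", "first"), "not plain covariate")
})
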
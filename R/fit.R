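# Maximum-likelihood Weibull proportional-hazards regression on
# counting-process data: delayed entry (left truncation), right censoring and
# interval-level (annually updated) covariates. With hazard
# h(t) = exp(eta) * p * t^(p-1), eta = X beta constant within each interval
# [a, b], the interval's log-likelihood contribution is
#   d * [log p + (p-1) log b + eta] - exp(eta) * (b^p - a^p).
# The shape is parameterised as log(p) for unconstrained quasi-Newton
# optimisation with an analytic gradient; standard errors come from the
# inverse observed information (numeric Hessian at the optimum).

#' Weibull proportional-hazards log-likelihood
#'
#' Log-likelihood of counting-process data under hazard
#' `exp(X beta) * p * t^(p-1)` with `p = exp(log_shape)`: the sum over
#' intervals of `event * log h(exit)` minus `H(exit) - H(entry)`. Exposed so
#' fits can be checked against independent implementations.
#'
#' @param beta Regression coefficients (length `ncol(X)`).
#' @param log_shape Log of the Weibull shape.
#' @param entry,exit,event Interval bounds and event flags.
#' @param X Design matrix.
#' @return Scalar log-likelihood.
#' @export
wph_loglik <- function(beta, log_shape, entry, exit, event, X) {
  p <- exp(log_shape)
  eta <- drop(X %*% beta)
  sum(event * (log_shape + (p - 1) * log(exit) + eta)) -
    sum(exp(eta) * (exit^p - entry^p))
}

wph_gradient <- function(beta, log_shape, entry, exit, event, X) {
  p <- exp(log_shape)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  bp <- exit^p; ap <- entry^p
  gb <- drop(crossprod(X, event - w * (bp - ap)))
  lb <- log(exit)
  la <- ifelse(entry > 0, log(entry), 0)      # a^p * log a -> 0 as a -> 0
  glp <- sum(event * (1 + p * lb)) - p * sum(w * (bp * lb - ap * la))
  c(gb, log_shape = glp)
}

#' Fit a Weibull proportional-hazards model
#'
#' Parametric survival regression with hazard
#' `exp(x'beta) * p * t^(p-1)`, supporting delayed entry and time-varying
#' covariates through counting-process data. The response is a
#' [survival::Surv()] object, either `Surv(time, event)` (entry at 0) or
#' `Surv(entry, exit, event)`. The linear predictor is taken as constant
#' within each data interval, so time-varying covariates enter as
#' interval-level columns (e.g. annual values), the convention the published
#' equations were estimated under. The first/second strata of the
#' Prentice-Williams-Peterson gap-time model are fitted as separate calls on
#' each stratum's own time scale.
#'
#' @param formula Model formula with a `Surv` response.
#' @param data Data frame of intervals.
#' @param init Optional named starting values (including `"log_shape"`).
#' @param control Passed to [stats::optim()] (method `"BFGS"`).
#' @return An object of class `weibull_ph` with `coefficients` (regression
#'   terms plus `log_shape`), `shape`, `vcov`, `loglik`, `n`, `nevent`,
#'   `convergence` and `iterations`.
#' @export
weibull_ph <- function(formula, data, init = NULL, control = list()) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y)) stop("the response must be a survival::Surv object")
  if (attr(y, "type") == "right") {
    entry <- rep(0, nrow(y)); exit <- y[, 1]; event <- y[, 2]
  } else if (attr(y, "type") == "counting") {
    entry <- y[, 1]; exit <- y[, 2]; event <- y[, 3]
  } else stop("unsupported Surv type: ", attr(y, "type"))
  if (any(!is.finite(entry)) || any(!is.finite(exit)))
    stop("non-finite interval bounds")
  if (any(entry < 0) || any(exit <= entry))
    stop("intervals must satisfy 0 <= entry < exit")
  if (any(event == 1 & exit <= 0)) stop("event flagged at time 0")
  if (sum(event) < 1) stop("no events in the data")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (any(!is.finite(X))) stop("non-finite covariate values")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  k <- ncol(X)
  par0 <- c(rep(0, k), 0)
  names(par0) <- c(colnames(X), "log_shape")
  if ("(Intercept)" %in% colnames(X)) {
    # start at the exponential-model MLE for the intercept
    par0["(Intercept)"] <- log(sum(event) / sum(exit - entry))
  }
  if (!is.null(init)) par0[names(init)] <- unlist(init)
  nll <- function(par)
    -wph_loglik(par[seq_len(k)], par[k + 1L], entry, exit, event, X)
  ngr <- function(par)
    -wph_gradient(par[seq_len(k)], par[k + 1L], entry, exit, event, X)
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)
  opt <- stats::optim(par0, nll, ngr, method = "BFGS", control = ctrl)
  grad <- ngr(opt$par)
  H <- stats::optimHess(opt$par, nll, ngr)
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k + 1, k + 1))
  dimnames(vcov) <- list(names(par0), names(par0))
  converged <- opt$convergence == 0 && sqrt(sum(grad^2)) < 1e-3 * (1 + abs(opt$value))
  if (!converged)
    warning("weibull_ph did not converge cleanly; inspect $convergence and $gradient")
  structure(list(
    coefficients = opt$par, shape = exp(opt$par[[k + 1L]]),
    vcov = vcov, loglik = -opt$value, gradient = -grad,
    n = length(exit), nevent = sum(event),
    convergence = converged, iterations = opt$counts[["function"]],
    formula = formula, call = cl, xnames = colnames(X)),
    class = "weibull_ph")
}

#' @export
print.weibull_ph <- function(x, digits = 4, ...) {
  cat("Weibull proportional-hazards fit\n")
  cat(sprintf("  %d intervals, %d events; log-likelihood %.3f%s\n",
              x$n, x$nevent, x$loglik,
              if (x$convergence) "" else "  [NOT CONVERGED]"))
  print(round(x$coefficients, digits))
  cat(sprintf("shape p = %.4f\n", x$shape))
  invisible(x)
}

#' @export
summary.weibull_ph <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, shape = object$shape,
                 loglik = object$loglik, n = object$n, nevent = object$nevent,
                 convergence = object$convergence, call = object$call),
            class = "summary.weibull_ph")
}

#' @export
print.summary.weibull_ph <- function(x, ...) {
  cat("Weibull proportional-hazards fit\n")
  cat(deparse(x$call), "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nshape p = %.4f; log-likelihood %.3f on %d intervals (%d events)\n",
              x$shape, x$loglik, x$n, x$nevent))
  if (!x$convergence) cat("WARNING: optimiser did not converge\n")
  invisible(x)
}

#' @export
coef.weibull_ph <- function(object, ...) object$coefficients

#' @export
vcov.weibull_ph <- function(object, ...) object$vcov

#' @export
logLik.weibull_ph <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
confint.weibull_ph <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - q * se, object$coefficients + q * se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

# model matrix for new data (no response needed)
.wph_X <- function(object, newdata) {
  tt <- stats::delete.response(stats::terms(object$formula))
  stats::model.matrix(tt, stats::model.frame(tt, newdata))
}

#' Predict from a Weibull proportional-hazards fit
#'
#' @param object A [weibull_ph()] fit.
#' @param newdata Data frame of covariates.
#' @param type `"lp"` (linear predictor), `"cumhaz"` (cumulative hazard over
#'   `[t0, t1]`) or `"risk"` (`1 - exp(-cumhaz)`).
#' @param t0,t1 Interval bounds for `"cumhaz"`/`"risk"`.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.weibull_ph <- function(object, newdata,
                               type = c("lp", "cumhaz", "risk"),
                               t0 = 0, t1 = NULL, ...) {
  type <- match.arg(type)
  X <- .wph_X(object, newdata)
  k <- length(object$xnames)
  eta <- drop(X %*% object$coefficients[seq_len(k)])
  if (type == "lp") return(eta)
  if (is.null(t1)) stop("t1 is required for cumulative hazard / risk predictions")
  p <- object$shape
  H <- exp(eta) * (t1^p - t0^p)
  if (type == "cumhaz") H else 1 - exp(-H)
}

#' @export
residuals.weibull_ph <- function(object, data, type = "martingale", ...) {
  type <- match.arg(type)
  mf <- stats::model.frame(object$formula, data)
  y <- stats::model.response(mf)
  if (attr(y, "type") == "right") {
    entry <- rep(0, nrow(y)); exit <- y[, 1]; event <- y[, 2]
  } else {
    entry <- y[, 1]; exit <- y[, 2]; event <- y[, 3]
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  k <- length(object$xnames)
  eta <- drop(X %*% object$coefficients[seq_len(k)])
  p <- object$shape
  event - exp(eta) * (exit^p - entry^p)
}

#' Simulate event times from a fitted model
#'
#' Inverse-transform draws of the event time from `entry`, administratively
#' censored at `entry + horizon`.
#'
#' @param object A [weibull_ph()] fit.
#' @param nsim Number of replicates (columns).
#' @param seed Optional seed.
#' @param newdata Covariate data frame.
#' @param entry Entry time(s) on the analysis time scale.
#' @param horizon Follow-up length in years.
#' @param ... Unused.
#' @return A data frame with columns `time` and `event` (`nsim = 1`), or a
#'   list of such data frames.
#' @export
simulate.weibull_ph <- function(object, nsim = 1, seed = NULL, newdata,
                                entry = 0, horizon, ...) {
  if (!is.null(seed)) set.seed(seed)
  X <- .wph_X(object, newdata)
  k <- length(object$xnames)
  eta <- drop(X %*% object$coefficients[seq_len(k)])
  p <- object$shape
  n <- nrow(X)
  entry <- rep_len(entry, n)
  one <- function() {
    rem <- stats::rexp(n)
    t_ev <- (entry^p + rem / exp(eta))^(1 / p)
    cens <- entry + horizon
    data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' @export
plot.weibull_ph <- function(x, t_max = 10, ...) {
  p <- x$shape
  b0 <- if ("(Intercept)" %in% names(x$coefficients))
    x$coefficients[["(Intercept)"]] else 0
  tt <- seq(0, t_max, length.out = 200)
  graphics::plot(tt, exp(b0) * tt^p, type = "l", xlab = "time (years)",
                 ylab = "baseline cumulative hazard", ...)
  invisible(x)
}

#' Read a counting-process CSV
#'
#' Reads and validates long-format survival data (columns `patient_id`,
#' `entry`, `exit`, `event`, plus covariates): intervals must have positive
#' width, and within a patient intervals must not overlap after sorting by
#' entry. Violations are reported with the offending row numbers.
#'
#' @param path CSV path (dialect of [write_counting_process()]).
#' @return A data frame sorted by patient then entry.
#' @export
read_counting_process <- function(path) {
  if (!file.exists(path)) stop(sprintf("counting-process file not found: %s", path))
  d <- utils::read.csv(path)
  need <- c("patient_id", "entry", "exit", "event")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("counting-process data: missing column(s): ", paste(miss, collapse = ", "))
  validate_counting_process(d)
}

#' @rdname read_counting_process
#' @param data An in-memory counting-process data frame.
#' @export
validate_counting_process <- function(data) {
  rows <- seq_len(nrow(data))
  bad <- which(!(data$entry >= 0 & data$exit > data$entry))
  if (length(bad))
    stop("invalid interval(s) (need 0 <= entry < exit) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (!all(data$event %in% c(0, 1)))
    stop("event flags must be 0/1")
  ord <- order(data$patient_id, data$entry)
  d <- data[ord, , drop = FALSE]
  same <- d$patient_id[-1] == d$patient_id[-nrow(d)]
  overlap <- which(same & d$entry[-1] < d$exit[-nrow(d)] - 1e-9)
  if (length(overlap)) {
    r1 <- rows[ord][overlap]; r2 <- rows[ord][overlap + 1L]
    stop(sprintf("overlapping intervals for patient %s at rows %d and %d",
                 d$patient_id[overlap[1]], r1[1], r2[1]))
  }
  rownames(d) <- NULL
  d
}

#' Collapse counting-process intervals with identical covariates
#'
#' Merges maximal runs of contiguous intervals (same patient, matching
#' covariate values, each interval starting where the previous one ended) into
#' single records. Because the Weibull PH log-likelihood depends on an
#' interval only through `exit^p - entry^p` and the terminal event flag, the
#' collapsed data give an identical likelihood while the row count drops
#' sharply when covariates rarely change.
#'
#' @param data Counting-process data frame (see [read_counting_process()]).
#' @param covariates Covariate columns that must match within a run; default
#'   all columns except `patient_id`, `entry`, `exit`, `event`.
#' @return The collapsed, canonically sorted data frame.
#' @export
collapse_counting_process <- function(data, covariates = NULL) {
  data <- validate_counting_process(data)
  if (is.null(covariates))
    covariates <- setdiff(names(data), c("patient_id", "entry", "exit", "event"))
  n <- nrow(data)
  if (n < 2) return(data)
  changed <- data$patient_id[-1] != data$patient_id[-n]
  for (v in covariates) {
    x <- data[[v]]
    d <- x[-1] != x[-n]
    d[is.na(d)] <- TRUE
    changed <- changed | d
  }
  newgrp <- c(TRUE, changed | abs(data$entry[-1] - data$exit[-n]) > 1e-9)
  starts <- which(newgrp)
  lastidx <- c(starts[-1] - 1L, n)
  out <- data[starts, , drop = FALSE]
  out$exit <- data$exit[lastidx]
  out$event <- as.integer(rowsum(data$event, cumsum(newgrp))[, 1] > 0)
  rownames(out) <- NULL
  out
}

#' Backward covariate selection by likelihood-ratio tests
#'
#' Repeatedly refits the model dropping the least significant term until all
#' remaining terms are significant at `alpha` (the selection rule used to
#' arrive at the published equations). Off by default in all workflows.
#'
#' @param formula,data As in [weibull_ph()].
#' @param alpha Significance threshold (default 0.05).
#' @return The final [weibull_ph()] fit.
#' @export
backward_select <- function(formula, data, alpha = 0.05) {
  fit <- weibull_ph(formula, data)
  repeat {
    terms_now <- attr(stats::terms(fit$formula), "term.labels")
    if (length(terms_now) <= 1) return(fit)
    pvals <- vapply(terms_now, function(tm) {
      f2 <- stats::update(fit$formula, paste(". ~ . -", tm))
      fit2 <- weibull_ph(f2, data)
      stats::pchisq(2 * (fit$loglik - fit2$loglik),
                    df = length(fit$coefficients) - length(fit2$coefficients),
                    lower.tail = FALSE)
    }, 0)
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha) return(fit)
    fit <- weibull_ph(stats::update(fit$formula,
                                    paste(". ~ . -", terms_now[worst])), data)
  }
}

#' Convert a fit to a risk equation
#'
#' Packages a [weibull_ph()] fit (plain covariate terms only; covariates are
#' assumed already centred in the fitting formula) as a [risk_equation()]
#' usable by the risk engine and serialisable with
#' [write_equation_library()].
#'
#' @param fit A [weibull_ph()] fit whose model-matrix columns are plain
#'   covariate names.
#' @param event,order Event type and order labels for the resulting equation.
#' @return A [risk_equation()] (built with `strict = FALSE`).
#' @export
as_risk_equation <- function(fit, event, order) {
  k <- length(fit$xnames)
  beta <- fit$coefficients[seq_len(k)]
  if (!"(Intercept)" %in% fit$xnames)
    stop("the fit must include an intercept")
  covs <- setdiff(fit$xnames, "(Intercept)")
  bad <- setdiff(covs, c(.binary_covariates, .continuous_covariates))
  if (length(bad))
    stop("model columns are not plain covariate names: ",
         paste(bad, collapse = ", "))
  risk_equation(
    event = event, order = order, constant = beta[["(Intercept)"]],
    shape = fit$shape,
    terms = lapply(covs, function(v)
      list(covariate = v, coef = beta[[v]],
           center = if (is_binary_covariate(v)) NULL else 0)),
    strict = FALSE)
}
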
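# Product-limit estimation, log-rank testing, Cox fitting and PH
# diagnostics.  Kaplan-Meier curves and Cox fits are backed by the
# 'survival' package behind this module's own contracts; the two-sample
# log-rank statistic is computed directly from risk-set counts (it is also
# the inner loop of survival-tree cut-point search, where calling out to
# survdiff per candidate split would dominate the runtime).

#' Kaplan-Meier product-limit estimate
#'
#' Deaths are processed before censorings at tied times (the product-limit
#' convention), and the Greenwood formula supplies the variance of S(t).
#'
#' @param times positive follow-up times (months).
#' @param events 0/1 event indicators.
#' @return object of class `km_curve`: list with `time` (distinct event
#'   times, ascending), `surv`, `n_risk`, `n_event`, `var` (Greenwood
#'   variance of S), and `n`.
#' @export
#' @examples
#' km_estimate(c(2, 4, 6), c(1, 1, 1))$surv
km_estimate <- function(times, events) {
  if (!length(times)) stopf("empty input to km_estimate")
  if (length(times) != length(events))
    stopf("'times' and 'events' lengths differ")
  if (any(is.na(times)) || any(times <= 0))
    stopf("all times must be positive and non-missing")
  if (!all(events %in% c(0, 1))) stopf("'events' must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "none")
  keep <- sf$n.event > 0
  structure(list(
    time = sf$time[keep],
    surv = sf$surv[keep],
    n_risk = sf$n.risk[keep],
    n_event = sf$n.event[keep],
    var = (sf$surv[keep] * sf$std.err[keep])^2,  # Greenwood
    n = length(times)
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d distinct event times\n",
              x$n, length(x$time)))
  invisible(x)
}

#' Survival percentage at a time point
#'
#' Right-continuous step-function evaluation of a [km_estimate()] curve,
#' carried forward beyond the last observed time, on the 0-100% scale.
#'
#' @param curve a `km_curve`.
#' @param t non-negative time (months).
#' @return survival percentage in \[0, 100\].
#' @export
#' @examples
#' survival_at(km_estimate(c(2, 4, 6), c(1, 1, 1)), 3)
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  check_scalar(t, "t", lower = 0)
  if (!length(curve$time)) return(100)
  idx <- findInterval(t, curve$time)   # last event time <= t
  100 * if (idx == 0) 1 else curve$surv[idx]
}

#' Export a KM curve as a TSV-ready table
#' @param curve a `km_curve`.
#' @return data.frame with time, at-risk, events, survival, variance.
#' @export
km_table <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  data.frame(time = curve$time, n_risk = curve$n_risk,
             n_event = curve$n_event, surv = curve$surv, var = curve$var)
}

# Two-sample log-rank machinery on pooled risk sets.  Returns the
# chi-square statistic; O(n log n).  `group` is logical/0-1 (group A).
#' @noRd
logrank_stat <- function(times, events, group) {
  ev_times <- times[events == 1]
  if (!length(ev_times)) return(NA_real_)
  dt <- sort(unique(ev_times))
  st_all <- sort(times)
  st_a <- sort(times[group == 1])
  Y <- length(times) - findInterval(dt - 1e-12, st_all)
  Ya <- length(st_a) - findInterval(dt - 1e-12, st_a)
  d_all <- tabulate(match(times[events == 1], dt), nbins = length(dt))
  ia <- events == 1 & group == 1
  d_a <- tabulate(match(times[ia], dt), nbins = length(dt))
  ok <- Y > 1
  O <- sum(d_a)
  E <- sum(d_all * Ya / Y)
  V <- sum((d_all * (Ya / Y) * (1 - Ya / Y) * (Y - d_all) / (Y - 1))[ok])
  if (V <= 0) return(NA_real_)
  (O - E)^2 / V
}

#' Two-sample log-rank test
#'
#' Standard (unweighted) log-rank statistic on 1 degree of freedom with
#' the chi-square upper-tail p-value.
#'
#' @param times_a,events_a follow-up and event indicator, group A.
#' @param times_b,events_b follow-up and event indicator, group B.
#' @return list with `chisq`, `p`, `df = 1`.
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b))
    stopf("both groups must be non-empty")
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  if (!all(events %in% c(0, 1))) stopf("'events' must be 0/1")
  group <- rep(c(1L, 0L), c(length(times_a), length(times_b)))
  if (sum(events) == 0) {
    warnf("no events in either group; log-rank statistic is 0")
    return(list(chisq = 0, p = 1, df = 1L))
  }
  cs <- logrank_stat(times, events, group)
  if (is.na(cs)) {
    warnf("degenerate risk sets; log-rank statistic is 0")
    return(list(chisq = 0, p = 1, df = 1L))
  }
  list(chisq = cs, p = pchisq(cs, df = 1, lower.tail = FALSE), df = 1L)
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-type maximization of the partial likelihood (via
#' `survival::coxph`) with Efron (default) or Breslow tie handling and a
#' convergence tolerance of 1e-9 on the relative log-likelihood change.
#' Monotone likelihood (perfect risk separation) is reported through an
#' honest `converged = FALSE` flag rather than an error.
#'
#' @param times,events follow-up (months) and 0/1 indicator.
#' @param x covariate matrix or data.frame (numeric columns).
#' @param ties `"efron"` or `"breslow"`.
#' @return object of class `cox_fit`: `coefficients`, `se`, `vcov`,
#'   `loglik` (at the estimate), `loglik_null`, `ties`, `converged`, `n`,
#'   `n_events`, and the underlying `coxph` object as `fit`.
#' @export
fit_cox <- function(times, events, x, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(as.data.frame(x))
  if (!is.numeric(x)) stopf("covariates must be numeric")
  if (nrow(x) != length(times))
    stopf("covariate rows (%d) do not match times (%d)",
          nrow(x), length(times))
  if (anyNA(x) || any(!is.finite(x))) stopf("covariates must be finite")
  if (sum(events) < 1) stopf("at least one event is required")
  const <- apply(x, 2, function(col) diff(range(col)) == 0)
  if (any(const))
    stopf("constant covariate(s): %s",
          paste(colnames(x)[const], collapse = ", "))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  dat <- data.frame(.time = times, .event = events, x,
                    check.names = FALSE)
  fml <- as.formula(paste("survival::Surv(.time, .event) ~",
                          paste(sprintf("`%s`", colnames(x)),
                                collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  vc <- vcov(fit)
  converged <- !warned && all(is.finite(beta)) &&
    all(is.finite(sqrt(diag(vc))))
  structure(list(
    coefficients = beta,
    se = sqrt(diag(vc)),
    vcov = vc,
    loglik = fit$loglik[2],
    loglik_null = fit$loglik[1],
    ties = ties,
    converged = converged,
    n = fit$n,
    n_events = fit$nevent,
    fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, converged = %s\n",
              x$n, x$n_events, x$ties, x$converged))
  tab <- data.frame(beta = x$coefficients, se = x$se,
                    hr = exp(x$coefficients))
  print(round(tab, 4))
  invisible(x)
}

#' Hazard ratio with 95% confidence interval
#'
#' `HR = exp(beta)`, `CI = exp(beta +/- 1.959964 * SE)`.
#'
#' @param fit a [fit_cox()] result.
#' @param covariate covariate name or index.
#' @return named numeric: `hr`, `lower`, `upper`.
#' @export
hr_ci <- function(fit, covariate) {
  stopifnot(inherits(fit, "cox_fit"))
  b <- fit$coefficients[covariate]
  s <- fit$se[covariate]
  if (anyNA(b)) stopf("unknown covariate '%s'", covariate)
  c(hr = unname(exp(b)), lower = unname(exp(b - Z95 * s)),
    upper = unname(exp(b + Z95 * s)))
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Correlates the scaled Schoenfeld residuals with a transform of event
#' time (default: rank) and returns the per-covariate score-test p-values,
#' via `survival::cox.zph`.
#'
#' @param fit a [fit_cox()] result.
#' @param transform `"rank"` (default), `"identity"` (`"km"` also
#'   accepted).
#' @return data.frame with `covariate`, `chisq`, `df`, `p`.
#' @export
schoenfeld_test <- function(fit, transform = c("rank", "identity", "km")) {
  stopifnot(inherits(fit, "cox_fit"))
  transform <- match.arg(transform)
  if (fit$n_events < 2) stopf("need at least 2 events")
  zp <- survival::cox.zph(fit$fit, transform = transform, global = FALSE)
  tab <- as.data.frame(zp$table)
  data.frame(covariate = rownames(tab), chisq = tab$chisq,
             df = tab$df, p = tab$p, row.names = NULL,
             stringsAsFactors = FALSE)
}
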
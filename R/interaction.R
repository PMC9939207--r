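# Stratified hazard ratios, the Z-test for effect-measure modification,
# and additive-interaction decomposition (RERI / AP / SI) with
# delta-method confidence intervals.

#' RERI / AP / SI point identities
#'
#' The three additive-interaction measures from the joint-exposure hazard
#' ratios (versus the doubly unexposed cell):
#' \deqn{RERI = HR_{11} - HR_{10} - HR_{01} + 1}
#' \deqn{AP = RERI / HR_{11}}
#' \deqn{SI = (HR_{11} - 1) / ((HR_{10} - 1) + (HR_{01} - 1))}
#' SI is flagged undefined when its excess-risk denominator is not
#' positive.
#'
#' @param hr10 hazard ratio, exposure A only (e.g. smoker, no metabolic
#'   syndrome).
#' @param hr01 hazard ratio, exposure B only.
#' @param hr11 hazard ratio, both exposures.
#' @return list with `reri`, `ap`, `si` (NA when undefined), `si_defined`.
#' @export
#' @examples
#' interaction_measures(1.07, 1.59, 4.08)
interaction_measures <- function(hr10, hr01, hr11) {
  for (nm in c("hr10", "hr01", "hr11"))
    check_scalar(get(nm), nm, lower = .Machine$double.eps)
  reri <- hr11 - hr10 - hr01 + 1
  ap <- reri / hr11
  denom <- (hr10 - 1) + (hr01 - 1)
  si_defined <- denom > 0
  si <- if (si_defined) (hr11 - 1) / denom else NA_real_
  list(reri = reri, ap = ap, si = si, si_defined = si_defined)
}

#' Z-test for effect-measure modification between two strata
#'
#' Compares the same log-hazard coefficient estimated in two independent
#' strata: `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a two-sided normal
#' p-value.
#'
#' @param beta1,se1 coefficient and standard error in stratum 1.
#' @param beta2,se2 coefficient and standard error in stratum 2.
#' @return list with `z`, `p`.
#' @export
#' @examples
#' z_interaction(log(4.84), 0.161, log(2.11), 0.172)
z_interaction <- function(beta1, se1, beta2, se2) {
  check_scalar(beta1, "beta1"); check_scalar(beta2, "beta2")
  check_scalar(se1, "se1"); check_scalar(se2, "se2")
  if (se1 <= 0 || se2 <= 0) stopf("standard errors must be positive")
  z <- (beta1 - beta2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# Build the model matrix of adjustment covariates (dummies for character
# columns), or NULL when the list is empty.
#' @noRd
adjust_matrix <- function(cohort, adjust) {
  if (!length(adjust)) return(NULL)
  check_columns(cohort, adjust)
  cols <- list()
  for (cv in adjust) {
    x <- cohort[[cv]]
    if (is.character(x) || is.factor(x)) {
      lev <- sort(unique(as.character(x)))
      for (lv in lev[-1])
        cols[[paste0(cv, lv)]] <- as.integer(as.character(x) == lv)
    } else cols[[cv]] <- as.numeric(x)
  }
  do.call(cbind, cols)
}

#' Stratified Cox hazard ratios for one covariate
#'
#' Fits one Cox model per stratum (e.g. smokers and never-smokers),
#' unadjusted and adjusted, and reports the focal covariate's HR with CI
#' plus the stratum-difference Z-test.
#'
#' @param cohort cohort data.frame with `time_months` and `event`.
#' @param covariate focal covariate column (numeric or 0/1).
#' @param stratifier binary 0/1 stratifying column (default `"smoking"`).
#' @param adjust character vector of adjustment covariates (may be empty).
#' @return object of class `stratified_hr`: per-stratum list with
#'   `unadjusted` and `adjusted` entries (`beta`, `se`, `hr`, `lower`,
#'   `upper`), plus `p_interaction` (adjusted scale).
#' @export
stratum_hrs <- function(cohort, covariate, stratifier = "smoking",
                        adjust = character()) {
  check_columns(cohort, c("time_months", "event", covariate, stratifier))
  svals <- sort(unique(cohort[[stratifier]]))
  if (length(svals) < 2)
    stopf("stratifier '%s' has a single level (%s)", stratifier,
          paste(svals, collapse = ", "))
  res <- list()
  for (sv in svals) {
    sub <- cohort[cohort[[stratifier]] == sv, , drop = FALSE]
    if (!nrow(sub) || sum(sub$event) < 1)
      stopf("stratum %s = %s has no events", stratifier, sv)
    one <- function(adj) {
      xm <- bind_covariates(
        setNames(data.frame(as.numeric(sub[[covariate]])), covariate),
        adjust_matrix(sub, adj))
      f <- fit_cox(sub$time_months, sub$event, xm)
      ci <- hr_ci(f, covariate)
      list(beta = unname(f$coefficients[covariate]),
           se = unname(f$se[covariate]),
           hr = ci[["hr"]], lower = ci[["lower"]], upper = ci[["upper"]])
    }
    res[[paste0(stratifier, "=", sv)]] <-
      list(unadjusted = one(character()), adjusted = one(adjust),
           n = nrow(sub), n_events = sum(sub$event))
  }
  a <- res[[1]]$adjusted; b <- res[[2]]$adjusted
  zt <- z_interaction(a$beta, a$se, b$beta, b$se)
  structure(list(covariate = covariate, stratifier = stratifier,
                 strata = res, z = zt$z, p_interaction = zt$p,
                 adjust = adjust),
            class = "stratified_hr")
}

#' @export
print.stratified_hr <- function(x, ...) {
  cat(sprintf("<stratified_hr> %s by %s\n", x$covariate, x$stratifier))
  for (nm in names(x$strata)) {
    st <- x$strata[[nm]]$adjusted
    cat(sprintf("  %s: HR %.2f (%.2f-%.2f)\n", nm, st$hr, st$lower,
                st$upper))
  }
  cat(sprintf("  p_interaction (Z-test) = %.4g\n", x$p_interaction))
  invisible(x)
}

#' Joint-exposure Cox model over the four exposure cells
#'
#' One Cox fit with three dummy covariates for the cells (A only, B only,
#' both) versus the doubly unexposed reference, plus optional adjustment
#' covariates.  Returns the cell hazard ratios with CIs, cell counts, and
#' the 3x3 coefficient covariance block needed for delta-method
#' interaction CIs.
#'
#' @param cohort cohort data.frame with `time_months` and `event`.
#' @param exposure_a,exposure_b binary 0/1 exposure columns (e.g.
#'   `"smoking"` and `"metsyn"`).
#' @param adjust adjustment covariate names.
#' @return object of class `joint_exposure`: list with `hr` (3-vector for
#'   cells a-only, b-only, both), `ci` (3x2), `beta`, `vcov` (3x3),
#'   `counts` (cases/total per cell incl. reference), `fit`.
#' @export
joint_hrs <- function(cohort, exposure_a, exposure_b,
                      adjust = character()) {
  check_columns(cohort, c("time_months", "event", exposure_a, exposure_b))
  a <- cohort[[exposure_a]]
  b <- cohort[[exposure_b]]
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stopf("exposures must be binary 0/1")
  cell <- paste0(a, b)
  counts <- data.frame(
    cell = c("00", "01", "10", "11"),
    label = c("neither",
              paste0(exposure_b, " only"),
              paste0(exposure_a, " only"),
              "both"),
    cases = vapply(c("00", "01", "10", "11"),
                   function(cl) sum(cohort$event[cell == cl]), integer(1)),
    total = vapply(c("00", "01", "10", "11"),
                   function(cl) sum(cell == cl), integer(1)),
    row.names = NULL
  )
  empty <- counts$cell[counts$total == 0]
  if (length(empty))
    stopf("empty exposure cell(s): %s",
          paste(counts$label[counts$cell %in% empty], collapse = ", "))
  if (counts$cases[counts$cell == "00"] < 1)
    stopf("reference cell 'neither' has no events")

  d01 <- as.integer(a == 0 & b == 1)
  d10 <- as.integer(a == 1 & b == 0)
  d11 <- as.integer(a == 1 & b == 1)
  xm <- bind_covariates(data.frame(d01 = d01, d10 = d10, d11 = d11),
                        adjust_matrix(cohort, adjust))
  f <- fit_cox(cohort$time_months, cohort$event, xm)
  keep <- c("d01", "d10", "d11")
  ci <- t(vapply(keep, function(k) hr_ci(f, k)[c("lower", "upper")],
                 numeric(2)))
  structure(list(
    exposure_a = exposure_a, exposure_b = exposure_b,
    hr = setNames(exp(f$coefficients[keep]), keep),
    ci = ci,
    beta = f$coefficients[keep],
    vcov = f$vcov[keep, keep],
    counts = counts,
    adjust = adjust,
    fit = f
  ), class = "joint_exposure")
}

#' @export
print.joint_exposure <- function(x, ...) {
  cat(sprintf("<joint_exposure> %s x %s\n", x$exposure_a, x$exposure_b))
  tab <- data.frame(cell = c("01", "10", "11"),
                    hr = unname(x$hr), lower = x$ci[, 1],
                    upper = x$ci[, 2])
  print(round(tab[-1] , 3))
  invisible(x)
}

#' Additive-interaction decomposition with confidence intervals
#'
#' Point estimates follow the RERI / AP / SI identities
#' ([interaction_measures()]).  95% CIs use the delta method: the gradient
#' of each measure with respect to the three cell log-hazard coefficients
#' is propagated through their covariance block; the SI interval is formed
#' on the log scale.  A bootstrap alternative refits the joint model on
#' subject resamples and takes percentile intervals.
#'
#' @param joint a [joint_hrs()] result.
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param cohort,reps,seed required for `method = "bootstrap"`: the cohort
#'   the joint model was fitted on, the number of resamples, and a seed.
#' @return object of class `additive_interaction`: list with `reri`, `ap`,
#'   `si` (each `c(est, lower, upper)`), `si_defined`, `method`.
#' @export
additive_measures <- function(joint, method = c("delta", "bootstrap"),
                              cohort = NULL, reps = 1000, seed = 1L) {
  stopifnot(inherits(joint, "joint_exposure"))
  method <- match.arg(method)
  b <- joint$beta            # (b01, b10, b11)
  V <- joint$vcov
  h01 <- exp(b[["d01"]]); h10 <- exp(b[["d10"]]); h11 <- exp(b[["d11"]])
  pt <- interaction_measures(h10, h01, h11)

  if (method == "delta") {
    # gradients with respect to (b01, b10, b11)
    g_reri <- c(-h01, -h10, h11)
    se_reri <- sqrt(drop(t(g_reri) %*% V %*% g_reri))
    g_ap <- c(-h01 / h11, -h10 / h11, (h10 + h01 - 1) / h11)
    se_ap <- sqrt(drop(t(g_ap) %*% V %*% g_ap))
    reri <- c(est = pt$reri, lower = pt$reri - Z95 * se_reri,
              upper = pt$reri + Z95 * se_reri)
    ap <- c(est = pt$ap, lower = pt$ap - Z95 * se_ap,
            upper = pt$ap + Z95 * se_ap)
    if (pt$si_defined && h11 > 1) {
      den <- (h10 - 1) + (h01 - 1)
      g_lsi <- c(-h01 / den, -h10 / den, h11 / (h11 - 1))
      se_lsi <- sqrt(drop(t(g_lsi) %*% V %*% g_lsi))
      si <- c(est = pt$si, lower = exp(log(pt$si) - Z95 * se_lsi),
              upper = exp(log(pt$si) + Z95 * se_lsi))
      si_defined <- TRUE
    } else {
      si <- c(est = NA_real_, lower = NA_real_, upper = NA_real_)
      si_defined <- FALSE
    }
  } else {
    if (is.null(cohort)) stopf("bootstrap method needs the cohort")
    set.seed(as.integer(seed))
    n <- nrow(cohort)
    draws <- matrix(NA_real_, reps, 3)
    for (r in seq_len(reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      jb <- tryCatch(
        joint_hrs(cohort[idx, , drop = FALSE], joint$exposure_a,
                  joint$exposure_b, joint$adjust),
        error = function(e) NULL)
      if (is.null(jb)) next
      m <- interaction_measures(jb$hr[["d10"]], jb$hr[["d01"]],
                                jb$hr[["d11"]])
      draws[r, ] <- c(m$reri, m$ap, m$si)
    }
    qs <- function(k) quantile(draws[, k], c(0.025, 0.975), na.rm = TRUE)
    reri <- c(est = pt$reri, lower = qs(1)[[1]], upper = qs(1)[[2]])
    ap <- c(est = pt$ap, lower = qs(2)[[1]], upper = qs(2)[[2]])
    si_defined <- pt$si_defined
    si <- if (si_defined)
      c(est = pt$si, lower = qs(3)[[1]], upper = qs(3)[[2]])
    else c(est = NA_real_, lower = NA_real_, upper = NA_real_)
  }
  structure(list(reri = reri, ap = ap, si = si, si_defined = si_defined,
                 method = method),
            class = "additive_interaction")
}

#' @export
print.additive_interaction <- function(x, ...) {
  fmt <- function(v, nm) {
    if (anyNA(v)) cat(sprintf("  %s: undefined\n", nm))
    else cat(sprintf("  %s: %.2f (%.2f to %.2f)\n", nm, v[1], v[2], v[3]))
  }
  cat(sprintf("<additive_interaction> (%s CIs)\n", x$method))
  fmt(x$reri, "RERI"); fmt(x$ap, "AP  "); fmt(x$si, "SI  ")
  invisible(x)
}

#' Serialize interaction results as JSON
#'
#' Writes the joint-exposure cell table and the additive-interaction
#' measures in one JSON report.
#'
#' @param joint a [joint_hrs()] result.
#' @param measures an [additive_measures()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_interaction_json <- function(joint, measures, path) {
  payload <- list(
    exposures = c(a = joint$exposure_a, b = joint$exposure_b),
    adjusted_for = joint$adjust,
    cells = cbind(joint$counts,
                  hr = c(1, unname(joint$hr[c("d01", "d10", "d11")]))[
                    match(joint$counts$cell, c("00", "01", "10", "11"))]),
    reri = as.list(measures$reri),
    ap = as.list(measures$ap),
    si = if (measures$si_defined) as.list(measures$si) else "undefined",
    ci_method = measures$method
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
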
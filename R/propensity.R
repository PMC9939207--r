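# Propensity-score model, greedy 1:1 nearest-neighbor matching on the
# logit of the score, and standardized-mean-difference balance diagnostics.

#' Fit the exposure propensity model
#'
#' Maximum-likelihood binary logistic regression of the treatment (ever
#' smoking by default) on baseline covariates; the fitted probability is
#' the propensity score.
#'
#' @param cohort cohort data.frame.
#' @param covariates character vector of covariate column names; character
#'   columns are converted to treatment-agnostic dummies via
#'   `model.matrix`.
#' @param treatment name of the binary 0/1 treatment column
#'   (default `"smoking"`).
#' @return object of class `propensity_model`: list with `coefficients`
#'   (intercept first, log-odds scale), `fitted` (per subject, in (0,1)),
#'   `converged`, `covariates`, `treatment`, and the underlying `glm`.
#' @export
fit_propensity <- function(cohort, covariates, treatment = "smoking") {
  check_columns(cohort, c(covariates, treatment))
  tr <- cohort[[treatment]]
  if (!all(tr %in% c(0, 1)))
    stopf("treatment column '%s' must be binary 0/1", treatment)
  if (sum(tr == 1) < 2L || sum(tr == 0) < 2L)
    stopf("need at least 2 subjects per exposure level (got %d treated, %d control)",
          sum(tr == 1), sum(tr == 0))
  dat <- cohort[, covariates, drop = FALSE]
  if (anyNA(dat))
    stopf("propensity covariates contain missing values")

  # complete-separation guard: a covariate whose ranges do not overlap
  # between groups makes the MLE diverge; name the culprit.
  for (cv in covariates) {
    x <- dat[[cv]]
    if (is.character(x) || is.factor(x)) next
    x1 <- x[tr == 1]; x0 <- x[tr == 0]
    if (max(x1) < min(x0) || max(x0) < min(x1))
      stopf("complete separation on covariate '%s'", cv)
  }

  dat[[treatment]] <- tr
  fml <- as.formula(paste(treatment, "~",
                          paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(
    glm(fml, data = dat, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100))
  )
  p <- fitted(fit)
  if (any(p <= 1e-12 | p >= 1 - 1e-12)) {
    # fitted probabilities numerically 0/1: quasi-separation
    sep <- names(which.max(abs(coef(fit)[-1])))
    stopf("complete or quasi-complete separation (covariate '%s')", sep)
  }
  structure(list(
    coefficients = coef(fit),
    fitted = as.numeric(p),
    converged = isTRUE(fit$converged),
    covariates = covariates,
    treatment = treatment,
    glm = fit
  ), class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("<propensity_model> treatment = %s, converged = %s\n",
              x$treatment, x$converged))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Greedy 1:1 nearest-neighbor matching on the propensity logit
#'
#' Treated subjects are processed in a seed-shuffled order; each is paired
#' with the closest still-available control on the logit of the propensity
#' score, without replacement.  Ties in distance are broken by the lower
#' control id.  A pair whose logit distance exceeds the caliper (expressed
#' as a multiple of the SD of the logit score over all subjects) is
#' discarded and the treated subject left unmatched.
#'
#' @param model a [fit_propensity()] result.
#' @param cohort the cohort the model was fitted on (row order must match).
#' @param caliper caliper width in SD-of-logit units (default 0.2), or
#'   `NULL`/`Inf` for no caliper.
#' @param seed integer seed for the processing order.
#' @return object of class `matched_pairs`: list with `pairs`
#'   (data.frame `treated_id`, `control_id`, `distance`), `unmatched_treated`,
#'   `unmatched_control`, `caliper`, `caliper_width` (absolute logit units),
#'   `seed`.
#' @export
match_nearest <- function(model, cohort, caliper = 0.2, seed = 1L) {
  stopifnot(inherits(model, "propensity_model"))
  check_columns(cohort, c("id", model$treatment))
  if (length(model$fitted) != nrow(cohort))
    stopf("model was fitted on %d subjects but cohort has %d rows",
          length(model$fitted), nrow(cohort))
  tr <- cohort[[model$treatment]]
  if (!any(tr == 1) || !any(tr == 0))
    stopf("both exposure groups must be non-empty")

  lg <- qlogis(model$fitted)
  width <- if (is.null(caliper) || !is.finite(caliper)) Inf
           else caliper * sd(lg)
  # degenerate case: identical scores give sd 0; with caliper 0 only
  # exact-score pairs are allowed, which a width of 0 implements
  if (is.na(width)) width <- Inf

  t_idx <- which(tr == 1)
  c_idx <- which(tr == 0)
  set.seed(as.integer(seed))
  t_idx <- t_idx[sample.int(length(t_idx))]

  # controls kept sorted by (logit, id) for nearest lookup
  ord <- order(lg[c_idx], cohort$id[c_idx])
  pool_idx <- c_idx[ord]
  pool_lg <- lg[pool_idx]
  pool_id <- cohort$id[pool_idx]
  alive <- rep(TRUE, length(pool_idx))

  pairs <- vector("list", length(t_idx))
  np <- 0L
  for (ti in t_idx) {
    cand <- which(alive)
    if (!length(cand)) break
    d <- abs(pool_lg[cand] - lg[ti])
    dmin <- min(d)
    if (dmin > width) next
    best <- cand[d == dmin]
    best <- best[which.min(pool_id[best])]   # tie-break: lower control id
    alive[best] <- FALSE
    np <- np + 1L
    pairs[[np]] <- c(cohort$id[ti], pool_id[best], dmin)
  }
  pairs <- if (np)
    do.call(rbind, pairs[seq_len(np)]) else matrix(numeric(0), ncol = 3)
  pairs <- data.frame(treated_id = pairs[, 1], control_id = pairs[, 2],
                      distance = pairs[, 3])
  if (!nrow(pairs)) warnf("no pairs satisfied the caliper")

  matched_t <- pairs$treated_id
  matched_c <- pairs$control_id
  structure(list(
    pairs = pairs,
    unmatched_treated = setdiff(cohort$id[tr == 1], matched_t),
    unmatched_control = setdiff(cohort$id[tr == 0], matched_c),
    caliper = caliper,
    caliper_width = width,
    seed = as.integer(seed)
  ), class = "matched_pairs")
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat(sprintf("<matched_pairs> %d pairs; %d treated and %d controls unmatched; caliper = %s SD\n",
              nrow(x$pairs), length(x$unmatched_treated),
              length(x$unmatched_control),
              if (is.finite(x$caliper_width)) format(x$caliper) else "none"))
  invisible(x)
}

#' Subset a cohort to matched subjects
#'
#' @param cohort cohort data.frame with an `id` column.
#' @param pairs a [match_nearest()] result.
#' @return the cohort rows whose id appears in a matched pair.
#' @export
matched_cohort <- function(cohort, pairs) {
  stopifnot(inherits(pairs, "matched_pairs"))
  keep <- c(pairs$pairs$treated_id, pairs$pairs$control_id)
  cohort[cohort$id %in% keep, , drop = FALSE]
}

# SMD between two vectors; binary vectors use the proportion analogue.
#' @noRd
smd_one <- function(x1, x0) {
  if (all(c(x1, x0) %in% c(0, 1))) {
    p1 <- mean(x1); p0 <- mean(x0)
    pooled <- (p1 * (1 - p1) + p0 * (1 - p0)) / 2
    if (pooled == 0) return(if (p1 == p0) 0 else Inf)
    return(abs(p1 - p0) / sqrt(pooled))
  }
  pooled <- (var(x1) + var(x0)) / 2
  if (is.na(pooled) || pooled == 0)
    return(if (isTRUE(all.equal(mean(x1), mean(x0)))) 0 else Inf)
  abs(mean(x1) - mean(x0)) / sqrt(pooled)
}

#' Standardized mean differences before and after matching
#'
#' Continuous covariates use
#' \eqn{|\bar x_1 - \bar x_0| / \sqrt{(s_1^2 + s_0^2)/2}}; binary
#' covariates the proportion-based analogue.  A zero pooled variance gives
#' SMD 0 when the means agree and `Inf` otherwise.  Character covariates
#' are expanded to one indicator per level.
#'
#' @param cohort cohort data.frame.
#' @param pairs a [match_nearest()] result (or `NULL` for before-only).
#' @param covariates covariate names.
#' @param treatment binary treatment column name.
#' @return data.frame of class `balance_report`: `covariate`, `smd_before`,
#'   `smd_after`.
#' @export
balance_smd <- function(cohort, pairs, covariates, treatment = "smoking") {
  check_columns(cohort, c(covariates, treatment, "id"))
  expand <- function(df) {
    out <- list()
    for (cv in covariates) {
      x <- df[[cv]]
      if (is.character(x) || is.factor(x)) {
        for (lv in sort(unique(as.character(cohort[[cv]]))))
          out[[paste0(cv, ":", lv)]] <- as.integer(as.character(x) == lv)
      } else out[[cv]] <- as.numeric(x)
    }
    out
  }
  compute <- function(df) {
    tr <- df[[treatment]]
    vars <- expand(df)
    vapply(vars, function(x) smd_one(x[tr == 1], x[tr == 0]), numeric(1))
  }
  before <- compute(cohort)
  after <- if (is.null(pairs)) rep(NA_real_, length(before))
           else compute(matched_cohort(cohort, pairs))
  structure(data.frame(covariate = names(before),
                       smd_before = unname(before),
                       smd_after = unname(after),
                       stringsAsFactors = FALSE),
            class = c("balance_report", "data.frame"))
}
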
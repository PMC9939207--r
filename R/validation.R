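# Calibration (Hosmer-Lemeshow) and cross-validated discrimination
# (AUROC) for the total risk score.

#' Hosmer-Lemeshow calibration test
#'
#' Subjects are binned into `g` equal-count groups by predicted
#' probability; the statistic is
#' \eqn{\sum_b (O_b - E_b)^2 / (E_b (1 - E_b/n_b))} with `g - 2` degrees
#' of freedom.  Bins whose probability boundaries coincide (fewer than `g`
#' distinct predictions) are merged with a warning and the degrees of
#' freedom adjusted.
#'
#' @param events 0/1 outcomes.
#' @param prob predicted probabilities in (0, 1).
#' @param g number of bins (default 10).
#' @return list with `chisq`, `df`, `p`, `table` (per-bin n, observed,
#'   expected).
#' @export
hosmer_lemeshow <- function(events, prob, g = 10) {
  if (length(events) != length(prob))
    stopf("'events' and 'prob' lengths differ")
  if (!all(events %in% c(0, 1))) stopf("'events' must be 0/1")
  if (any(prob <= 0 | prob >= 1))
    stopf("probabilities must lie strictly in (0, 1)")
  n <- length(events)
  if (n < g) stopf("need at least g = %d subjects", g)

  ord <- order(prob)
  # equal-count bins; identical boundary probabilities merge bins
  bin <- ceiling(seq_len(n) / (n / g))[rank(prob, ties.method = "first")]
  edges <- tapply(prob[ord], bin[ord], max)
  if (length(unique(signif(edges, 12))) < length(edges)) {
    warnf("fewer than %d distinct probability bins; merging", g)
    bin <- match(prob, sort(unique(prob)))
    bin <- ceiling(bin / (max(bin) / min(g, max(bin))))
  }
  bins <- sort(unique(bin))
  O <- tapply(events, bin, sum)
  E <- tapply(prob, bin, sum)
  nb <- tapply(events, bin, length)
  denom <- E * (1 - E / nb)
  ok <- denom > 0
  chisq <- sum(((O - E)^2 / denom)[ok])
  df <- max(length(bins) - 2L, 1L)
  list(chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE),
       table = data.frame(bin = bins, n = as.vector(nb),
                          observed = as.vector(O),
                          expected = as.vector(E)))
}

#' Area under the ROC curve (rank estimator)
#'
#' Mann-Whitney concordance with midranks for ties: the probability that
#' a random event subject has a more event-like score than a random
#' non-event subject, plus half the tie probability.  With
#' `orientation = "higher-risk"` (default) larger scores mean higher
#' predicted mortality; use `"lower-risk"` for survival-rate style scores
#' where larger is better (the score is negated internally).
#'
#' @param scores numeric scores.
#' @param labels 0/1 outcome labels; both classes must be present.
#' @param orientation `"higher-risk"` or `"lower-risk"`.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(1, 2, 3, 4), c(0, 0, 1, 1))
auroc <- function(scores, labels,
                  orientation = c("higher-risk", "lower-risk")) {
  orientation <- match.arg(orientation)
  if (length(scores) != length(labels))
    stopf("'scores' and 'labels' lengths differ")
  if (!all(labels %in% c(0, 1))) stopf("'labels' must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stopf("both outcome classes must be present")
  if (orientation == "lower-risk") scores <- -scores
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUROC of a score-building procedure
#'
#' Folds are stratified by event status.  For each fold the entire score
#' construction is re-run on the training 9/10 (by calling `builder` on
#' the training rows) and applied to the held-out rows; the held-out
#' (score, outcome) pairs are pooled and a single AUROC computed, with a
#' percentile bootstrap CI over resamples of the pooled pairs.  The
#' outcome is death-during-follow-up as a binary label (censoring time
#' ignored); `min_followup` optionally restricts to subjects whose
#' follow-up or event time reaches that many months, as a sensitivity
#' analysis.
#'
#' @param cohort cohort data.frame with `event` (and whatever columns the
#'   builder needs).
#' @param builder `function(train)` returning a `function(newdata)` that
#'   yields a numeric score per row.
#' @param k number of folds (default 10).
#' @param seed integer seed for fold assignment and bootstrap.
#' @param boot_reps bootstrap resamples for the CI (default 2000).
#' @param orientation passed to [auroc()]; default `"lower-risk"` because
#'   the survival-rate total score decreases with risk.
#' @param min_followup optional months; keep only subjects with
#'   `event == 1` or `time_months >= min_followup`.
#' @return object of class `cv_auroc`: list with `auroc`, `ci`,
#'   `per_fold`, `k`, `seed`, `folds` (assignment per retained row),
#'   `n`.
#' @export
cv_auroc <- function(cohort, builder, k = 10, seed = 1L,
                     boot_reps = 2000,
                     orientation = c("lower-risk", "higher-risk"),
                     min_followup = NULL) {
  orientation <- match.arg(orientation)
  check_columns(cohort, "event")
  if (!is.null(min_followup)) {
    check_columns(cohort, "time_months")
    cohort <- cohort[cohort$event == 1 |
                       cohort$time_months >= min_followup, , drop = FALSE]
  }
  n <- nrow(cohort)
  ev <- cohort$event
  if (sum(ev) < k || sum(1 - ev) < k)
    stopf("cannot stratify %d events / %d non-events into %d folds",
          sum(ev), sum(1 - ev), k)

  set.seed(as.integer(seed))
  fold <- integer(n)
  for (cls in c(0, 1)) {
    idx <- which(ev == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }

  pooled_score <- numeric(n)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    test <- fold == f
    predictor <- builder(cohort[!test, , drop = FALSE])
    pooled_score[test] <- predictor(cohort[test, , drop = FALSE])
    per_fold[f] <- if (length(unique(ev[test])) == 2)
      auroc(pooled_score[test], ev[test], orientation) else NA_real_
  }
  est <- auroc(pooled_score, ev, orientation)

  boot <- numeric(boot_reps)
  for (r in seq_len(boot_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[r] <- if (length(unique(ev[idx])) == 2)
      auroc(pooled_score[idx], ev[idx], orientation) else NA_real_
  }
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  structure(list(auroc = est, ci = ci, per_fold = per_fold, k = k,
                 seed = as.integer(seed), folds = fold, n = n),
            class = "cv_auroc")
}

#' @export
print.cv_auroc <- function(x, ...) {
  cat(sprintf("<cv_auroc> pooled AUROC = %.3f (95%% CI %.3f-%.3f), k = %d, n = %d\n",
              x$auroc, x$ci[1], x$ci[2], x$k, x$n))
  invisible(x)
}

#' Default score-building procedure for cross-validation
#'
#' Returns a builder closure for [cv_auroc()] that, on each training set,
#' re-derives survival-tree cut points for the continuous factors,
#' rebuilds the score table at the horizon, and scores new data by total
#' score.  Held-out categories falling outside the training table (never
#' happens with interval labels) would error loudly.
#'
#' @param categorical character vector of categorical factor columns.
#' @param continuous character vector of continuous factor columns (tree
#'   cut points re-derived per fold).
#' @param horizon score horizon in months.
#' @param max_leaves,min_leaf,alpha tree parameters, see [tree_cutoffs()].
#' @return `function(train)` -> `function(newdata)` -> numeric scores.
#' @export
score_builder <- function(categorical, continuous = character(),
                          horizon = 173, max_leaves = 3, min_leaf = 20,
                          alpha = 0.05) {
  force(categorical); force(continuous); force(horizon)
  function(train) {
    specs <- lapply(continuous, function(v)
      tree_cutoffs(train$time_months, train$event, train[[v]],
                   max_leaves = max_leaves, min_leaf = min_leaf,
                   alpha = alpha, variable = v))
    for (sp in specs) train <- categorize(train, sp)
    factors <- c(categorical,
                 vapply(specs, function(sp)
                   paste0(sp$variable, "_cat"), character(1)))
    # a factor that ended up single-category carries no information but
    # stays in the table (constant offset)
    tab <- build_score_table(train, factors, horizon = horizon)
    function(newdata) {
      for (sp in specs) newdata <- categorize(newdata, sp)
      total_score(newdata, tab)
    }
  }
}
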
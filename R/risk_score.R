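# Survival-rate risk score: survival-tree cut-point selection for
# continuous factors, per-category integer scores (KM survival at a fixed
# horizon divided by 10), total score, and quantile stratification.

#' Survival-tree cut-point selection for a continuous factor
#'
#' Recursive binary partitioning driven by the two-sample log-rank
#' statistic.  Candidate splits are the midpoints between sorted distinct
#' values of `x`; a split is admissible when both children hold at least
#' `min_leaf` subjects, and is accepted when its log-rank p-value is at
#' most `alpha`.  Leaves are split best-first (largest admissible
#' chi-square) until `max_leaves` is reached or no admissible split
#' remains.
#'
#' @param times,events follow-up (months) and 0/1 indicator.
#' @param x continuous factor values.
#' @param max_leaves maximum number of categories (default 3, giving at
#'   most two cut points).
#' @param min_leaf minimum subjects per category (default 20).
#' @param alpha significance level a split must reach (default 0.05).
#' @param variable name used for labels.
#' @return object of class `cutoff_spec`: list with `variable`, `cuts`
#'   (strictly increasing, possibly empty), `labels`, `stats` (per
#'   accepted split: cut, chisq, p).
#' @export
#' @examples
#' set.seed(1)
#' x <- runif(300, 0, 10)
#' tm <- rexp(300, rate = 0.02 * ifelse(x > 5, 2, 1))
#' tree_cutoffs(pmin(tm, 60), as.integer(tm <= 60), x)
tree_cutoffs <- function(times, events, x, max_leaves = 3, min_leaf = 20,
                         alpha = 0.05, variable = deparse(substitute(x))) {
  if (length(x) != length(times))
    stopf("'x' and 'times' lengths differ")
  if (anyNA(x)) stopf("'x' must not contain missing values")
  if (length(x) < 2 * min_leaf)
    stopf("need at least 2 * min_leaf = %d subjects", 2 * min_leaf)

  # Scan every candidate cut point at once: the k-th candidate's "left"
  # group is the union of the first k x-value blocks, so group-wise
  # at-risk and death counts are cumulative sums over blocks.  Equivalent
  # to a per-candidate log-rank loop (cross-checked in the tests) but
  # O(blocks x event-times) instead of O(blocks x n log n).
  best_split <- function(idx) {
    xs <- x[idx]
    ts <- times[idx]
    ev <- events[idx]
    ux <- sort(unique(xs))
    if (length(ux) < 2 || sum(ev) == 0) return(NULL)
    block <- match(xs, ux)
    dt <- sort(unique(ts[ev == 1]))
    at_risk <- outer(ts, dt, ">=")                     # n x J
    death <- outer(ts, dt, "==") & ev == 1
    fb <- factor(block, levels = seq_along(ux))
    Yb <- rowsum(at_risk + 0, fb)                      # B x J
    Db <- rowsum(death + 0, fb)
    Ya <- apply(Yb, 2, cumsum)                         # candidate k = first k blocks
    Da <- apply(Db, 2, cumsum)
    if (is.null(dim(Ya))) { Ya <- rbind(Ya); Da <- rbind(Da) }
    K <- length(ux) - 1
    Ya <- Ya[seq_len(K), , drop = FALSE]
    Da <- Da[seq_len(K), , drop = FALSE]
    Y <- colSums(Yb)
    d <- colSums(Db)
    frac <- sweep(Ya, 2, Y, "/")
    O <- rowSums(Da)
    E <- rowSums(sweep(frac, 2, d, "*"))
    vterm <- sweep(frac * (1 - frac), 2,
                   ifelse(Y > 1, d * (Y - d) / (Y - 1), 0), "*")
    V <- rowSums(vterm)
    nleft <- cumsum(tabulate(block, nbins = length(ux)))[seq_len(K)]
    chisq <- ifelse(V > 0, (O - E)^2 / V, NA_real_)
    admissible <- nleft >= min_leaf & (length(xs) - nleft) >= min_leaf &
      !is.na(chisq)
    if (!any(admissible)) return(NULL)
    k <- which(admissible)[which.max(chisq[admissible])]
    best <- list(cut = (ux[k] + ux[k + 1]) / 2, chisq = chisq[k],
                 p = pchisq(chisq[k], 1, lower.tail = FALSE))
    if (best$p > alpha) return(NULL)
    best
  }

  leaves <- list(seq_along(x))
  stats <- list()
  repeat {
    if (length(leaves) >= max_leaves) break
    cand <- lapply(leaves, best_split)
    ok <- !vapply(cand, is.null, logical(1))
    if (!any(ok)) break
    k <- which(ok)[which.max(vapply(cand[ok], `[[`, numeric(1), "chisq"))]
    sp <- cand[[k]]
    idx <- leaves[[k]]
    leaves[[k]] <- NULL
    leaves <- c(leaves, list(idx[x[idx] <= sp$cut]),
                list(idx[x[idx] > sp$cut]))
    stats[[length(stats) + 1L]] <- sp
  }

  cuts <- sort(vapply(stats, `[[`, numeric(1), "cut"))
  labels <- cut_labels(cuts)
  structure(list(variable = variable, cuts = cuts, labels = labels,
                 stats = do.call(rbind, lapply(stats, as.data.frame))),
            class = "cutoff_spec")
}

# Human-readable interval labels for a sorted cut vector; right-closed so
# x <= first cut falls in the first category.
#' @noRd
cut_labels <- function(cuts) {
  if (!length(cuts)) return("all")
  k <- length(cuts) + 1
  fmt <- function(v) format(signif(v, 6), trim = TRUE)
  lab <- character(k)
  lab[1] <- paste0("<=", fmt(cuts[1]))
  if (k > 2)
    for (i in 2:(k - 1))
      lab[i] <- paste0("(", fmt(cuts[i - 1]), "-", fmt(cuts[i]), "]")
  lab[k] <- paste0(">", fmt(cuts[length(cuts)]))
  lab
}

#' @export
print.cutoff_spec <- function(x, ...) {
  cat(sprintf("<cutoff_spec> %s: %s\n", x$variable,
              if (length(x$cuts)) paste(signif(x$cuts, 4), collapse = ", ")
              else "no cut points"))
  invisible(x)
}

#' Apply a cut-point spec to a cohort
#'
#' Adds a character category column named `<variable>_cat` using the
#' spec's right-closed intervals.
#'
#' @param cohort cohort data.frame.
#' @param spec a [tree_cutoffs()] result.
#' @return the cohort with the new category column.
#' @export
categorize <- function(cohort, spec) {
  stopifnot(inherits(spec, "cutoff_spec"))
  check_columns(cohort, spec$variable)
  x <- cohort[[spec$variable]]
  idx <- findInterval(x, spec$cuts, left.open = FALSE) + 1L
  # findInterval counts cuts <= x; right-closed wants x <= cut in the
  # lower bin, so shift exact boundary hits down
  if (length(spec$cuts))
    idx <- idx - as.integer(x %in% spec$cuts)
  cohort[[paste0(spec$variable, "_cat")]] <- spec$labels[idx]
  cohort
}

#' Integer risk score from a survival percentage
#'
#' `round(survival_percent / 10)` with half-up rounding (2.5 scores 3),
#' so scores lie in 0..10.  Vectorized.
#'
#' @param survival_percent value(s) in \[0, 100\].
#' @return integer score(s).
#' @export
#' @examples
#' assign_score(c(86, 59, 70, 8, 24))
assign_score <- function(survival_percent) {
  if (any(is.na(survival_percent)))
    stopf("survival percent must not be missing")
  if (any(survival_percent < 0 | survival_percent > 100))
    stopf("survival percent must lie in [0, 100]")
  as.integer(floor(survival_percent / 10 + 0.5))
}

#' Build the per-category survival-rate score table
#'
#' For each factor and each of its categories, estimates Kaplan-Meier
#' survival at the horizon on that category's subjects and converts it to
#' an integer score via [assign_score()].
#'
#' @param cohort cohort data.frame with `time_months`, `event`, and one
#'   (categorical) column per factor.  Continuous factors must have been
#'   categorized first (see [tree_cutoffs()] / [categorize()]).
#' @param factors character vector of categorical factor column names.
#' @param horizon horizon t* in months (default 173).
#' @return object of class `score_table`: data.frame with `factor`,
#'   `category`, `n`, `survival_percent`, `score`; attributes `horizon`
#'   and `factors`.
#' @export
build_score_table <- function(cohort, factors, horizon = 173) {
  check_columns(cohort, c("time_months", "event", factors))
  check_scalar(horizon, "horizon", lower = 0)
  rows <- list()
  for (fc in factors) {
    vals <- cohort[[fc]]
    if (anyNA(vals))
      stopf("factor '%s' has missing categories", fc)
    for (lv in sort(unique(as.character(vals)))) {
      sub <- cohort[vals == lv, , drop = FALSE]
      if (!nrow(sub)) stopf("factor '%s' category '%s' is empty", fc, lv)
      sp <- survival_at(km_estimate(sub$time_months, sub$event), horizon)
      rows[[length(rows) + 1L]] <- data.frame(
        factor = fc, category = lv, n = nrow(sub),
        survival_percent = sp, score = assign_score(sp),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "horizon") <- horizon
  attr(out, "factors") <- factors
  class(out) <- c("score_table", "data.frame")
  out
}

#' Total risk score per subject
#'
#' Sums the per-factor scores matched by each subject's category.  Errors
#' (naming the factor) if a subject's category is absent from the table.
#'
#' @param cohort cohort data.frame holding every factor column of `table`.
#' @param table a [build_score_table()] result.
#' @return integer vector of total scores, one per row of `cohort`.
#' @export
total_score <- function(cohort, table) {
  stopifnot(inherits(table, "score_table"))
  factors <- attr(table, "factors")
  check_columns(cohort, factors)
  total <- integer(nrow(cohort))
  for (fc in factors) {
    sub <- table[table$factor == fc, ]
    idx <- match(as.character(cohort[[fc]]), sub$category)
    if (anyNA(idx)) {
      bad <- unique(as.character(cohort[[fc]])[is.na(idx)])
      stopf("factor '%s': category '%s' not in score table", fc, bad[1])
    }
    total <- total + sub$score[idx]
  }
  total
}

#' Stratify total scores into quantile groups
#'
#' Empirical quantiles (R's default type-7 linear interpolation) split the
#' scores into group 1 (`T < q25`), group 2 (`q25 <= T < q75`) and group 3
#' (`T >= q75`) for the default `probs = c(0.25, 0.75)`.
#'
#' @param total integer/numeric total scores.
#' @param probs quantile probabilities (strictly increasing, in (0,1)).
#' @return list with `group` (integer labels 1..k), `boundaries` (the
#'   quantile values).
#' @export
group_by_quantiles <- function(total, probs = c(0.25, 0.75)) {
  if (!length(total)) stopf("no scores supplied")
  if (any(diff(probs) <= 0) || any(probs <= 0 | probs >= 1))
    stopf("'probs' must be strictly increasing within (0, 1)")
  if (length(unique(total)) == 1L) {
    warnf("all total scores identical; single group")
    return(list(group = rep(1L, length(total)),
                boundaries = numeric(0)))
  }
  q <- unname(quantile(total, probs, type = 7))
  group <- findInterval(total, q, left.open = FALSE) + 1L
  # findInterval puts T == q into the upper side already (q <= T);
  # matches group 2 = [q25, q75), group 3 = [q75, ...]
  list(group = group, boundaries = q)
}

#' Cox risk estimates for the total score
#'
#' Fits (i) a Cox model with the total score as a continuous covariate
#' (per-unit HR) and (ii) a Cox model on quantile-group dummies versus
#' group 1, both adjusted for the supplied covariates.
#'
#' @param cohort cohort data.frame with `time_months`, `event`.
#' @param total total scores (one per row).
#' @param adjust adjustment covariate names.
#' @param probs quantile probabilities for grouping.
#' @return list with `per_unit` (`beta`, `se`, `hr`, `lower`, `upper`,
#'   `p`), `groups` (data.frame of group HRs vs group 1), `boundaries`.
#' @export
score_mortality_hr <- function(cohort, total, adjust = character(),
                               probs = c(0.25, 0.75)) {
  check_columns(cohort, c("time_months", "event"))
  if (length(total) != nrow(cohort))
    stopf("'total' length does not match cohort rows")
  am <- adjust_matrix(cohort, adjust)
  xm <- bind_covariates(data.frame(total = as.numeric(total)), am)
  f1 <- fit_cox(cohort$time_months, cohort$event, xm)
  ci <- hr_ci(f1, "total")
  b <- unname(f1$coefficients["total"]); s <- unname(f1$se["total"])
  per_unit <- list(beta = b, se = s, hr = ci[["hr"]],
                   lower = ci[["lower"]], upper = ci[["upper"]],
                   p = 2 * pnorm(-abs(b / s)))

  gq <- group_by_quantiles(total, probs)
  k <- max(gq$group)
  groups <- NULL
  if (k > 1) {
    gm <- lapply(2:k, function(g) as.integer(gq$group == g))
    names(gm) <- paste0("group", 2:k)
    xm2 <- bind_covariates(as.data.frame(gm), am)
    f2 <- fit_cox(cohort$time_months, cohort$event, xm2)
    groups <- do.call(rbind, lapply(2:k, function(g) {
      nm <- paste0("group", g)
      ci <- hr_ci(f2, nm)
      data.frame(group = g, hr = ci[["hr"]], lower = ci[["lower"]],
                 upper = ci[["upper"]])
    }))
  }
  list(per_unit = per_unit, groups = groups, boundaries = gq$boundaries,
       group = gq$group)
}
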
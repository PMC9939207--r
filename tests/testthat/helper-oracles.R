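# Independent oracles used across the suite.  These stay deliberately
# naive (loops, enumeration) and never call the code paths they check.

# Cox partial log-likelihood, written straight from its definition.
# `x` is a one-column matrix / vector; `beta` scalar.
oracle_cox_loglik <- function(beta, times, events, x,
                              ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.numeric(x)
  eta <- beta * x
  dt <- sort(unique(times[events == 1]))
  ll <- 0
  for (t in dt) {
    risk <- times >= t
    dead <- times == t & events == 1
    d <- sum(dead)
    ll <- ll + sum(eta[dead])
    if (ties == "breslow") {
      ll <- ll - d * log(sum(exp(eta[risk])))
    } else {
      sr <- sum(exp(eta[risk]))
      sd <- sum(exp(eta[dead]))
      for (l in seq_len(d) - 1)
        ll <- ll - log(sr - (l / d) * sd)
    }
  }
  ll
}

# Grid/line-search maximizer of the oracle partial likelihood.
oracle_cox_mle <- function(times, events, x, ties = "efron",
                           lower = -5, upper = 5) {
  opt <- optimize(function(b) oracle_cox_loglik(b, times, events, x, ties),
                  c(lower, upper), maximum = TRUE, tol = 1e-7)
  opt$maximum
}

# Brute-force optimal 1:1 assignment (total |score| distance) by
# enumerating all permutations; for tiny problems only.
oracle_optimal_assignment <- function(treated_scores, control_scores) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_along(control_scores))) {
    tot <- sum(abs(treated_scores - control_scores[p]))
    if (tot < best) best <- tot
  }
  best
}

# Quick exponential two-group survival data with optional censoring.
make_surv <- function(n, rate0 = 0.02, hr = 1, p_group = 0.5,
                      cens_rate = 0.01, horizon = 120, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- rbinom(n, 1, p_group)
  tfail <- rexp(n, rate0 * ifelse(g == 1, hr, 1))
  cens <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
  time <- pmin(tfail, cens, horizon)
  data.frame(time = time, event = as.integer(tfail <= pmin(cens, horizon)),
             group = g)
}

# Minimal propensity_model stub for matching tests with chosen scores.
fake_ps_model <- function(scores, treatment = "smoking") {
  structure(list(coefficients = c(`(Intercept)` = 0),
                 fitted = scores, converged = TRUE,
                 covariates = character(), treatment = treatment,
                 glm = NULL),
            class = "propensity_model")
}

# Adjustment sets: the conventional baseline five, and the full list of
# hazard-relevant covariates under which the generator's Cox model is
# correctly specified (needed for conditional-HR recovery, because the
# hazard ratio is non-collapsible over the strong tumor-factor effects).
baseline_adjust <- c("age", "sex", "drinking", "bmi", "family_history")
full_adjust <- c(baseline_adjust, "tnm_stage", "invasion_depth",
                 "n_category", "distant_metastasis", "lauren", "embolus",
                 "tumor_size", "wbc", "hemoglobin", "nlr", "plr")

# Per-category survival percent / printed score pairs of the published
# 13-factor score table (31 categories), used for exact score-rule and
# total-bound checks.
published_score_rows <- function() {
  df <- rbind(
    c("tnm",       "I/II",   86, 9), c("tnm",    "III/IV",  46, 5),
    c("invasion",  "T1/T2",  88, 9), c("invasion", "T3/T4", 50, 5),
    c("ncat",      "N0",     82, 8), c("ncat",   "N1",      61, 6),
    c("ncat",      "N2",     38, 4), c("ncat",   "N3",      20, 2),
    c("metastasis", "neg",   64, 6), c("metastasis", "pos",  8, 1),
    c("lauren",    "intestinal", 70, 7), c("lauren", "diffuse", 49, 5),
    c("embolus",   "neg",    66, 7), c("embolus", "pos",    44, 4),
    c("size",      "<=5.8",  66, 7), c("size",   ">5.8",    43, 4),
    c("nodes",     "Q1",     74, 7), c("nodes",  "Q2",      42, 4),
    c("nodes",     "Q3",     21, 2),
    c("wbc",       "Q1",     59, 6), c("wbc",    "Q2",      46, 5),
    c("hemoglobin", "Q1",    49, 5), c("hemoglobin", "Q2",  59, 6),
    c("hemoglobin", "Q3",    70, 7),
    c("nlr",       "Q1",     68, 7), c("nlr",    "Q2",      58, 6),
    c("nlr",       "Q3",     46, 5),
    c("plr",       "Q1",     60, 6), c("plr",    "Q2",      46, 5),
    c("metsyn",    "no",     60, 6), c("metsyn", "yes",     24, 2)
  )
  data.frame(factor = df[, 1], category = df[, 2],
             survival = as.numeric(df[, 3]), score = as.integer(df[, 4]),
             stringsAsFactors = FALSE)
}
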
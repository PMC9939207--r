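# Synthetic surgical-cohort generator.
#
# A single seeded stream drives all draws, in this documented order:
# demographics (age, sex, drinking, family history) -> smoking ->
# metabolic component flags -> metabolic measurements -> blood indexes ->
# tumor factors -> latent failure time -> dropout time.  Changing the order
# would change the stream, so it is part of the reproducibility contract.

#' Column dictionary for the cohort interchange format
#'
#' One row per column of the flat cohort CSV: name, storage type, and a
#' short description with units.  This is the single source of truth; a
#' copy ships as `inst/extdata/cohort_schema.tsv` for use outside R.
#'
#' @return data.frame with columns `column`, `type`, `description`.
#' @export
cohort_schema <- function() {
  s <- rbind(
    c("id", "integer", "subject identifier"),
    c("age", "numeric", "age at surgery, years"),
    c("sex", "character", "male / female"),
    c("drinking", "integer", "ever alcohol drinking (0/1)"),
    c("family_history", "integer", "family cancer history (0/1)"),
    c("bmi", "numeric", "body-mass index, kg/m^2"),
    c("fbg", "numeric", "fasting blood glucose, mmol/L"),
    c("glucose_2h", "numeric", "2-h plasma glucose, mmol/L (may be NA)"),
    c("diabetes_dx", "integer", "previously diagnosed diabetes (0/1)"),
    c("sbp", "numeric", "systolic blood pressure, mm Hg"),
    c("dbp", "numeric", "diastolic blood pressure, mm Hg"),
    c("antihypertensive", "integer", "on antihypertensive therapy (0/1)"),
    c("triglycerides", "numeric", "serum triglycerides, mmol/L"),
    c("hdlc", "numeric", "HDL cholesterol, mmol/L"),
    c("neutrophil", "numeric", "neutrophil count, 10^9/L"),
    c("lymphocyte", "numeric", "lymphocyte count, 10^9/L"),
    c("monocyte", "numeric", "monocyte count, 10^9/L"),
    c("eosinophil", "numeric", "eosinophil count, 10^9/L"),
    c("basophil", "numeric", "basophil count, 10^9/L"),
    c("wbc", "numeric", "white blood cell count, 10^9/L"),
    c("rbc", "numeric", "red blood cell count, 10^12/L"),
    c("hemoglobin", "numeric", "hemoglobin, g/L"),
    c("rdw", "numeric", "red cell distribution width, %"),
    c("platelet", "numeric", "platelet count, 10^9/L"),
    c("tnm_stage", "character", "TNM stage: I/II or III/IV"),
    c("invasion_depth", "character", "invasion depth: T1/T2 or T3/T4"),
    c("n_category", "character", "regional nodes: N0, N1, N2, N3"),
    c("distant_metastasis", "integer", "distant metastasis (0/1)"),
    c("lauren", "character", "Lauren type: intestinal / diffuse"),
    c("embolus", "integer", "tumor embolus (0/1)"),
    c("tumor_size", "numeric", "tumor size, cm"),
    c("positive_nodes", "integer", "number of positive regional nodes"),
    c("smoking", "integer", "ever cigarette smoking (0/1)"),
    c("time_months", "numeric", "follow-up time, months"),
    c("event", "integer", "1 = cancer-specific death, 0 = censored")
  )
  data.frame(column = s[, 1], type = s[, 2], description = s[, 3],
             stringsAsFactors = FALSE)
}

# Empty cohort with correct column types.
#' @noRd
empty_cohort <- function() {
  sch <- cohort_schema()
  cols <- lapply(sch$type, function(tp) switch(tp,
    integer = integer(0), numeric = numeric(0), character = character(0)))
  names(cols) <- sch$column
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# Truncated-normal draw via inverse CDF; vectorized over n.
#' @noRd
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic surgical cancer cohort
#'
#' Draws a subject-level table with demographics, metabolic measurements,
#' blood-count indexes, tumor pathology, confounded smoking assignment and
#' proportional-hazards survival with a configurable additive interaction
#' between ever-smoking and metabolic syndrome (see [sim_config()] for the
#' hazard model).  Event time is the minimum of the latent failure time,
#' an exponential dropout time, and the administrative horizon; the event
#' flag is 1 only for failures.
#'
#' The generated metabolic measurements are consistent with the drawn
#' component flags, so [classify_metabolic()] applied to the output
#' recovers the generating status exactly.  The generating exposure flags
#' are attached as `attr(cohort, "truth")` for recovery tests.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return a `data.frame` following [cohort_schema()].
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(n_subjects = 200, seed = 7))
#' mean(coh$event)
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  n <- as.integer(config$n_subjects)
  if (n == 0L) return(empty_cohort())

  set.seed(if (is.null(seed)) as.integer(config$seed) else as.integer(seed))

  # --- demographics -------------------------------------------------------
  age <- rnorm(n, config$age_mean, config$age_sd)
  age <- pmin(pmax(age, 18), 95)
  male <- rbinom(n, 1, config$p_male)
  drinking <- rbinom(n, 1, config$p_drinking)
  famhx <- rbinom(n, 1, config$p_family_history)

  # --- smoking (confounded assignment) ------------------------------------
  lp_smoke <- config$smoke_intercept + config$smoke_b_male * male +
    config$smoke_b_drinking * drinking + config$smoke_b_age * (age - 60)
  smoking <- rbinom(n, 1, plogis(lp_smoke))

  # --- metabolic component flags ------------------------------------------
  obesity <- rbinom(n, 1, config$p_obesity)
  hyperglycemia <- rbinom(n, 1, config$p_hyperglycemia)
  hypertension <- rbinom(n, 1, config$p_hypertension)
  dyslipidemia <- rbinom(n, 1, config$p_dyslipidemia)
  metsyn <- as.integer(obesity + hyperglycemia + hypertension +
                         dyslipidemia >= 3L)

  # --- measurements consistent with the flags -----------------------------
  bmi <- ifelse(obesity == 1,
                rtnorm(n, config$bmi_mean, config$bmi_sd, lower = 25),
                rtnorm(n, config$bmi_mean, config$bmi_sd, upper = 24.99))

  dm_among_hg <- rbinom(n, 1, 0.25)
  fbg <- ifelse(hyperglycemia == 1,
                6.1 + rexp(n, rate = 1 / 1.5),
                rtnorm(n, 5.1, 0.5, lower = 3.0, upper = 6.05))
  diabetes_dx <- as.integer(hyperglycemia == 1 & dm_among_hg == 1)
  has_ogtt <- rbinom(n, 1, 0.30) == 1
  g2h_hi <- 7.8 + rexp(n, rate = 1 / 2)
  g2h_lo <- runif(n, 4.5, 7.7)
  glucose_2h <- ifelse(hyperglycemia == 1, g2h_hi, g2h_lo)
  glucose_2h[!has_ogtt] <- NA_real_

  on_meds <- rbinom(n, 1, 0.30)
  antihypertensive <- as.integer(hypertension == 1 & on_meds == 1)
  sbp_hi <- 140 + rexp(n, rate = 1 / 12)
  sbp_lo <- runif(n, 100, 139.5)
  dbp_hi <- runif(n, 70, 95)
  dbp_lo <- runif(n, 60, 89.5)
  sbp <- ifelse(hypertension == 1 & antihypertensive == 0, sbp_hi, sbp_lo)
  dbp <- ifelse(hypertension == 1 & antihypertensive == 0, dbp_hi, dbp_lo)

  via_tg <- rbinom(n, 1, 0.70)
  tg_hi <- 1.7 + rexp(n, rate = 1 / 0.8)
  tg_lo <- runif(n, 0.5, 1.69)
  triglycerides <- ifelse(dyslipidemia == 1 & via_tg == 1, tg_hi, tg_lo)
  hdlc_floor <- ifelse(male == 1, 0.9, 1.0)
  hdlc_lo <- hdlc_floor - runif(n, 0.05, 0.35)
  hdlc_ok <- hdlc_floor + runif(n, 0.02, 0.8)
  hdlc <- ifelse(dyslipidemia == 1 & via_tg == 0, hdlc_lo, hdlc_ok)

  # --- blood indexes -------------------------------------------------------
  bl <- config$blood
  neutrophil <- rlnorm(n, bl$neutrophil[1], bl$neutrophil[2])
  lymphocyte <- rlnorm(n, bl$lymphocyte[1], bl$lymphocyte[2])
  monocyte <- rlnorm(n, bl$monocyte[1], bl$monocyte[2])
  eosinophil <- rlnorm(n, bl$eosinophil[1], bl$eosinophil[2])
  basophil <- rlnorm(n, bl$basophil[1], bl$basophil[2])
  wbc <- neutrophil + lymphocyte + monocyte + eosinophil + basophil
  rbc <- rlnorm(n, bl$rbc[1], bl$rbc[2])
  hemoglobin <- rnorm(n, bl$hemoglobin[1], bl$hemoglobin[2])
  hemoglobin <- pmax(hemoglobin, 50)
  rdw <- pmax(rnorm(n, bl$rdw[1], bl$rdw[2]), 10)
  platelet <- rlnorm(n, bl$platelet[1], bl$platelet[2])

  # --- tumor factors (independent of exposures by default) ----------------
  tnm34 <- rbinom(n, 1, config$p_tnm34)
  t34 <- rbinom(n, 1, config$p_t34)
  ncat <- sample.int(4L, n, replace = TRUE, prob = config$p_ncat) - 1L
  metastasis <- rbinom(n, 1, config$p_metastasis)
  diffuse <- rbinom(n, 1, config$p_diffuse)
  embolus <- rbinom(n, 1, config$p_embolus)
  tumor_size <- rlnorm(n, config$tumor_size_meanlog, config$tumor_size_sdlog)
  # positive node counts consistent with the N category (AJCC bands)
  positive_nodes <- integer(n)
  positive_nodes[ncat == 1] <- sample(1:2, sum(ncat == 1), replace = TRUE)
  positive_nodes[ncat == 2] <- sample(3:6, sum(ncat == 2), replace = TRUE)
  positive_nodes[ncat == 3] <- 7L + rnbinom(sum(ncat == 3), size = 3,
                                            mu = 6)

  # --- hazard and follow-up ------------------------------------------------
  hz <- config$hazards
  ah <- config$adjust_hazards
  nlr <- neutrophil / lymphocyte
  plr <- platelet / lymphocyte
  lp <- hz$tnm34 * tnm34 + hz$t34 * t34 +
    hz$n1 * (ncat == 1) + hz$n2 * (ncat == 2) + hz$n3 * (ncat == 3) +
    hz$metastasis * metastasis + hz$diffuse * diffuse +
    hz$embolus * embolus + hz$size_per_cm * (tumor_size - 4.7) +
    hz$wbc_per_unit * (wbc - 6.5) +
    hz$hemoglobin_per_g * (hemoglobin - 130) +
    hz$nlr_per_unit * (nlr - 2) + hz$plr_per_unit * (plr - 150) +
    ah$age_per_year * (age - 60) + ah$male * male +
    ah$drinking * drinking + ah$family_history * famhx +
    ah$bmi_per_unit * (bmi - 22.5)
  reri_true <- config$hr11 - config$hr10 - config$hr01 + 1
  m <- 1 + (config$hr10 - 1) * smoking + (config$hr01 - 1) * metsyn +
    reri_true * smoking * metsyn
  if (any(m <= 0))
    stopf("joint-exposure hazard multiplier is non-positive for some cell")
  rate <- config$baseline_rate * exp(lp) * m

  t_fail <- rexp(n, rate = rate)
  t_drop <- if (config$dropout_rate > 0)
    rexp(n, rate = config$dropout_rate) else rep(Inf, n)
  t_cens <- pmin(t_drop, config$horizon_months)
  time_months <- pmin(t_fail, t_cens)
  event <- as.integer(t_fail <= t_cens)

  cohort <- data.frame(
    id = seq_len(n),
    age = age,
    sex = ifelse(male == 1, "male", "female"),
    drinking = drinking,
    family_history = famhx,
    bmi = bmi,
    fbg = fbg,
    glucose_2h = glucose_2h,
    diabetes_dx = diabetes_dx,
    sbp = sbp, dbp = dbp,
    antihypertensive = antihypertensive,
    triglycerides = triglycerides,
    hdlc = hdlc,
    neutrophil = neutrophil, lymphocyte = lymphocyte,
    monocyte = monocyte, eosinophil = eosinophil, basophil = basophil,
    wbc = wbc, rbc = rbc, hemoglobin = hemoglobin, rdw = rdw,
    platelet = platelet,
    tnm_stage = ifelse(tnm34 == 1, "III/IV", "I/II"),
    invasion_depth = ifelse(t34 == 1, "T3/T4", "T1/T2"),
    n_category = paste0("N", ncat),
    distant_metastasis = metastasis,
    lauren = ifelse(diffuse == 1, "diffuse", "intestinal"),
    embolus = embolus,
    tumor_size = tumor_size,
    positive_nodes = as.integer(positive_nodes),
    smoking = smoking,
    time_months = time_months,
    event = event,
    stringsAsFactors = FALSE
  )
  attr(cohort, "truth") <- data.frame(
    id = seq_len(n), obesity = obesity, hyperglycemia = hyperglycemia,
    hypertension = hypertension, dyslipidemia = dyslipidemia,
    metsyn = metsyn, rate = rate
  )
  cohort
}

#' Analytic additive-interaction truth implied by a simulation config
#'
#' Applies the RERI / AP / SI identities to the configured joint-exposure
#' hazard multipliers; used as the known truth in recovery and coverage
#' tests.
#'
#' @param config a [sim_config()].
#' @return list with elements `reri`, `ap`, `si` (`si` is `NA` and flagged
#'   by `si_defined = FALSE` when the excess-risk denominator
#'   `(hr10 - 1) + (hr01 - 1)` is not positive).
#' @export
#' @examples
#' true_interaction(sim_config(hr10 = 1.07, hr01 = 1.59, hr11 = 4.08))
true_interaction <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  interaction_measures(config$hr10, config$hr01, config$hr11)
}

#' Write / read a cohort CSV
#'
#' The interchange format is a flat CSV whose header matches
#' [cohort_schema()] exactly.  `read_cohort()` validates the header and
#' column types and errors with a column-level diagnostic on mismatch.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `read_cohort()` returns the validated data.frame.
#' @export
write_cohort <- function(cohort, path) {
  check_columns(cohort, cohort_schema()$column, where = "cohort")
  write.csv(cohort[, cohort_schema()$column], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  sch <- cohort_schema()
  check_columns(df, sch$column, where = sprintf("cohort file '%s'", path))
  for (i in seq_len(nrow(sch))) {
    cl <- sch$column[i]
    df[[cl]] <- switch(sch$type[i],
                       integer = as.integer(df[[cl]]),
                       numeric = as.numeric(df[[cl]]),
                       character = as.character(df[[cl]]))
  }
  bad <- df$time_months <= 0 & !is.na(df$time_months)
  if (any(bad))
    stopf("cohort file '%s': non-positive follow-up time for id(s) %s",
          path, paste(head(df$id[bad], 5), collapse = ", "))
  if (!all(df$event %in% c(0L, 1L)))
    stopf("cohort file '%s': column 'event' must be 0/1", path)
  df
}
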
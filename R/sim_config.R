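#' Simulation configuration for synthetic surgical cohorts
#'
#' Builds the parameter object consumed by [generate_cohort()]. Defaults
#' describe a plausible East-Asian surgical gastric-cancer cohort: median
#' age about 60 years, a heavily male and heavily smoking population,
#' metabolic-syndrome prevalence near 5%, about 45% cancer-specific deaths
#' during follow-up and heavy censoring (random dropout plus an
#' administrative cutoff at 183.3 months).
#'
#' The two exposures of interest are ever-smoking and metabolic syndrome.
#' Their joint effect on the hazard is parameterized *additively*: the
#' hazard multiplier for a subject with smoking indicator `s` and
#' metabolic-syndrome indicator `g` is
#' \deqn{m(s, g) = 1 + (hr10 - 1) s + (hr01 - 1) g + RERI \cdot s g}
#' with \eqn{RERI = hr11 - hr10 - hr01 + 1}, so the configured
#' relative excess risk due to interaction is an exact simulation
#' parameter, not a by-product.  `hr10` is the multiplier for smoker-only,
#' `hr01` for metabolic-syndrome-only and `hr11` for both, all relative to
#' the doubly unexposed cell.
#'
#' Smoking is assigned by a logistic model in sex, drinking and age so that
#' naive smoker versus never-smoker contrasts are confounded; the
#' propensity-matching stage exists to remove exactly this.
#'
#' Metabolic components are drawn as Bernoulli flags at the configured
#' prevalences and the underlying measurements (fasting glucose, blood
#' pressure, triglycerides, HDL cholesterol, BMI) are then drawn
#' consistently with each flag, so that [classify_metabolic()] recovers the
#' generated status exactly.
#'
#' @param n_subjects number of subjects (>= 0).
#' @param seed integer seed; all draws derive from this single stream.
#' @param age_mean,age_sd age at surgery, years.
#' @param p_male,p_drinking,p_family_history covariate prevalences.
#' @param bmi_mean,bmi_sd body-mass index, kg/m^2 (before conditioning on
#'   the obesity flag).
#' @param smoke_intercept,smoke_b_male,smoke_b_drinking,smoke_b_age
#'   log-odds model for ever-smoking; age enters per year, centred at 60.
#' @param p_obesity,p_hyperglycemia,p_hypertension,p_dyslipidemia
#'   metabolic-component prevalences (independent Bernoulli draws).
#' @param p_tnm34,p_t34,p_metastasis,p_diffuse,p_embolus tumor-factor
#'   category probabilities; `p_ncat` is the length-4 probability vector
#'   for N0--N3.
#' @param p_ncat probabilities for regional node categories N0--N3.
#' @param tumor_size_meanlog,tumor_size_sdlog log-normal tumor size, cm.
#' @param hazards named list of per-category / per-unit log-hazards for the
#'   tumor and blood prognostic factors (see defaults for names; continuous
#'   terms are centred at typical values inside the generator).
#' @param adjust_hazards named list of log-hazards for the adjustment
#'   covariates (age per year centred at 60, male, drinking,
#'   family_history, bmi per kg/m^2 centred at 22.5).
#' @param hr10,hr01,hr11 joint-exposure hazard multipliers: smoker-only,
#'   metabolic-syndrome-only, and both, versus neither.  All must be > 0.
#' @param baseline_rate baseline hazard per month for the doubly unexposed
#'   reference subject (all categorical factors at reference, continuous
#'   factors at their centring values).
#' @param dropout_rate exponential random-dropout rate per month
#'   (independent censoring); 0 disables dropout.
#' @param horizon_months administrative censoring horizon, months.
#' @param blood named list of `c(meanlog, sdlog)` pairs for the log-normal
#'   blood counts, plus normal mean/sd for hemoglobin and RDW.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [generate_cohort()], [true_interaction()]
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 500, seed = 42)
#' cfg$hr11
sim_config <- function(n_subjects = 2000,
                       seed = 1L,
                       age_mean = 60, age_sd = 10,
                       p_male = 0.80,
                       p_drinking = 0.25,
                       p_family_history = 0.15,
                       bmi_mean = 22.3, bmi_sd = 3,
                       smoke_intercept = -0.3,
                       smoke_b_male = 2.2,
                       smoke_b_drinking = 1.0,
                       smoke_b_age = 0.02,
                       p_obesity = 0.20,
                       p_hyperglycemia = 0.25,
                       p_hypertension = 0.30,
                       p_dyslipidemia = 0.25,
                       p_tnm34 = 0.71,
                       p_t34 = 0.81,
                       p_ncat = c(0.31, 0.32, 0.30, 0.07),
                       p_metastasis = 0.105,
                       p_diffuse = 0.57,
                       p_embolus = 0.36,
                       tumor_size_meanlog = log(4.7),
                       tumor_size_sdlog = 0.45,
                       hazards = list(
                         tnm34 = log(3.0),
                         t34 = log(2.0),
                         n1 = log(1.8), n2 = log(3.0), n3 = log(5.0),
                         metastasis = log(3.5),
                         diffuse = log(1.8),
                         embolus = log(1.6),
                         size_per_cm = log(1.12),
                         wbc_per_unit = 0.05,
                         hemoglobin_per_g = -0.008,
                         nlr_per_unit = 0.08,
                         plr_per_unit = 0.002
                       ),
                       adjust_hazards = list(
                         age_per_year = 0.02,
                         male = 0.10,
                         drinking = 0,
                         family_history = 0,
                         bmi_per_unit = 0
                       ),
                       hr10 = 1.07, hr01 = 1.59, hr11 = 4.08,
                       baseline_rate = 4e-4,
                       dropout_rate = 0.007,
                       horizon_months = 183.3,
                       blood = list(
                         neutrophil = c(log(3.4), 0.35),
                         lymphocyte = c(log(1.8), 0.30),
                         monocyte = c(log(0.40), 0.35),
                         eosinophil = c(log(0.12), 0.60),
                         basophil = c(log(0.03), 0.50),
                         rbc = c(log(4.4), 0.10),
                         platelet = c(log(240), 0.30),
                         hemoglobin = c(131, 22),
                         rdw = c(13.5, 1.2)
                       )) {
  cfg <- list(
    n_subjects = n_subjects, seed = seed,
    age_mean = age_mean, age_sd = age_sd,
    p_male = p_male, p_drinking = p_drinking,
    p_family_history = p_family_history,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    smoke_intercept = smoke_intercept, smoke_b_male = smoke_b_male,
    smoke_b_drinking = smoke_b_drinking, smoke_b_age = smoke_b_age,
    p_obesity = p_obesity, p_hyperglycemia = p_hyperglycemia,
    p_hypertension = p_hypertension, p_dyslipidemia = p_dyslipidemia,
    p_tnm34 = p_tnm34, p_t34 = p_t34, p_ncat = p_ncat,
    p_metastasis = p_metastasis, p_diffuse = p_diffuse,
    p_embolus = p_embolus,
    tumor_size_meanlog = tumor_size_meanlog,
    tumor_size_sdlog = tumor_size_sdlog,
    hazards = hazards, adjust_hazards = adjust_hazards,
    hr10 = hr10, hr01 = hr01, hr11 = hr11,
    baseline_rate = baseline_rate, dropout_rate = dropout_rate,
    horizon_months = horizon_months,
    blood = blood
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  check_scalar(cfg$n_subjects, "n_subjects", lower = 0)
  if (cfg$n_subjects != floor(cfg$n_subjects))
    stopf("'n_subjects' must be a whole number")
  check_scalar(cfg$seed, "seed")
  for (p in c("p_male", "p_drinking", "p_family_history", "p_obesity",
              "p_hyperglycemia", "p_hypertension", "p_dyslipidemia",
              "p_tnm34", "p_t34", "p_metastasis", "p_diffuse",
              "p_embolus"))
    check_scalar(cfg[[p]], p, lower = 0, upper = 1)
  if (length(cfg$p_ncat) != 4L || any(cfg$p_ncat < 0) ||
      abs(sum(cfg$p_ncat) - 1) > 1e-8)
    stopf("'p_ncat' must be 4 non-negative probabilities summing to 1")
  for (p in c("hr10", "hr01", "hr11"))
    check_scalar(cfg[[p]], p, lower = .Machine$double.eps)
  # the four exposure-cell hazard multipliers must all be positive; with
  # the additive parameterization they are exactly (1, hr10, hr01, hr11)
  m <- c(1, cfg$hr10, cfg$hr01, cfg$hr11)
  if (any(m <= 0))
    stopf("joint-exposure hazard multiplier is non-positive for some cell")
  check_scalar(cfg$baseline_rate, "baseline_rate",
               lower = .Machine$double.eps)
  check_scalar(cfg$dropout_rate, "dropout_rate", lower = 0)
  check_scalar(cfg$horizon_months, "horizon_months",
               lower = .Machine$double.eps)
  check_scalar(cfg$age_sd, "age_sd", lower = 0)
  check_scalar(cfg$bmi_sd, "bmi_sd", lower = 0)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  n_subjects: %d   seed: %d\n",
              as.integer(x$n_subjects), as.integer(x$seed)))
  cat(sprintf("  exposure multipliers: hr10 = %.3g, hr01 = %.3g, hr11 = %.3g\n",
              x$hr10, x$hr01, x$hr11))
  ti <- true_interaction(x)
  cat(sprintf("  implied truth: RERI = %.3g, AP = %.3g, SI = %s\n",
              ti$reri, ti$ap,
              if (is.na(ti$si)) "undefined" else sprintf("%.3g", ti$si)))
  cat(sprintf("  baseline rate: %.4g/month, dropout: %.4g/month, horizon: %.1f months\n",
              x$baseline_rate, x$dropout_rate, x$horizon_months))
  invisible(x)
}

#' Read a simulation configuration from a flat key = value file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and lines
#' starting with `#` are ignored.  Values are parsed as numbers when
#' possible; `p_ncat` may be given as four comma-separated numbers.
#' Unknown keys are an error so typos do not silently fall back to
#' defaults.  Keys for the nested `hazards` / `adjust_hazards` / `blood`
#' lists use a dotted form, e.g. `hazards.tnm34 = 1.1`.
#'
#' @param path file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  kv <- read_keyvalue(path)
  args <- list()
  nested <- list()
  for (key in names(kv)) {
    val <- kv[[key]]
    if (grepl("^(hazards|adjust_hazards|blood)\\.", key)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      nested[[parts[1]]][[parts[2]]] <- val
    } else {
      args[[key]] <- val
    }
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stopf("unknown simulation config key(s): %s",
          paste(unknown, collapse = ", "))
  cfg <- do.call(sim_config, args)
  for (blk in names(nested)) {
    bad <- setdiff(names(nested[[blk]]), names(cfg[[blk]]))
    if (length(bad))
      stopf("unknown %s key(s): %s", blk, paste(bad, collapse = ", "))
    cfg[[blk]][names(nested[[blk]])] <- nested[[blk]]
  }
  validate_sim_config(cfg)
  cfg
}

# Parse a flat key-value text file into a named list of numerics / strings.
#' @noRd
read_keyvalue <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3L) stopf("cannot parse config line: '%s'", ln)
    key <- trimws(m[2])
    val <- trimws(m[3])
    if (grepl(",", val)) {
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      out[[key]] <- if (anyNA(num)) val else num
    } else {
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (is.na(num)) val else num
    }
  }
  out
}
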
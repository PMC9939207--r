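# Configuration-driven orchestration: simulate/load -> derive -> match ->
# interaction -> score -> validate, with file outputs shaped like the
# analysis tables of a cohort report.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline.  Either `input_csv` (a cohort
#' CSV following [cohort_schema()]) or `simulate` (a [sim_config()]) must
#' be supplied.
#'
#' @param input_csv path to a cohort CSV, or `NULL` to simulate.
#' @param simulate a [sim_config()] used when `input_csv` is `NULL`.
#' @param adjust adjustment covariates for all Cox models.
#' @param caliper matching caliper in SD-of-logit units (`NULL` = none).
#' @param match_seed seed for the matching order.
#' @param score_cohort `"matched"` (default) or `"full"`: which cohort the
#'   score table is built on.
#' @param categorical_factors,continuous_factors score factors; continuous
#'   ones get survival-tree cut points.
#' @param horizon score horizon t* in months.
#' @param max_leaves,min_leaf,alpha survival-tree parameters.
#' @param quantile_probs probabilities for score-group boundaries.
#' @param cv_folds,cv_seed,boot_reps validation settings.
#' @param out_dir output directory.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(input_csv = NULL,
                            simulate = sim_config(),
                            adjust = c("age", "sex", "drinking", "bmi",
                                       "family_history"),
                            caliper = 0.2,
                            match_seed = 1L,
                            score_cohort = c("matched", "full"),
                            categorical_factors = c(
                              "tnm_stage", "invasion_depth", "n_category",
                              "distant_metastasis", "lauren", "embolus",
                              "metsyn"),
                            continuous_factors = c(
                              "tumor_size", "positive_nodes", "wbc",
                              "hemoglobin", "nlr", "plr"),
                            horizon = 173,
                            max_leaves = 3, min_leaf = 20, alpha = 0.05,
                            quantile_probs = c(0.25, 0.75),
                            cv_folds = 10, cv_seed = 1L,
                            boot_reps = 2000,
                            out_dir = "survsynergy_out") {
  score_cohort <- match.arg(score_cohort)
  cfg <- list(input_csv = input_csv, simulate = simulate,
              adjust = adjust, caliper = caliper,
              match_seed = as.integer(match_seed),
              score_cohort = score_cohort,
              categorical_factors = categorical_factors,
              continuous_factors = continuous_factors,
              horizon = horizon, max_leaves = max_leaves,
              min_leaf = min_leaf, alpha = alpha,
              quantile_probs = quantile_probs,
              cv_folds = as.integer(cv_folds),
              cv_seed = as.integer(cv_seed),
              boot_reps = as.integer(boot_reps),
              out_dir = out_dir)
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from a flat key = value file
#'
#' Keys match the arguments of [analysis_config()]; list-valued settings
#' are comma-separated; simulation parameters use the `sim.` prefix (e.g.
#' `sim.n_subjects = 5000`).
#'
#' @param path file path.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  kv <- read_keyvalue(path)
  sim_keys <- grep("^sim\\.", names(kv), value = TRUE)
  sim_args <- kv[sim_keys]
  names(sim_args) <- sub("^sim\\.", "", names(sim_args))
  kv[sim_keys] <- NULL
  known <- setdiff(names(formals(analysis_config)), "simulate")
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stopf("unknown analysis config key(s): %s",
          paste(unknown, collapse = ", "))
  for (k in c("adjust", "categorical_factors", "continuous_factors"))
    if (!is.null(kv[[k]]) && is.character(kv[[k]]))
      kv[[k]] <- trimws(strsplit(kv[[k]], ",")[[1]])
  kv$simulate <- do.call(sim_config, sim_args)
  do.call(analysis_config, kv)
}

# One-line config echo used for the run log and the config hash.
# out_dir is excluded: it is a file location, not an analysis parameter,
# and including it would break byte-reproducibility across destinations.
#' @noRd
config_echo <- function(config) {
  flat <- unlist(config[setdiff(names(config), c("simulate", "out_dir"))])
  sim <- unlist(lapply(unclass(config$simulate), function(x)
    paste(format(x, digits = 10), collapse = ",")))
  c(paste0(names(flat), " = ", flat),
    paste0("sim.", names(sim), " = ", sim))
}

#' Run the full analysis pipeline
#'
#' Executes derive -> match -> stratified + joint interaction analysis ->
#' score construction -> validation and writes the report bundle to
#' `config$out_dir`:
#' \itemize{
#'   \item `matched_pairs.csv`, `balance.tsv`
#'   \item `interaction.json` (joint-exposure cells + RERI/AP/SI)
#'   \item `score_table.tsv`, `scored_cohort.csv`
#'   \item `validation.json` (per-unit/group HRs, Hosmer-Lemeshow,
#'     cross-validated AUROC)
#'   \item `run.log` (package version, seeds, config echo and hash)
#' }
#' Every file is reproducible byte-for-byte for a fixed configuration.
#'
#' @param config an [analysis_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(nm) file.path(config$out_dir, nm)

  # --- input --------------------------------------------------------------
  cohort <- stage("input", {
    if (!is.null(config$input_csv)) read_cohort(config$input_csv)
    else generate_cohort(config$simulate)
  })
  say("cohort: %d subjects, %d events", nrow(cohort), sum(cohort$event))

  # --- derive -------------------------------------------------------------
  cohort <- stage("derive", derive_clinical(cohort))

  # --- match --------------------------------------------------------------
  ps_covs <- intersect(config$adjust, names(cohort))
  model <- stage("match", fit_propensity(cohort, ps_covs))
  pairs <- stage("match", match_nearest(model, cohort,
                                        caliper = config$caliper,
                                        seed = config$match_seed))
  balance <- stage("match", balance_smd(cohort, pairs, ps_covs))
  matched <- matched_cohort(cohort, pairs)
  say("matched: %d pairs", nrow(pairs$pairs))
  write.csv(pairs$pairs, outfile("matched_pairs.csv"), row.names = FALSE)
  write.table(balance, outfile("balance.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  # --- interaction --------------------------------------------------------
  strat <- stage("interaction",
                 stratum_hrs(matched, "metsyn", "smoking",
                             adjust = config$adjust))
  joint <- stage("interaction",
                 joint_hrs(matched, "smoking", "metsyn",
                           adjust = config$adjust))
  measures <- stage("interaction", additive_measures(joint))
  write_interaction_json(joint, measures, outfile("interaction.json"))
  say("RERI = %.2f (%.2f to %.2f)", measures$reri[1], measures$reri[2],
      measures$reri[3])

  # --- score --------------------------------------------------------------
  score_coh <- if (config$score_cohort == "matched") matched else cohort
  specs <- stage("score", lapply(config$continuous_factors, function(v)
    tree_cutoffs(score_coh$time_months, score_coh$event, score_coh[[v]],
                 max_leaves = config$max_leaves,
                 min_leaf = config$min_leaf, alpha = config$alpha,
                 variable = v)))
  for (sp in specs) score_coh <- categorize(score_coh, sp)
  factors <- c(config$categorical_factors,
               paste0(config$continuous_factors, "_cat"))
  table <- stage("score", build_score_table(score_coh, factors,
                                            horizon = config$horizon))
  total <- stage("score", total_score(score_coh, table))
  hrres <- stage("score", score_mortality_hr(score_coh, total,
                                             adjust = config$adjust,
                                             probs = config$quantile_probs))
  score_coh$total_score <- total
  score_coh$score_group <- hrres$group
  write.table(as.data.frame(table), outfile("score_table.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(score_coh, outfile("scored_cohort.csv"), row.names = FALSE)
  say("total score range: %d-%d; per-unit HR = %.3f",
      min(total), max(total), hrres$per_unit$hr)

  # --- validate -----------------------------------------------------------
  recal <- stage("validate",
                 glm(score_coh$event ~ total, family = binomial()))
  hl <- stage("validate",
              hosmer_lemeshow(score_coh$event, fitted(recal)))
  builder <- score_builder(config$categorical_factors,
                           config$continuous_factors,
                           horizon = config$horizon,
                           max_leaves = config$max_leaves,
                           min_leaf = config$min_leaf,
                           alpha = config$alpha)
  base_coh <- if (config$score_cohort == "matched") matched else cohort
  cv <- stage("validate",
              cv_auroc(base_coh, builder, k = config$cv_folds,
                       seed = config$cv_seed,
                       boot_reps = config$boot_reps))
  validation <- list(
    per_unit_hr = hrres$per_unit,
    group_hrs = hrres$groups,
    group_boundaries = hrres$boundaries,
    hosmer_lemeshow = hl[c("chisq", "df", "p")],
    cv_auroc = list(estimate = cv$auroc, ci = cv$ci,
                    per_fold = cv$per_fold, k = cv$k, seed = cv$seed)
  )
  jsonlite::write_json(validation, outfile("validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("HL p = %.3f; CV AUROC = %.3f (%.3f-%.3f)", hl$p, cv$auroc,
      cv$ci[1], cv$ci[2])

  # --- run log ------------------------------------------------------------
  echo <- config_echo(config)
  log_lines <- c(
    sprintf("survsynergy %s (R %s.%s)", as.character(packageVersion("survsynergy")),
            R.version$major, R.version$minor),
    sprintf("config hash: %s", fnv1a32(echo)),
    sprintf("seeds: simulate = %s, match = %d, cv = %d",
            if (is.null(config$input_csv))
              as.integer(config$simulate$seed) else "n/a (file input)",
            config$match_seed, config$cv_seed),
    "--- config ---", echo)
  writeLines(log_lines, outfile("run.log"))

  invisible(list(cohort = cohort, model = model, pairs = pairs,
                 balance = balance, stratified = strat, joint = joint,
                 measures = measures, cutoffs = specs,
                 score_table = table, total = total, score_hr = hrres,
                 hosmer_lemeshow = hl, cv = cv, config = config))
}
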
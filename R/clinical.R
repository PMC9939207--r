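# Metabolic-syndrome classification (Chinese Diabetes Society, 2004) and
# derived blood-count ratio indexes.

#' Classify metabolic syndrome (CDS 2004 criteria)
#'
#' A subject has metabolic syndrome when at least three of the four
#' components hold:
#' \itemize{
#'   \item obesity: BMI >= 25 kg/m^2;
#'   \item hyperglycemia: fasting glucose >= 6.1 mmol/L, or 2-h plasma
#'     glucose >= 7.8 mmol/L, or previously diagnosed diabetes;
#'   \item hypertension: SBP/DBP >= 140/90 mm Hg, or antihypertensive
#'     therapy;
#'   \item dyslipidemia: triglycerides >= 1.7 mmol/L, or HDL cholesterol
#'     < 0.9 mmol/L (males) / < 1.0 mmol/L (females).
#' }
#' Boundary handling follows the criteria as written: `>=` everywhere
#' except the strict `<` for HDL cholesterol.  A missing 2-h glucose is a
#' non-qualifying disjunct (the other two routes can still qualify), not a
#' missing-data error; any other missing required measurement is an error
#' naming the field and the offending row.
#'
#' @param profile data.frame with columns `bmi`, `fbg`, `glucose_2h`
#'   (optional column), `diabetes_dx`, `sbp`, `dbp`, `antihypertensive`,
#'   `triglycerides`, `hdlc`, `sex` (`"male"`/`"female"`).  One row per
#'   subject.
#' @return data.frame with logical-as-integer columns `obesity`,
#'   `hyperglycemia`, `hypertension`, `dyslipidemia`, `n_components`,
#'   `metsyn`.
#' @export
#' @examples
#' classify_metabolic(data.frame(
#'   bmi = 25, fbg = 6.1, glucose_2h = NA, diabetes_dx = 0,
#'   sbp = 140, dbp = 80, antihypertensive = 0,
#'   triglycerides = 1.0, hdlc = 1.5, sex = "male"))
classify_metabolic <- function(profile) {
  required <- c("bmi", "fbg", "diabetes_dx", "sbp", "dbp",
                "antihypertensive", "triglycerides", "hdlc", "sex")
  check_columns(profile, required, where = "metabolic profile")
  if (!"glucose_2h" %in% names(profile))
    profile$glucose_2h <- NA_real_
  for (fld in required) {
    bad <- is.na(profile[[fld]])
    if (any(bad))
      stopf("missing measurement '%s' for row(s) %s", fld,
            paste(head(which(bad), 5), collapse = ", "))
  }
  if (!all(profile$sex %in% c("male", "female")))
    stopf("'sex' must be 'male' or 'female'")
  neg <- c("bmi", "fbg", "sbp", "dbp", "triglycerides", "hdlc")
  for (fld in neg)
    if (any(profile[[fld]] < 0))
      stopf("negative measurement in '%s'", fld)

  obesity <- profile$bmi >= 25
  g2h <- profile$glucose_2h
  hyperglycemia <- profile$fbg >= 6.1 |
    (!is.na(g2h) & g2h >= 7.8) |
    profile$diabetes_dx == 1
  hypertension <- profile$sbp >= 140 | profile$dbp >= 90 |
    profile$antihypertensive == 1
  hdlc_cut <- ifelse(profile$sex == "male", 0.9, 1.0)
  dyslipidemia <- profile$triglycerides >= 1.7 | profile$hdlc < hdlc_cut

  n_components <- as.integer(obesity) + as.integer(hyperglycemia) +
    as.integer(hypertension) + as.integer(dyslipidemia)
  data.frame(
    obesity = as.integer(obesity),
    hyperglycemia = as.integer(hyperglycemia),
    hypertension = as.integer(hypertension),
    dyslipidemia = as.integer(dyslipidemia),
    n_components = n_components,
    metsyn = as.integer(n_components >= 3L)
  )
}

#' Blood-count ratio indexes
#'
#' NLR = neutrophil/lymphocyte, PLR = platelet/lymphocyte,
#' LMR = lymphocyte/monocyte, MRR = monocyte/RBC.  A zero denominator
#' makes only the affected ratio undefined (`NA` with a warning); the
#' others are still returned.
#'
#' @param neutrophil,lymphocyte,monocyte,platelet,rbc non-negative
#'   concentrations (10^9/L; RBC 10^12/L), vectorized.
#' @return data.frame with columns `nlr`, `plr`, `lmr`, `mrr`.
#' @export
#' @examples
#' derive_ratios(4, 2, 0.4, 300, 4.5)
derive_ratios <- function(neutrophil, lymphocyte, monocyte, platelet, rbc) {
  args <- list(neutrophil = neutrophil, lymphocyte = lymphocyte,
               monocyte = monocyte, platelet = platelet, rbc = rbc)
  for (nm in names(args))
    if (any(args[[nm]] < 0, na.rm = TRUE))
      stopf("negative count in '%s'", nm)
  ratio <- function(num, den, name) {
    out <- num / den
    undef <- !is.na(den) & den == 0
    if (any(undef)) {
      warnf("%s undefined for %d subject(s): zero denominator",
            name, sum(undef))
      out[undef] <- NA_real_
    }
    out
  }
  data.frame(
    nlr = ratio(neutrophil, lymphocyte, "NLR"),
    plr = ratio(platelet, lymphocyte, "PLR"),
    lmr = ratio(lymphocyte, monocyte, "LMR"),
    mrr = ratio(monocyte, rbc, "MRR")
  )
}

#' Add derived clinical columns to a cohort
#'
#' Convenience wrapper: appends the metabolic component flags, component
#' count, metabolic-syndrome flag ([classify_metabolic()]) and the four
#' blood ratios ([derive_ratios()]) to the cohort table.
#'
#' @param cohort a cohort data.frame (see [cohort_schema()]).
#' @param missing_policy how to treat subjects with missing required
#'   metabolic measurements: `"error"` (default, complete-case enforced
#'   upstream) or `"drop"` to remove them with a message.
#' @return the cohort with columns `obesity`, `hyperglycemia`,
#'   `hypertension`, `dyslipidemia`, `n_components`, `metsyn`, `nlr`,
#'   `plr`, `lmr`, `mrr` appended.
#' @export
derive_clinical <- function(cohort, missing_policy = c("error", "drop")) {
  missing_policy <- match.arg(missing_policy)
  required <- c("bmi", "fbg", "diabetes_dx", "sbp", "dbp",
                "antihypertensive", "triglycerides", "hdlc", "sex")
  check_columns(cohort, c(required, "neutrophil", "lymphocyte",
                          "monocyte", "platelet", "rbc"))
  if (missing_policy == "drop") {
    ok <- complete.cases(cohort[, required])
    if (!all(ok)) {
      message(sprintf("dropping %d subject(s) with missing metabolic data",
                      sum(!ok)))
      cohort <- cohort[ok, , drop = FALSE]
    }
  }
  ms <- classify_metabolic(cohort)
  rt <- derive_ratios(cohort$neutrophil, cohort$lymphocyte,
                      cohort$monocyte, cohort$platelet, cohort$rbc)
  cbind(cohort, ms, rt)
}
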
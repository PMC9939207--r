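# survsynergy

Additive smoking × metabolic-syndrome interaction and survival-rate risk
scoring for surgical cancer cohorts.

## What it is for

Epidemiologists studying postsurgical cancer mortality often need to ask
whether two presurgical exposures — here ever-smoking and metabolic
syndrome — act **super-additively** on the cancer-specific hazard, and to
condense a panel of prognostic factors into a simple integer risk score a
clinician can sum by hand. `survsynergy` is a tested, reproducible R
implementation of that full analysis:

1. **Synthetic cohorts** (`sim_config()`, `generate_cohort()`): surgical
   cohorts with proportional-hazards survival, administrative + random
   censoring, confounded smoking assignment, and a configurable *additive*
   interaction — the joint hazard multiplier is
   `m(s,g) = 1 + (hr10−1)s + (hr01−1)g + RERI·sg`, so the true RERI is a
   simulation parameter.
2. **Clinical derivation** (`derive_clinical()`): metabolic syndrome by
   the 2004 Chinese Diabetes Society rule (≥3 of obesity, hyperglycemia,
   hypertension, dyslipidemia) and the blood-count ratios NLR, PLR, LMR,
   MRR.
3. **Propensity matching** (`fit_propensity()`, `match_nearest()`,
   `balance_smd()`): logistic propensity for smoking, greedy 1:1
   nearest-neighbor matching on the logit with a 0.2-SD caliper, and
   standardized-mean-difference balance diagnostics.
4. **Survival engine** (`km_estimate()`, `logrank()`, `fit_cox()`,
   `schoenfeld_test()`): Kaplan–Meier, log-rank, Cox (Efron ties) and a
   Schoenfeld-residual proportional-hazards test.
5. **Additive interaction** (`joint_hrs()`, `additive_measures()`,
   `z_interaction()`): from the four exposure-cell hazard ratios,

   ```
   RERI = HR11 − HR10 − HR01 + 1
   AP   = RERI / HR11
   SI   = (HR11 − 1) / ((HR10 − 1) + (HR01 − 1))
   ```

   with delta-method 95% CIs (SI on the log scale; bootstrap optional).
6. **Risk score** (`tree_cutoffs()`, `build_score_table()`,
   `total_score()`, `group_by_quantiles()`, `score_mortality_hr()`):
   log-rank survival-tree cut points for continuous factors, a
   per-category integer score = KM survival % at 173 months ÷ 10
   (half-up), per-subject totals, and <25% / 25–75% / ≥75% quantile
   groups.
7. **Validation** (`hosmer_lemeshow()`, `auroc()`, `cv_auroc()`):
   Hosmer–Lemeshow calibration of a logistic recalibration of the total
   score, and 10-fold cross-validated AUROC in which the *entire* score
   construction is re-run per fold.

See `vignettes/methods.Rmd` for the models, assumptions, and the design
decisions (non-collapsibility of adjusted hazard ratios, maximally
selected log-rank inflation in the tree, tie and rounding conventions).

## Worked example

```r
library(survsynergy)

cfg <- analysis_config(
  simulate = sim_config(n_subjects = 5000, seed = 42),
  continuous_factors = c("tumor_size", "wbc", "hemoglobin", "nlr"),
  cv_folds = 5, boot_reps = 200, out_dir = "demo_out")
res <- run_pipeline(cfg)
```

prints (numbers from this exact run):

```
cohort: 5000 subjects, 2309 events
matched: 849 pairs
RERI = 0.58 (-0.52 to 1.69)
total score range: 31-49; per-unit HR = 0.726
HL p = 0.978; CV AUROC = 0.719 (0.698-0.744)
```

Reading it: 5,000 synthetic subjects (46% cancer-specific deaths); 849
never-smokers matched 1:1 to smokers within the caliper; on the matched
cohort the baseline-adjusted additive interaction is RERI 0.58 (its CI
covers the attenuated truth — the report adjusts for the five baseline
covariates only, so cell HRs are non-collapsed; see the vignette); each
one-point increase of the total score carries a 27% lower mortality
hazard; the Hosmer–Lemeshow p of 0.98 shows no calibration failure, and
the cross-validated AUROC of 0.72 measures out-of-fold discrimination of
the re-built score. The first score-table rows:

```
          factor category    n survival_percent score
1      tnm_stage     I/II  489         59.48022     6
2      tnm_stage   III/IV 1209         28.07216     3
3 invasion_depth    T1/T2  336         45.81743     5
4 invasion_depth    T3/T4 1362         34.97013     3
```

The bundle under `demo_out/` holds the matched pairs, balance table,
interaction JSON, score table, scored cohort, validation JSON and a run
log with seeds and a config hash; reruns are byte-identical.

A command-line front end with `simulate / derive / match / interact /
score / validate / run-all` subcommands ships as
`inst/cli/survsynergy.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/survsynergy.R", package = "survsynergy"))')" \
  run-all --config analysis.txt --out out_dir
```

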
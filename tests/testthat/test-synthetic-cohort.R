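# Generator contracts: schema, reproducibility, censoring logic, the
# additive-interaction truth identities, and calibration of the stated
# cohort conditions.

test_that("n_subjects = 0 yields an empty table with the full schema", {
  coh <- generate_cohort(sim_config(n_subjects = 0, seed = 1))
  expect_identical(nrow(coh), 0L)
  expect_identical(names(coh), cohort_schema()$column)
  expect_identical(vapply(coh, function(x) class(x)[1], character(1)),
                   setNames(cohort_schema()$type, cohort_schema()$column))
})

test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- sim_config(n_subjects = 500, seed = 20240915)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # and the seed argument overrides the config seed
  expect_identical(generate_cohort(cfg, seed = 7),
                   generate_cohort(sim_config(n_subjects = 500, seed = 7)))
})

test_that("schema invariants hold on a generated cohort", {
  coh <- generate_cohort(sim_config(n_subjects = 2000, seed = 3))
  expect_true(all(coh$time_months > 0))
  expect_true(all(coh$event %in% 0:1))
  expect_true(all(coh$time_months <= 183.3))
  expect_true(all(coh$sex %in% c("male", "female")))
  expect_true(all(coh$tnm_stage %in% c("I/II", "III/IV")))
  expect_true(all(coh$n_category %in% paste0("N", 0:3)))
  expect_true(all(coh$lauren %in% c("intestinal", "diffuse")))
  num <- vapply(coh, is.numeric, logical(1))
  num_ok <- vapply(coh[num], function(x) all(is.na(x) | x >= 0),
                   logical(1))
  expect_true(all(num_ok[setdiff(names(num_ok), "age")]))
})

test_that("event flag follows min(failure, dropout, horizon)", {
  # without dropout, every censored subject must sit exactly at the horizon
  cfg <- sim_config(n_subjects = 800, seed = 5, dropout_rate = 0,
                    horizon_months = 60)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$time_months[coh$event == 0] == 60))
  expect_true(all(coh$time_months[coh$event == 1] <= 60))
})

test_that("defaults reproduce the stated cohort conditions", {
  coh <- generate_cohort(sim_config(n_subjects = 20000, seed = 11))
  # ~44% cancer-specific deaths, median follow-up ~44 months, heavy
  # censoring with maximum at the administrative horizon
  expect_gt(mean(coh$event), 0.38)
  expect_lt(mean(coh$event), 0.52)
  expect_gt(median(coh$time_months), 36)
  expect_lt(median(coh$time_months), 52)
  coh <- derive_clinical(coh)
  expect_gt(mean(coh$metsyn), 0.02)
  expect_lt(mean(coh$metsyn), 0.10)
  expect_gt(mean(coh$smoking), 0.7)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(hr10 = 0), "hr10")
  expect_error(sim_config(n_subjects = -1), "n_subjects")
  expect_error(sim_config(p_male = 1.2), "p_male")
  expect_error(sim_config(baseline_rate = 0), "baseline_rate")
  expect_error(sim_config(p_ncat = c(0.5, 0.5)), "p_ncat")
})

test_that("true_interaction identities", {
  # exact additivity
  ti <- true_interaction(sim_config(hr10 = 1.5, hr01 = 1.5, hr11 = 2.0))
  expect_equal(ti$reri, 0)
  expect_equal(ti$ap, 0)
  expect_equal(ti$si, 1)
  # published joint hazard ratios: identities give 2.42 / 0.593 / 4.67
  ti <- true_interaction(sim_config(hr10 = 1.07, hr01 = 1.59, hr11 = 4.08))
  expect_equal(ti$reri, 2.42)
  expect_equal(ti$ap, 2.42 / 4.08)
  expect_equal(ti$si, 3.08 / 0.66)
  # degenerate excess-risk denominator
  ti <- true_interaction(sim_config(hr10 = 1, hr01 = 1, hr11 = 3))
  expect_false(ti$si_defined)
  expect_true(is.na(ti$si))
})

test_that("classify_metabolic recovers the generating component flags", {
  coh <- generate_cohort(sim_config(n_subjects = 3000, seed = 13))
  truth <- attr(coh, "truth")
  got <- classify_metabolic(coh)
  expect_identical(got$obesity, truth$obesity)
  expect_identical(got$hyperglycemia, truth$hyperglycemia)
  expect_identical(got$hypertension, truth$hypertension)
  expect_identical(got$dyslipidemia, truth$dyslipidemia)
  expect_identical(got$metsyn, truth$metsyn)
})

test_that("unexposed-group KM converges to the configured baseline curve", {
  # zero out all covariate effects so the doubly unexposed hazard is
  # exactly the configured constant baseline rate
  hz0 <- lapply(sim_config()$hazards, function(x) 0)
  ah0 <- lapply(sim_config()$adjust_hazards, function(x) 0)
  cfg <- sim_config(n_subjects = 50000, seed = 21, hazards = hz0,
                    adjust_hazards = ah0)
  coh <- generate_cohort(cfg)
  truth <- attr(coh, "truth")
  un <- coh$smoking == 0 & truth$metsyn == 0
  km <- km_estimate(coh$time_months[un], coh$event[un])
  grid <- seq(5, 150, by = 5)
  emp <- vapply(grid, function(t) survival_at(km, t) / 100, numeric(1))
  expect_lt(max(abs(emp - exp(-cfg$baseline_rate * grid))), 0.02)
})

test_that("null world: log-rank on smoking rejects at ~5%", {
  # all hazard effects off: smoking is confounded with covariates, but
  # none of them touch the hazard, so the marginal log-rank null holds
  hz0 <- lapply(sim_config()$hazards, function(x) 0)
  ah0 <- lapply(sim_config()$adjust_hazards, function(x) 0)
  reps <- 400
  rej <- 0
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_subjects = 2000, seed = 31000 + r, hazards = hz0,
                      adjust_hazards = ah0, hr10 = 1, hr01 = 1, hr11 = 1)
    coh <- generate_cohort(cfg)
    s <- coh$smoking == 1
    lr <- logrank(coh$time_months[s], coh$event[s],
                  coh$time_months[!s], coh$event[!s])
    rej <- rej + (lr$p < 0.05)
  }
  # 400 replicates: binomial 99.9% band around 0.05 is ~[0.02, 0.09]
  expect_gt(rej / reps, 0.02)
  expect_lt(rej / reps, 0.09)
})

test_that("cohort CSV round-trips and read_cohort validates the schema", {
  coh <- generate_cohort(sim_config(n_subjects = 50, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$time_months, coh$time_months, tolerance = 1e-12)
  expect_identical(back$n_category, coh$n_category)
  # schema violation: drop the event column
  broken <- coh[, setdiff(names(coh), "event")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, path2, row.names = FALSE)
  expect_error(read_cohort(path2), "event")
})

test_that("shipped schema file matches the in-code dictionary", {
  path <- system.file("extdata", "cohort_schema.tsv",
                      package = "survsynergy")
  shipped <- read.delim(path, stringsAsFactors = FALSE)
  expect_identical(shipped, cohort_schema())
})
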
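# KM / log-rank / Cox engine, checked against hand calculations,
# brute-force partial-likelihood maximization, and survdiff.

test_that("KM product-limit matches the hand calculation", {
  km <- km_estimate(c(2, 4, 6), c(1, 1, 1))
  expect_equal(km$time, c(2, 4, 6))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(survival_at(km, 3), 100 * 2 / 3)
  expect_equal(survival_at(km, 1.99), 100)
  expect_equal(survival_at(km, 1e6), 0)
})

test_that("KM handles censoring and the all-censored case", {
  km <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_length(km$time, 0)
  expect_equal(survival_at(km, 50), 100)
  # censored at an event time stays in that risk set (deaths first)
  km2 <- km_estimate(c(2, 2, 5), c(1, 0, 1))
  expect_equal(km2$surv, c(2 / 3, 0))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(survival_at(km2, -1), "t")
})

test_that("KM with no censoring equals the empirical survivor function", {
  set.seed(12)
  tm <- round(rexp(300, 0.05), 1) + 0.1
  km <- km_estimate(tm, rep(1, 300))
  for (t in quantile(tm, c(0.1, 0.5, 0.9)))
    expect_equal(survival_at(km, t), 100 * mean(tm > t))
  expect_true(all(diff(km$surv) <= 0))
})

test_that("log-rank agrees with survdiff and is symmetric", {
  set.seed(19)
  for (r in 1:15) {
    a <- make_surv(60, hr = sample(c(1, 2), 1))
    b <- make_surv(50)
    lr <- logrank(a$time, a$event, b$time, b$event)
    sd_fit <- survival::survdiff(
      survival::Surv(time, event) ~ g,
      data = data.frame(time = c(a$time, b$time),
                        event = c(a$event, b$event),
                        g = rep(0:1, c(nrow(a), nrow(b)))))
    expect_equal(lr$chisq, sd_fit$chisq, tolerance = 1e-8)
  }
  a <- make_surv(40, seed = 5)
  same <- logrank(a$time, a$event, a$time, a$event)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  expect_warning(lr0 <- logrank(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
                 "no events")
  expect_equal(lr0$p, 1)
})

test_that("log-rank toy matches the hand O-E / hypergeometric form", {
  # group A: times 1, 3 (deaths), 5, 7 censored; group B: 2, 4 deaths,
  # 6, 8 censored -- small enough to tabulate by hand
  ta <- c(1, 3, 5, 7); ea <- c(1, 1, 0, 0)
  tb <- c(2, 4, 6, 8); eb <- c(1, 1, 0, 0)
  # risk sets at death times 1,2,3,4: Y=8,7,6,5; Ya=4,3,3,2; one death each
  O <- 2
  E <- 4 / 8 + 3 / 7 + 3 / 6 + 2 / 5
  V <- sum(c(4 / 8 * (1 - 4 / 8), 3 / 7 * (1 - 3 / 7),
             3 / 6 * (1 - 3 / 6), 2 / 5 * (1 - 2 / 5)))
  lr <- logrank(ta, ea, tb, eb)
  expect_equal(lr$chisq, (O - E)^2 / V, tolerance = 1e-10)
})

test_that("Cox fit matches brute-force partial-likelihood maximization", {
  # n = 8 with ties, both tie corrections
  tm <- c(2, 2, 3, 5, 5, 7, 9, 11)
  ev <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x <- c(0, 1, 1, 0, 1, 0, 1, 0)
  for (ties in c("efron", "breslow")) {
    f <- fit_cox(tm, ev, data.frame(x = x), ties = ties)
    b_oracle <- oracle_cox_mle(tm, ev, x, ties = ties)
    expect_equal(unname(f$coefficients), b_oracle, tolerance = 1e-4)
    expect_equal(f$loglik, oracle_cox_loglik(f$coefficients, tm, ev, x,
                                             ties = ties),
                 tolerance = 1e-8)
    # partial likelihood at the estimate is no worse than at zero
    expect_gte(f$loglik, oracle_cox_loglik(0, tm, ev, x, ties = ties))
  }
})

test_that("Cox: symmetric groups give beta = 0; Efron = Breslow tie-free", {
  tm <- rep(c(3, 6, 9, 12), 2)
  ev <- rep(c(1, 1, 0, 1), 2)
  x <- rep(c(0, 1), each = 4)
  f <- fit_cox(tm, ev, data.frame(x = x))
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-7)
  set.seed(3)
  d <- make_surv(150, hr = 1.6)
  d$time <- d$time + runif(150, 0, 1e-4)   # break ties
  fe <- fit_cox(d$time, d$event, data.frame(g = d$group), ties = "efron")
  fb <- fit_cox(d$time, d$event, data.frame(g = d$group), ties = "breslow")
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-6)
})

test_that("Cox recovers a known rate ratio at large n", {
  d <- make_surv(10000, rate0 = 0.02, hr = 2, cens_rate = 0.01, seed = 99)
  f <- fit_cox(d$time, d$event, data.frame(g = d$group))
  expect_lt(abs(unname(f$coefficients) - log(2)), 0.05)
  expect_true(f$converged)
})

test_that("Cox rejects bad inputs and flags monotone likelihood", {
  d <- make_surv(50, seed = 1)
  expect_error(fit_cox(d$time, d$event, data.frame(k = rep(2, 50))),
               "constant")
  expect_error(fit_cox(d$time, rep(0, 50), data.frame(g = d$group)),
               "at least one event")
  # perfect risk separation: the covariate orders all event times first
  tm <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ev <- c(1, 1, 1, 1, 0, 0, 0, 0)
  xx <- c(1, 1, 1, 1, 0, 0, 0, 0)
  f <- fit_cox(tm, ev, data.frame(x = xx))
  expect_false(f$converged)
})

test_that("hr_ci closed forms and printed-CI round trip", {
  f <- structure(list(coefficients = c(x = 0), se = c(x = 0.1),
                      vcov = matrix(0.01, dimnames = list("x", "x")),
                      converged = TRUE),
                 class = "cox_fit")
  ci <- hr_ci(f, "x")
  expect_equal(ci[["hr"]], 1)
  expect_equal(ci[["lower"]], exp(-1.959964 * 0.1))
  expect_equal(ci[["upper"]], exp(1.959964 * 0.1))
  # reconstruct a printed interval from its implied SE
  se <- (log(2.96) - log(1.51)) / (2 * 1.959964)
  beta <- (log(2.96) + log(1.51)) / 2
  f2 <- structure(list(coefficients = c(x = beta), se = c(x = se)),
                  class = "cox_fit")
  ci2 <- hr_ci(f2, "x")
  expect_equal(round(ci2[["lower"]], 2), 1.51)
  expect_equal(round(ci2[["upper"]], 2), 2.96)
  expect_true(ci2[["lower"]] < ci2[["hr"]] && ci2[["hr"]] < ci2[["upper"]])
})

test_that("Schoenfeld test detects a reversing effect and not a null one", {
  gen_reversing <- function(n, b = log(2.5), flip = 50) {
    g <- rbinom(n, 1, 0.5)
    r1 <- 0.02 * exp(b * g)
    t1 <- rexp(n, r1)
    t2 <- flip + rexp(n, 0.02 * exp(-b * g))
    tm <- ifelse(t1 <= flip, t1, t2)
    data.frame(time = pmin(tm, 150),
               event = as.integer(tm <= 150), g = g)
  }
  set.seed(55)
  hits <- 0
  for (r in 1:20) {
    d <- gen_reversing(2000)
    f <- fit_cox(d$time, d$event, data.frame(g = d$g))
    hits <- hits + (schoenfeld_test(f)$p < 0.05)
  }
  expect_gt(hits / 20, 0.8)
  # specificity: proportional hazards, no time trend
  calm <- 0
  for (r in 1:100) {
    d <- make_surv(500, hr = 1.5)
    f <- fit_cox(d$time, d$event, data.frame(g = d$group))
    calm <- calm + (schoenfeld_test(f)$p > 0.05)
  }
  expect_gte(calm / 100, 0.86)
  d <- make_surv(30, seed = 2)
  d$event <- 0; d$event[1] <- 1
  f1 <- fit_cox(d$time, d$event, data.frame(g = d$group))
  expect_error(schoenfeld_test(f1), "2 events")
})
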
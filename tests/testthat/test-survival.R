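test_that("time_to_dr codes distant recurrence as the event and censors everything else", {
  df <- data.frame(followup_time = c(4.0, 2.5, 11.0, 6.0),
                   event_type = c("secondary_carcinoma", "distant_recurrence",
                                  "none", "death"))
  out <- time_to_dr(df)
  expect_equal(out$duration, df$followup_time)
  expect_equal(out$event, c(0L, 1L, 0L, 0L))
  expect_error(time_to_dr(data.frame(followup_time = 0, event_type = "none")),
               "positive")
  expect_error(time_to_dr(data.frame(followup_time = 1, event_type = "relapse")),
               "event_type")
})

test_that("Kaplan-Meier reproduces hand-computed product-limit tables", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$steps$surv, c(2/3, 1/3, 0))

  # all censored: no steps, curve identically 1
  km0 <- km_curve(c(2, 5, 9), c(0, 0, 0))
  expect_equal(nrow(km0$steps), 0)

  # mixed example with a tie and interleaved censoring:
  # times 2(ev) 3(cens) 4(ev,ev) 5(cens) 6(ev)
  km2 <- km_curve(c(2, 3, 4, 4, 5, 6), c(1, 0, 1, 1, 0, 1))
  expect_equal(km2$steps$time, c(2, 4, 6))
  expect_equal(km2$steps$n_risk, c(6L, 4L, 1L))
  expect_equal(km2$steps$surv, c(5/6, 5/6 * 2/4, 0))

  # right-continuous, non-increasing, starts below 1 only after first event
  expect_true(all(diff(km2$steps$surv) <= 0))
})

test_that("Kaplan-Meier ignores how far beyond the last event a censoring time lies", {
  t0 <- c(1, 2, 4, 7); e0 <- c(1, 0, 1, 0)   # last event at t = 4
  a <- km_curve(t0, e0)
  b <- km_curve(c(1, 2, 4, 15), e0)          # same subject censored later
  expect_equal(a$steps$surv, b$steps$surv)
  expect_equal(a$steps$time, b$steps$time)
  # whereas a censoring time moved before an event changes the risk set
  c_ <- km_curve(c(1, 3, 4, 7), e0)
  expect_equal(c_$steps$surv, a$steps$surv)  # still at risk at t=4 either way
})

test_that("Cox fit agrees with an independent implementation to 1e-6 (ties included)", {
  skip_if_not_installed("survival")
  set.seed(14)
  n <- 120
  x1 <- rbinom(n, 1, 0.4); x2 <- rnorm(n)
  t <- ceiling(rexp(n, 0.2 * exp(0.8 * x1 - 0.5 * x2)))  # integer times -> heavy ties
  cc <- sample(3:10, n, replace = TRUE)
  dur <- pmin(t, cc); ev <- as.integer(t <= cc)
  X <- cbind(x1 = x1, x2 = x2)
  for (ties in c("efron", "breslow")) {
    mine <- cox_fit(dur, ev, X, ties = ties)
    ref <- survival::coxph(survival::Surv(dur, ev) ~ x1 + x2, ties = ties)
    expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_equal(unname(mine$loglik["final"]), unname(ref$loglik[2]), tolerance = 1e-8)
  }
  # with no ties the two tie conventions coincide
  set.seed(15)
  t2 <- rexp(n, 0.2 * exp(0.6 * x1)); c2 <- runif(n, 1, 10)
  f_e <- cox_fit(pmin(t2, c2), as.integer(t2 <= c2), cbind(x1 = x1), ties = "efron")
  f_b <- cox_fit(pmin(t2, c2), as.integer(t2 <= c2), cbind(x1 = x1), ties = "breslow")
  expect_equal(coef(f_e), coef(f_b), tolerance = 1e-10)
})

test_that("Cox optimum has a ~zero score and null effects are recovered", {
  set.seed(16)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1)                       # log-HR = 0
  cc <- runif(n, 2, 15)
  f <- cox_fit(pmin(t, cc), as.integer(t <= cc), cbind(marker = x))
  expect_true(f$converged)
  expect_lt(f$gradient_norm, 1e-8)
  expect_true(f$lower[1] <= 1 && 1 <= f$upper[1])
  expect_lt(abs(coef(f)[1]), 0.3)
})

test_that("complete separation is reported as monotone likelihood, not a silent fit", {
  dur <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ev <- rep(1L, 8)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)          # all early events in one group
  f <- cox_fit(dur, ev, cbind(x = x))
  expect_true(f$monotone_likelihood)
  expect_false(f$converged)
  expect_error(cox_fit(dur, ev, cbind(x = rep(1, 8))), "constant covariate")
  expect_error(cox_fit(dur, rep(0L, 8), cbind(x = x)), "at least one event")
})

test_that("distant-recurrence model report covers univariable and both multivariable layouts", {
  coh <- generate_cohort(default_config(n_patients = 700), seed = 21)
  rep <- run_dr_models(coh)
  expect_gt(rep$n_complete, 400)
  expect_equal(rep$n_complete + rep$n_dropped, nrow(coh))
  expect_true(all(c("age", "pt_category", "nodal", "grade", "esr1", "pgr",
                    "erbb2", "mki67", "er_ref", "pr_ref", "her2_ref",
                    "ki67_ref", "ki67_ref_gt20") %in% names(rep$univariable)))
  expect_s3_class(rep$multivariable_calls, "strat4_cox")
  expect_s3_class(rep$multivariable_reference, "strat4_cox")
  # 3-level Ki67 expands to two contrasts against the low group
  expect_equal(sum(grepl("ki67_ref", names(coef(rep$multivariable_reference)))), 2)
  expect_true(all(rep$multivariable_calls$hr > 0))

  # zero events -> unfit report
  coh0 <- coh
  coh0$event_type <- "none"
  expect_true(run_dr_models(coh0)$unfit)

  # constant covariate is excluded with a diagnostic
  coh1 <- coh
  coh1$grade <- "G2"
  expect_message(rep1 <- run_dr_models(coh1), "constant covariate")
  expect_true("grade" %in% rep1$dropped_covariates)
})
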
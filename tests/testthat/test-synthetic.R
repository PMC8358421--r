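test_that("default configuration encodes the study margins", {
  cfg <- default_config()
  expect_equal(cfg$n_patients, 1115)
  expect_equal(cfg$control$invalid_frac, 0.035)
  # call-positive fractions conditional on a valid control
  expect_equal(cfg$markers$ESR1$call_pos_frac, 0.937 / 0.965, tolerance = 1e-12)
  expect_equal(cfg$markers$MKI67$call_pos_frac, 0.456 / 0.965, tolerance = 1e-12)
  # latent prevalences are solved so mixture tails hit the call fractions
  for (m in c("ESR1", "PGR", "ERBB2", "MKI67")) {
    mk <- cfg$markers[[m]]
    implied <- mk$prevalence * (1 - pnorm(mk$cutoff, mk$mu_pos, mk$sd)) +
      (1 - mk$prevalence) * (1 - pnorm(mk$cutoff, mk$mu_neg, mk$sd))
    expect_equal(implied, mk$call_pos_frac, tolerance = 1e-12)
  }
  # generating hazard ratios are the published univariable values
  expect_equal(unname(exp(cfg$hazard$log_hr[c("MKI67", "PGR", "ERBB2", "ESR1")])),
               c(2.35, 0.50, 2.92, 0.40))
  # corrupted configurations are rejected before generation
  bad <- default_config(n_patients = 50)
  bad$markers$ESR1$prevalence <- 1.2
  expect_error(generate_cohort(bad, seed = 1), "prevalence")
  bad2 <- default_config(n_patients = 50)
  bad2$markers$PGR$sd <- -1
  expect_error(generate_cohort(bad2, seed = 1), "SD")
  bad3 <- default_config(n_patients = 50)
  bad3$control$window_frac <- 2
  expect_error(generate_cohort(bad3, seed = 1), "probabilit")
})

test_that("cohort generation is seed-reproducible and schema-complete", {
  cfg <- default_config(n_patients = 200)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  c <- generate_cohort(cfg, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$ct_esr1, c$ct_esr1))
  need <- c("sample_id", "ct_cyfip1", "ct_esr1", "ct_pgr", "ct_erbb2",
            "ct_mki67", "er_percent", "pr_percent", "ki67_percent",
            "her2_ihc", "ish_ratio", "ish_copies", "age", "pt_category",
            "nodal", "grade", "arm", "followup_time", "event_type")
  expect_true(all(need %in% names(a)))
  expect_true(all(a$followup_time > 0))
})

test_that("zero reference misclassification yields perfect downstream agreement", {
  cfg <- default_config(n_patients = 400)
  for (m in c("ESR1", "PGR", "ERBB2")) {
    cfg$markers[[m]]$ref_pos_given <- c(call_pos = 1, call_neg = 0)
  }
  cfg$markers$MKI67$ref_int_given <- c(call_pos = 0, call_neg = 0)
  cfg$markers$MKI67$ref_high_given_nonint <- c(call_pos = 1, call_neg = 0)
  cfg$her2_render$missing_frac <- 0
  coh <- generate_cohort(cfg, seed = 12)
  fit <- concordance(classify_cohort(coh), classify_reference(coh))
  for (m in names(fit$markers)) {
    expect_equal(fit$markers[[m]]$kappa$kappa, 1,
                 info = paste("marker", m))
  }
})

test_that("generated call margins converge to the configured prevalences (LLN)", {
  cfg <- default_config(n_patients = 50000)
  coh <- generate_cohort(cfg, seed = 40)
  calls <- classify_cohort(coh)
  n <- nrow(coh)
  targets <- c(esr1 = 0.937, pgr = 0.758, erbb2 = 0.038, mki67 = 0.456)
  for (m in names(targets)) {
    p <- targets[[m]]
    got <- mean(calls[[paste0("status_", m)]] == "positive")
    expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n))
  }
  inv <- mean(calls$status_esr1 == "invalid")
  expect_lt(abs(inv - 0.035), 3 * sqrt(0.035 * 0.965 / n))
})

test_that("null marker hazard gives coinciding survival strata", {
  cfg <- default_config(n_patients = 20000)
  cfg$hazard$log_hr[c("ESR1", "PGR", "ERBB2", "MKI67")] <- 0
  coh <- generate_cohort(cfg, seed = 33)
  calls <- classify_cohort(coh)
  tt <- time_to_dr(coh)
  pos <- calls$status_mki67 == "positive"
  neg <- calls$status_mki67 == "negative"
  km_p <- km_curve(tt$duration[pos], tt$event[pos])
  km_n <- km_curve(tt$duration[neg], tt$event[neg])
  s_at <- function(km, t) {
    i <- sum(km$steps$time <= t)
    if (i == 0) 1 else km$steps$surv[i]
  }
  for (t in c(5, 8, 11))
    expect_lt(abs(s_at(km_p, t) - s_at(km_n, t)), 0.015)
})

test_that("2x2 fixture expansion round-trips exactly through the pipeline", {
  vc <- validation_counts()
  for (i in seq_len(nrow(vc))) {
    spec <- as.list(vc[i, ])
    rec <- expand_two_by_two_fixture(spec)
    expect_equal(nrow(rec), vc$a[i] + vc$b[i] + vc$c[i] + vc$d[i])
    t <- build_two_by_two(classify_cohort(rec), classify_reference(rec),
                          vc$marker[i])
    expect_equal(c(t$a, t$b, t$c, t$d),
                 c(vc$a[i], vc$b[i], vc$c[i], vc$d[i]))
    expect_equal(sum(t$exclusions), 0)
  }
  one <- expand_two_by_two_fixture(list(marker = "PGR", a = 0, b = 0, c = 0, d = 1))
  t1 <- build_two_by_two(classify_cohort(one), classify_reference(one), "PGR")
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(0, 0, 0, 1))
  expect_error(expand_two_by_two_fixture(list(marker = "PGR", a = -1, b = 0,
                                              c = 0, d = 0)), "non-negative")
})
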
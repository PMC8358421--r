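test_that("Wilson interval matches score-equation root-finding to 1e-10", {
  set.seed(31)
  ns <- sample(1:500, 60, replace = TRUE)
  ks <- vapply(ns, function(n) sample(0:n, 1), integer(1))
  for (i in seq_along(ns)) {
    got <- wilson_interval(ks[i], ns[i])
    want <- wilson_by_rootfinding(ks[i], ns[i])
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
  expect_equal(unname(wilson_interval(0, 25)[1]), 0)
  expect_equal(unname(wilson_interval(25, 25)[2]), 1)
  expect_error(wilson_interval(3, 0), "n must be")
})

test_that("published-precision checks: PR NPA interval and HER2 PPA lower limit", {
  ci <- 100 * wilson_interval(97, 120)
  expect_equal(round_half_up(ci, 1), c(lower = 72.9, upper = 86.9))
  expect_equal(round_half_up(100 * wilson_interval(41, 59)[["lower"]], 1), 56.9)
})

test_that("proportion_stats returns exact ratios and handles degenerate denominators", {
  t <- two_by_two(41, 1, 18, 1014)
  s <- proportion_stats(t)
  expect_equal(round_half_up(100 * s["PPA", "estimate"], 1), 69.5)
  expect_equal(round_half_up(100 * s["NPA", "estimate"], 1), 99.9)
  expect_equal(round_half_up(100 * s["OPA", "estimate"], 1), 98.2)

  s2 <- proportion_stats(two_by_two(158, 66, 9, 260))
  expect_equal(round_half_up(100 * s2["OPA", "estimate"], 1), 84.8)

  perf <- proportion_stats(two_by_two(7, 0, 0, 5))
  expect_equal(perf$estimate, rep(1, 3))

  nod <- proportion_stats(two_by_two(0, 3, 0, 4))   # no reference positives
  expect_true(is.na(nod["PPA", "estimate"]))
  expect_false(anyNA(nod[c("OPA", "NPA"), "estimate"]))
})

test_that("OPA decomposes exactly as the prevalence-weighted PPA/NPA mixture", {
  set.seed(17)
  for (i in 1:25) {
    x <- rmultinom(1, sample(20:500, 1), prob = runif(4, 0.05, 1))
    t <- two_by_two(x[1], x[2], x[3], x[4])
    s <- proportion_stats(t)
    if (anyNA(s$estimate)) next
    expect_equal(s["OPA", "estimate"],
                 s["PPA", "estimate"] * (t$a + t$c) / t$n +
                   s["NPA", "estimate"] * (t$b + t$d) / t$n)
  }
})

test_that("Cohen's kappa: closed-form cases, bounds and symmetry", {
  expect_equal(cohens_kappa(two_by_two(50, 50, 50, 50))$kappa, 0)
  expect_equal(cohens_kappa(two_by_two(7, 0, 0, 13))$kappa, 1)
  k <- cohens_kappa(two_by_two(1045, 0, 12, 19))
  expect_equal(round_half_up(k$kappa, 2), 0.75)
  expect_equal(round_half_up(c(k$lower, k$upper), 2), c(0.62, 0.89))
  # kappa <= po; transposition invariance (swap test/reference labels)
  set.seed(5)
  for (i in 1:20) {
    x <- rmultinom(1, sample(10:300, 1), prob = runif(4, 0.05, 1))
    t <- two_by_two(x[1], x[2], x[3], x[4])
    kk <- cohens_kappa(t)
    if (is.na(kk$kappa)) next
    expect_lte(kk$kappa, kk$po + 1e-12)
    kt <- cohens_kappa(two_by_two(x[1], x[3], x[2], x[4]))
    expect_equal(kk$kappa, kt$kappa)
  }
  # degenerate margins
  expect_true(is.na(cohens_kappa(two_by_two(5, 0, 0, 0))$kappa))
})

test_that("performance-target gates compare unrounded lower limits inclusively", {
  st <- list(
    ESR1 = proportion_stats(two_by_two(1045, 0, 12, 19)),
    ERBB2 = proportion_stats(two_by_two(41, 1, 18, 1014)))
  g <- evaluate_performance_targets(st)
  expect_true(all(g$met[g$marker == "ESR1"]))
  expect_false(g$met[g$marker == "ERBB2" & g$statistic == "PPA"])
  expect_true(g$met[g$marker == "ERBB2" & g$statistic == "NPA"])
  # boundary: lower limit exactly equal to the threshold counts as met
  fake <- st["ESR1"]
  fake$ESR1["PPA", "lower"] <- 0.80
  g2 <- evaluate_performance_targets(fake)
  expect_true(g2$met[g2$statistic == "PPA"])
})

test_that("build_two_by_two applies the exclusion rules and the accounting identity", {
  # all-invalid input: empty table, tallied
  coh <- random_panels(10, seed = 3)
  coh$ct_cyfip1 <- 37
  t <- build_two_by_two(classify_cohort(coh), classify_reference(coh), "ESR1")
  expect_equal(t$n, 0)
  expect_equal(t$exclusions[["invalid"]], 10)

  # MKi67: 2 indeterminate calls + 3 intermediate references among 10 -> n = 5
  coh <- data.frame(sample_id = 1:10,
                    ct_cyfip1 = c(rep(28, 8), 33, 33),
                    ct_esr1 = 26, ct_pgr = 26, ct_erbb2 = 26,
                    ct_mki67 = c(rep(26, 5), rep(35, 3), rep(38, 2)),
                    er_percent = 90, pr_percent = 90,
                    ki67_percent = c(90, 90, 10, 20, 10, 0, 0, 0, 0, 0),
                    her2_ihc = "3+", ish_ratio = NA_real_, ish_copies = NA_real_)
  t <- build_two_by_two(classify_cohort(coh), classify_reference(coh), "MKI67")
  expect_equal(t$exclusions[["indeterminate"]], 2)
  expect_equal(t$exclusions[["intermediate_ki67"]], 3)
  expect_equal(t$n, 5)

  # accounting identity on a generated cohort, every marker
  coh <- generate_cohort(default_config(n_patients = 600), seed = 9)
  calls <- classify_cohort(coh); ref <- classify_reference(coh)
  for (m in c("ESR1", "PGR", "ERBB2", "MKI67")) {
    t <- build_two_by_two(calls, ref, m)
    expect_equal(t$n + sum(t$exclusions), nrow(coh))
  }
})

test_that("chi-square matches first-principles expected counts and the arm comparison", {
  set.seed(23)
  for (i in 1:10) {
    m <- matrix(rpois(6, 30) + 1, 2, 3)
    got <- chi_square_rxc(m)
    expect_equal(got$statistic, chisq_by_hand(m), tolerance = 1e-12)
    expect_equal(got$df, 2)
  }
  arm <- matrix(c(590, 418, 525, 487), 2, 2)
  expect_equal(round_half_up(chi_square_rxc(arm)$p.value, 3), 0.003)
  same <- matrix(c(30, 60, 10, 20), 2, 2)   # identical group distributions
  got <- chi_square_rxc(same)
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_equal(got$p.value, 1)
  expect_warning(chi_square_rxc(rbind(c(5, 5, 0), c(3, 7, 0))), "zero-margin")
})

test_that("Fisher 2x2 equals full-margin enumeration for all tables with n <= 10", {
  for (n in 2:10) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    for (j in seq_len(nrow(parts))) {
      a <- parts$a[j]; b <- parts$b[j]; c <- parts$c[j]
      d <- n - a - b - c
      expect_equal(fisher_exact_2x2(matrix(c(a, c, b, d), 2, 2)),
                   fisher_by_enumeration(a, b, c, d), tolerance = 1e-9)
    }
  }
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2, 2)), 1)  # zero margin
  # transposition symmetry
  expect_equal(fisher_exact_2x2(matrix(c(1, 9, 9, 1), 2, 2)),
               fisher_exact_2x2(matrix(c(1, 9, 9, 1), 2, 2, byrow = TRUE)))
})

test_that("Wilcoxon rank-sum: exact small-sample path matches permutation enumeration", {
  set.seed(77)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, replace = TRUE)   # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$p.value, wilcoxon_by_enumeration(x, y), tolerance = 1e-12)
  }
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(wilcoxon_rank_sum(c(2, 2), c(2, 2, 2))$p.value, 1)
})

test_that("Wilcoxon large-sample path agrees with the classical approximation and has power", {
  set.seed(8)
  x <- rnorm(40); y <- rnorm(45)
  got <- wilcoxon_rank_sum(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  # clearly shifted distributions are detected
  set.seed(9)
  rej <- mean(replicate(40, {
    wilcoxon_rank_sum(rnorm(60), rnorm(60, 1))$p.value < 0.05
  }))
  expect_gte(rej, 0.9)
})
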
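# Independent oracles used to check the analytic implementations.

# Wilson interval endpoints by numerically solving the score equation
# |p_hat - p| = z * sqrt(p (1 - p) / n) for p.
wilson_by_rootfinding <- function(k, n, conf.level = 0.95) {
  z <- qnorm((1 + conf.level) / 2)
  p_hat <- k / n
  g <- function(p) (p_hat - p)^2 - z^2 * p * (1 - p) / n
  # p_hat itself is a (trivial) sign-change endpoint, so bracket strictly
  # inside (0, p_hat) and (p_hat, 1); at k = 0 / k = n the outer endpoint is
  # the exact limit
  lo <- if (k == 0) 0 else
    uniroot(g, c(1e-15, p_hat * (1 - 1e-12)), tol = 1e-14)$root
  hi <- if (k == n) 1 else
    uniroot(g, c(p_hat + (1 - p_hat) * 1e-12, 1 - 1e-15), tol = 1e-14)$root
  c(lo, hi)
}

# Fisher two-sided p by enumerating every table with the observed margins.
fisher_by_enumeration <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  as <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, as) * choose(r2, c1 - as) / choose(n, c1)
  p_obs <- pr[as == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Two-sided rank-sum p by enumerating every assignment of the pooled values
# to the first group, recomputing midranks from scratch each time.
wilcoxon_by_enumeration <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); N <- length(pooled)
  sets <- combn(N, n1)
  stat <- function(ix) sum(rank(pooled)[ix])
  Ws <- apply(sets, 2, stat)
  mu <- n1 * (N + 1) / 2
  W <- stat(seq_len(n1))
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-10)
}

# Pearson chi-square computed from first principles (expected counts from
# the margins).
chisq_by_hand <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# A plain random Ct/IHC cohort for property tests (not the calibrated
# generator; covers edge regions more densely).
random_panels <- function(n, seed) {
  set.seed(seed)
  data.frame(
    sample_id = seq_len(n),
    ct_cyfip1 = runif(n, 25, 40),
    ct_esr1 = runif(n, 22, 40),
    ct_pgr = runif(n, 22, 40),
    ct_erbb2 = runif(n, 22, 40),
    ct_mki67 = runif(n, 22, 40),
    er_percent = sample(c(0, 1, 5, seq(10, 100, 10)), n, TRUE),
    pr_percent = sample(c(0, 1, 5, seq(10, 100, 10)), n, TRUE),
    ki67_percent = sample(c(0, 1, 5, seq(10, 100, 10)), n, TRUE),
    her2_ihc = sample(c("0", "1+", "2+", "3+"), n, TRUE),
    ish_ratio = ifelse(runif(n) < 0.5, runif(n, 0.5, 4), NA),
    ish_copies = NA_real_,
    stringsAsFactors = FALSE)
}
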
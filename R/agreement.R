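# Agreement engine: 2x2 construction under the prespecified exclusion rules,
# OPA/PPA/NPA with Wilson score intervals, Cohen's kappa, performance-target
# gates, and the baseline group-comparison tests.

#' Construct a 2x2 agreement table
#'
#' Cell layout follows the reporting convention
#' reference+/test+ (`a`), reference-/test+ (`b`),
#' reference+/test- (`c`), reference-/test- (`d`).
#'
#' @param a,b,c,d non-negative integer counts.
#' @param marker optional marker label.
#' @param exclusions optional named integer vector of excluded-sample tallies.
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d, marker = NULL, exclusions = integer(0)) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stopf("2x2 counts must be non-negative integers")
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d),
                 n = as.integer(a + b + c + d),
                 marker = marker, exclusions = exclusions),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("2x2 agreement table%s (n = %d)\n",
              if (!is.null(x$marker)) paste0(" [", x$marker, "]") else "", x$n))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("test+", "test-"), c("ref+", "ref-")))
  print(m)
  if (length(x$exclusions) && sum(x$exclusions) > 0) {
    cat("excluded:", paste(sprintf("%s=%d", names(x$exclusions),
                                   x$exclusions), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The score interval (no continuity correction):
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n}}
#' with \eqn{z} the standard-normal quantile at \eqn{(1+\gamma)/2}. Well
#' behaved at proportions of 0 or 1 (lower limit is exactly 0 at 0/n).
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param conf.level confidence level, default 0.95.
#' @return numeric `c(lower, upper)` on the proportion (0--1) scale.
#' @export
#' @examples
#' wilson_interval(97, 120)   # c(0.729, 0.869) at 1-decimal percent rounding
wilson_interval <- function(successes, n, conf.level = 0.95) {
  if (length(n) != 1 || n < 1) stopf("n must be a single integer >= 1")
  if (successes < 0 || successes > n) stopf("successes must lie in [0, n]")
  z <- stats::qnorm((1 + conf.level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  lo <- (centre - half) / denom
  hi <- (centre + half) / denom
  c(lower = max(0, lo), upper = min(1, hi))
}

#' Overall, positive and negative percent agreement of a 2x2 table
#'
#' OPA = (a+d)/n, PPA = a/(a+c) (sensitivity against the reference), NPA =
#' d/(b+d) (specificity). Ratios are exact; use [round_half_up()]-based
#' rendering (1 decimal on the percent scale) only for display. A zero
#' denominator yields `NA` for that statistic rather than an error.
#'
#' @param t a [two_by_two()] object.
#' @param conf.level confidence level for the Wilson intervals.
#' @return data.frame with rows OPA/PPA/NPA: `estimate`, `lower`, `upper`
#'   (proportions), `successes`, `trials`.
#' @export
proportion_stats <- function(t, conf.level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- list(OPA = c(t$a + t$d, t$n),
                PPA = c(t$a, t$a + t$c),
                NPA = c(t$d, t$b + t$d))
  out <- do.call(rbind, lapply(names(cells), function(nm) {
    k <- cells[[nm]][1]; den <- cells[[nm]][2]
    if (den == 0) {
      data.frame(statistic = nm, estimate = NA_real_, lower = NA_real_,
                 upper = NA_real_, successes = k, trials = den)
    } else {
      ci <- wilson_interval(k, den, conf.level)
      data.frame(statistic = nm, estimate = k / den, lower = ci[["lower"]],
                 upper = ci[["upper"]], successes = k, trials = den)
    }
  }))
  rownames(out) <- out$statistic
  out
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' \eqn{p_o = (a+d)/n} and \eqn{p_e} from the table margins. The confidence
#' interval uses the simple asymptotic standard error
#' \eqn{\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}}, truncated to \[-1, 1\].
#'
#' @param t a [two_by_two()] object.
#' @param conf.level confidence level, default 0.95.
#' @return list: `kappa`, `se`, `lower`, `upper`, `po`, `pe`. Degenerate
#'   margins (`pe == 1`) yield `NA` kappa.
#' @export
cohens_kappa <- function(t, conf.level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  if (t$n < 1) stopf("kappa requires n >= 1")
  n <- t$n
  po <- (t$a + t$d) / n
  pe <- ((t$a + t$c) * (t$a + t$b) + (t$b + t$d) * (t$c + t$d)) / n^2
  if (isTRUE(all.equal(pe, 1))) {
    return(list(kappa = NA_real_, se = NA_real_, lower = NA_real_,
                upper = NA_real_, po = po, pe = pe))
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- stats::qnorm((1 + conf.level) / 2)
  list(kappa = kappa, se = se,
       lower = max(-1, kappa - z * se), upper = min(1, kappa + z * se),
       po = po, pe = pe)
}

#' Prespecified performance targets (minimum acceptable lower 95% limits)
#'
#' The study design fixes, per marker, the minimum acceptable lower 95%
#' two-sided confidence limit for PPA and NPA (percent scale): ER (80, 80),
#' PR (70, 65), HER2 (75, 80), Ki67 (65, 65).
#'
#' @return data.frame with columns `marker`, `ppa_min`, `npa_min`.
#' @export
performance_targets <- function() {
  data.frame(marker = c("ESR1", "PGR", "ERBB2", "MKI67"),
             label = c("ER", "PR", "HER2", "Ki67"),
             ppa_min = c(80, 70, 75, 65),
             npa_min = c(80, 65, 80, 65),
             stringsAsFactors = FALSE)
}

#' Evaluate the performance-target gates
#'
#' A target is met when the unrounded Wilson lower 95% limit is at or above
#' the prespecified threshold.
#'
#' @param stats named list of [proportion_stats()] results (names are marker
#'   ids) or a `strat4_concordance` object.
#' @param targets a data.frame as returned by [performance_targets()].
#' @return data.frame: `marker`, `statistic`, `lower_pct`, `threshold_pct`,
#'   `met` (logical).
#' @export
evaluate_performance_targets <- function(stats, targets = performance_targets()) {
  if (inherits(stats, "strat4_concordance"))
    stats <- lapply(stats$markers, function(m) m$stats)
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    m <- targets$marker[i]
    if (is.null(stats[[m]])) next
    st <- stats[[m]]
    for (stat in c("PPA", "NPA")) {
      thr <- if (stat == "PPA") targets$ppa_min[i] else targets$npa_min[i]
      lo <- 100 * st[stat, "lower"]
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, statistic = stat, lower_pct = lo, threshold_pct = thr,
        met = !is.na(lo) && lo >= thr, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build the 2x2 agreement table for one marker under the exclusion rules
#'
#' Exclusions, tallied in order: STRAT4-invalid calls (all markers);
#' indeterminate calls (PGR/MKi67); reference-side exclusions — samples with
#' intermediate (10--20\%) Ki67 protein expression for MKi67, missing HER2
#' reference for ERBB2, and missing reference generally. For MKi67 the
#' remaining reference groups dichotomise low -> negative, high -> positive.
#'
#' @param calls data.frame from [classify_cohort()].
#' @param reference data.frame from [classify_reference()].
#' @param marker marker id (`"ESR1"`, `"PGR"`, `"ERBB2"`, `"MKI67"`).
#' @return a [two_by_two()] object carrying the exclusion tally; the
#'   invariant `n + sum(exclusions) == nrow(calls)` always holds.
#' @export
build_two_by_two <- function(calls, reference, marker) {
  marker <- match_marker(marker)
  stopifnot(length(marker) == 1L)
  df <- merge(calls, reference, by = "sample_id", sort = TRUE)
  if (nrow(df) != nrow(calls))
    stopf("calls and reference tables do not pair 1:1 on sample_id")
  status <- df[[paste0("status_", tolower(marker))]]
  excl <- c(invalid = 0L, indeterminate = 0L,
            intermediate_ki67 = 0L, missing_reference = 0L)
  keep <- rep(TRUE, nrow(df))

  inv <- status == "invalid"
  excl["invalid"] <- sum(inv); keep <- keep & !inv
  ind <- keep & status == "indeterminate"
  excl["indeterminate"] <- sum(ind); keep <- keep & !ind

  if (marker == "MKI67") {
    ref_raw <- df$ki67_group
    inter <- keep & !is.na(ref_raw) & ref_raw == "intermediate"
    excl["intermediate_ki67"] <- sum(inter); keep <- keep & !inter
    ref <- ifelse(ref_raw == "high", "positive",
                  ifelse(ref_raw == "low", "negative", NA_character_))
  } else {
    ref <- df[[REF_OF[[marker]]]]
  }
  mis <- keep & is.na(ref)
  excl["missing_reference"] <- sum(mis); keep <- keep & !mis

  s <- status[keep]; r <- ref[keep]
  two_by_two(a = sum(r == "positive" & s == "positive"),
             b = sum(r == "negative" & s == "positive"),
             c = sum(r == "positive" & s == "negative"),
             d = sum(r == "negative" & s == "negative"),
             marker = marker, exclusions = excl)
}

#' Pearson chi-square test for an r x c contingency table
#'
#' No continuity correction. Rows/columns with a zero margin are dropped
#' with a warning before testing.
#'
#' @param table matrix of counts.
#' @return list: `statistic`, `df`, `p.value`, `expected`.
#' @export
chi_square_rxc <- function(table) {
  table <- as.matrix(table)
  rz <- rowSums(table) == 0; cz <- colSums(table) == 0
  if (any(rz) || any(cz)) {
    warnf("dropping %d zero-margin row(s) and %d column(s)", sum(rz), sum(cz))
    table <- table[!rz, !cz, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2)
    stopf("chi-square needs at least a 2x2 table after dropping zero margins")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, expected = ct$expected)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p-value by summing the hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed one.
#'
#' @param t a [two_by_two()] object or a 2x2 matrix of counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(t) {
  m <- if (inherits(t, "two_by_two")) matrix(c(t$a, t$c, t$b, t$d), 2, 2)
       else as.matrix(t)
  stopifnot(all(dim(m) == c(2, 2)))
  stats::fisher.test(m)$p.value
}

#' Wilcoxon rank-sum test with midrank ties
#'
#' Statistic is the rank sum of `x` over the pooled midranks. Small pooled
#' samples (n <= 20) are tested exactly by enumerating all assignments of
#' the pooled ranks to the two groups (valid under ties because the midranks
#' are fixed); larger samples use the normal approximation with the tie
#' correction (no continuity correction). Two-sided p is the probability of
#' a rank sum at least as far from its null expectation as observed.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max largest pooled size for the exact enumeration path.
#' @return list: `statistic` (rank sum of `x`), `p.value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 20) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = sum(rank(pooled)[seq_along(x)]), p.value = 1,
                method = "degenerate"))
  r <- rank(pooled)              # midranks
  n1 <- length(x); N <- length(pooled)
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  if (N <= exact_max) {
    sets <- utils::combn(N, n1)
    Ws <- colSums(matrix(r[sets], nrow = n1))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-10)
    list(statistic = W, p.value = p, method = "exact")
  } else {
    n2 <- N - n1
    ties <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu) / sqrt(sig2)
    list(statistic = W, p.value = 2 * stats::pnorm(-abs(z)),
         method = "normal")
  }
}
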
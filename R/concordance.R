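# Top-level concordance analysis: one call builds, per marker, the 2x2 table
# under the exclusion rules and the full agreement statistics, plus the
# performance-target gate report.

#' Concordance analysis of STRAT4 calls against the IHC/ISH reference
#'
#' For each requested marker, builds the 2x2 table with
#' [build_two_by_two()], computes OPA/PPA/NPA with Wilson score intervals,
#' Cohen's kappa with its asymptotic interval, and evaluates the
#' prespecified performance-target gates on the unrounded lower limits.
#'
#' @param calls data.frame from [classify_cohort()].
#' @param reference data.frame from [classify_reference()].
#' @param markers markers to analyse (default all four).
#' @param conf.level confidence level, default 0.95.
#' @param targets performance targets, see [performance_targets()].
#' @return object of class `strat4_concordance` with components `markers`
#'   (per marker: `table`, `stats`, `kappa`), `gates`, `conf.level`,
#'   `n_input`.
#' @export
#' @examples
#' cfg <- default_config(n_patients = 300)
#' coh <- generate_cohort(cfg, seed = 1)
#' fit <- concordance(classify_cohort(coh), classify_reference(coh))
#' fit
concordance <- function(calls, reference, markers = MARKERS,
                        conf.level = 0.95, targets = performance_targets()) {
  markers <- match_marker(markers)
  per <- lapply(markers, function(m) {
    t <- build_two_by_two(calls, reference, m)
    list(table = t,
         stats = proportion_stats(t, conf.level),
         kappa = cohens_kappa(t, conf.level))
  })
  names(per) <- markers
  obj <- structure(list(markers = per, conf.level = conf.level,
                        n_input = nrow(calls), targets = targets),
                   class = "strat4_concordance")
  obj$gates <- evaluate_performance_targets(obj, targets)
  obj
}

#' @export
print.strat4_concordance <- function(x, ...) {
  cat(sprintf("Concordance of STRAT4 delta-Ct calls vs IHC/ISH reference (N input = %d)\n\n",
              x$n_input))
  hdr <- sprintf("%-6s %5s %5s %5s %5s %5s  %-22s %-22s %-22s %-14s",
                 "marker", "a", "b", "c", "d", "n",
                 "OPA % (95% CI)", "PPA % (95% CI)", "NPA % (95% CI)",
                 "kappa (95% CI)")
  cat(hdr, "\n")
  for (m in names(x$markers)) {
    e <- x$markers[[m]]; t <- e$table; s <- e$stats; k <- e$kappa
    f <- function(row) sprintf("%s (%s-%s)", fmt_pct(s[row, "estimate"]),
                               fmt_pct(s[row, "lower"]), fmt_pct(s[row, "upper"]))
    kf <- if (is.na(k$kappa)) "NA" else
      sprintf("%.2f (%.2f-%.2f)", round_half_up(k$kappa, 2),
              round_half_up(k$lower, 2), round_half_up(k$upper, 2))
    cat(sprintf("%-6s %5d %5d %5d %5d %5d  %-22s %-22s %-22s %-14s\n",
                m, t$a, t$b, t$c, t$d, t$n, f("OPA"), f("PPA"), f("NPA"), kf))
    ex <- t$exclusions[t$exclusions > 0]
    if (length(ex))
      cat(sprintf("       excluded: %s\n",
                  paste(sprintf("%s=%d", names(ex), ex), collapse = ", ")))
  }
  cat("\nPerformance-target gates (lower 95% limit vs prespecified minimum):\n")
  g <- x$gates
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-6s %s: %5.1f%% vs %g%% -> %s\n", g$marker[i],
                g$statistic[i], round_half_up(g$lower_pct[i], 1),
                g$threshold_pct[i], ifelse(g$met[i], "met", "not met")))
  invisible(x)
}

#' @export
summary.strat4_concordance <- function(object, ...) {
  df <- as.data.frame(object)
  structure(list(table = df, gates = object$gates), class = "summary.strat4_concordance")
}

#' @export
print.summary.strat4_concordance <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("\n")
  print(x$gates, row.names = FALSE)
  invisible(x)
}

#' Machine-readable concordance report
#'
#' One row per marker with counts, exclusion tallies, unrounded agreement
#' statistics (percent scale) and kappa.
#'
#' @param x a `strat4_concordance` object.
#' @param ... unused.
#' @return data.frame.
#' @export
as.data.frame.strat4_concordance <- function(x, ...) {
  do.call(rbind, lapply(names(x$markers), function(m) {
    e <- x$markers[[m]]; t <- e$table; s <- e$stats; k <- e$kappa
    data.frame(marker = m, a = t$a, b = t$b, c = t$c, d = t$d, n = t$n,
               excluded_invalid = t$exclusions[["invalid"]],
               excluded_indeterminate = t$exclusions[["indeterminate"]],
               excluded_intermediate_ki67 = t$exclusions[["intermediate_ki67"]],
               excluded_missing_reference = t$exclusions[["missing_reference"]],
               opa = 100 * s["OPA", "estimate"],
               opa_lower = 100 * s["OPA", "lower"], opa_upper = 100 * s["OPA", "upper"],
               ppa = 100 * s["PPA", "estimate"],
               ppa_lower = 100 * s["PPA", "lower"], ppa_upper = 100 * s["PPA", "upper"],
               npa = 100 * s["NPA", "estimate"],
               npa_lower = 100 * s["NPA", "lower"], npa_upper = 100 * s["NPA", "upper"],
               kappa = k$kappa, kappa_lower = k$lower, kappa_upper = k$upper,
               stringsAsFactors = FALSE)
  }))
}
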
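# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: per-marker call prevalences (including invalid and
# indeterminate fractions driven by the shared control gene), the
# call-vs-reference discordance pattern, and an exponential
# proportional-hazards outcome model on the latent marker truths and
# clinical covariates. Also expands deterministic 2x2 fixtures that
# round-trip through the full calling pipeline.

# Published marginal call/reference frequencies and 2x2 discordance
# structure of the assay validation cohort (n = 1115), used as generator
# defaults.
#' Published 2x2 validation counts per marker
#'
#' The (a, b, c, d) = (ref+/test+, ref-/test+, ref+/test-, ref-/test-)
#' counts reported by the assay's clinical validation study, used as
#' deterministic fixtures.
#'
#' @return data.frame with columns `marker`, `a`, `b`, `c`, `d`.
#' @export
validation_counts <- function() {
  data.frame(marker = c("ESR1", "PGR", "ERBB2", "MKI67"),
             a = c(1045L, 822L, 41L, 158L),
             b = c(0L, 23L, 1L, 66L),
             c = c(12L, 81L, 18L, 9L),
             d = c(19L, 97L, 1014L, 260L),
             stringsAsFactors = FALSE)
}

#' Default synthetic-cohort configuration
#'
#' Defaults encode the study conditions of the validation cohort:
#' per-marker call prevalences (positive/negative/invalid/indeterminate
#' margins), call-conditional reference probabilities reproducing the
#' published discordance structure, clinical covariate distributions, and a
#' proportional-hazards outcome model whose log-hazard ratios are the
#' published univariable values, with the baseline hazard calibrated so the
#' distant-recurrence event fraction is ~14.1% under uniform administrative
#' censoring on 5--16 years.
#'
#' Latent marker prevalences are solved from the target call-positive
#' fractions and the Gaussian delta-Ct mixture tails, so the generated call
#' margins match the targets in expectation.
#'
#' @param n_patients cohort size, default 1115.
#' @return object of class `strat4_config`.
#' @export
default_config <- function(n_patients = 1115) {
  thr <- strat4_thresholds()
  # call margins as fractions of the whole cohort (invalid = control > 35)
  invalid_frac <- 0.035
  call_pos <- c(ESR1 = 0.937, PGR = 0.758, ERBB2 = 0.038, MKI67 = 0.456)
  mix <- list(ESR1 = c(mu_pos = 3.0, mu_neg = -4.0, sd = 1.5),
              PGR = c(mu_pos = -0.5, mu_neg = -6.5, sd = 1.2),
              ERBB2 = c(mu_pos = 2.0, mu_neg = -4.5, sd = 1.2),
              MKI67 = c(mu_pos = -1.5, mu_neg = -6.5, sd = 1.0))
  markers <- lapply(MARKERS, function(m) {
    cut <- thr$delta_ct_cutoff[[m]]
    mx <- mix[[m]]
    p_call <- call_pos[[m]] / (1 - invalid_frac)  # conditional on valid control
    tail_pos <- 1 - stats::pnorm(cut, mx[["mu_pos"]], mx[["sd"]])
    tail_neg <- 1 - stats::pnorm(cut, mx[["mu_neg"]], mx[["sd"]])
    prevalence <- (p_call - tail_neg) / (tail_pos - tail_neg)
    if (is.na(prevalence) || prevalence < 0 || prevalence > 1)
      stopf("infeasible mixture for %s: cannot reach call-positive fraction %.3f",
            m, p_call)
    list(cutoff = cut, mu_pos = mx[["mu_pos"]], mu_neg = mx[["mu_neg"]],
         sd = mx[["sd"]], prevalence = prevalence, call_pos_frac = p_call)
  })
  names(markers) <- MARKERS
  # reference status conditional on the latent call (delta-Ct vs cut-off),
  # from the published 2x2 row proportions
  markers$ESR1$ref_pos_given <- c(call_pos = 1045 / 1045, call_neg = 12 / 31)
  markers$PGR$ref_pos_given <- c(call_pos = 822 / 845, call_neg = 81 / 178)
  markers$ERBB2$ref_pos_given <- c(call_pos = 41 / 42, call_neg = 18 / 1032)
  markers$MKI67$ref_int_given <- c(call_pos = 0.5656, call_neg = 0.3654)
  markers$MKI67$ref_high_given_nonint <- c(call_pos = 158 / 224, call_neg = 9 / 269)

  structure(list(
    n_patients = n_patients,
    thresholds = thr,
    control = list(invalid_frac = invalid_frac,
                   # fraction of valid-control samples whose control Ct falls
                   # in the weak (31, 35] window; one shared window must serve
                   # both the PGR (4.8%) and MKi67 (11.4%) indeterminate margins
                   window_frac = 0.228,
                   ct_valid = c(25, 31), ct_window = c(31, 35),
                   ct_invalid = c(35, 40)),
    markers = markers,
    her2_render = list(missing_frac = 2 / 1115,
                       p_3plus_given_pos = 0.8,
                       ratio_pos = c(2.2, 5.0),
                       p_2plus_given_neg = 0.1, p_0_given_neg = 0.3,
                       ratio_neg = c(0.8, 1.6)),
    covariates = list(
      age_mean = 64.3, age_sd = 9.5, age_range = c(40.9, 80.7),
      pt_probs = c(pT1 = 0.585, pT2 = 0.384, pT3 = 0.027, missing = 0.004),
      nodal_probs = c("0" = 0.619, "1-3" = 0.263, "4-10" = 0.085,
                      ">10" = 0.029, missing = 0.004),
      grade_probs = c(G1 = 0.180, G2 = 0.546, G3 = 0.200, GX = 0.070,
                      missing = 0.004),
      arm_probs = c(TAM = 0.529, "TAM+AG" = 0.471)),
    hazard = list(
      baseline = 0.0097,            # events/year; calibrated to ~14.1% DR
      age_center = 64.6,
      log_hr = c(ESR1 = log(0.40), PGR = log(0.50), ERBB2 = log(2.92),
                 MKI67 = log(2.35), age = log(0.98),
                 pT2 = log(2.34), pT3 = log(2.92),
                 nodal_1_3 = log(2.42), nodal_4_10 = log(5.60),
                 nodal_gt10 = log(6.36),
                 G2 = log(1.44), G3 = log(1.66), GX = log(1.25)),
      other_event_rate = 0.015,     # death / secondary carcinoma (censoring)
      censor_range = c(5, 16))
  ), class = "strat4_config")
}

#' @export
print.strat4_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort configuration: n = %d\n", x$n_patients))
  cat(sprintf("  control: invalid %.1f%%, weak-window %.1f%% of valid\n",
              100 * x$control$invalid_frac, 100 * x$control$window_frac))
  for (m in MARKERS) {
    mk <- x$markers[[m]]
    cat(sprintf("  %-5s cutoff %5.1f, latent prevalence %.3f, mixture N(%.1f,%.1f)/N(%.1f,%.1f)\n",
                m, mk$cutoff, mk$prevalence, mk$mu_pos, mk$sd, mk$mu_neg, mk$sd))
  }
  cat(sprintf("  baseline hazard %.4f /yr; censoring U(%g, %g) yr\n",
              x$hazard$baseline, x$hazard$censor_range[1], x$hazard$censor_range[2]))
  invisible(x)
}

sample_levels <- function(n, probs) {
  lv <- names(probs)
  out <- sample(lv, n, replace = TRUE, prob = probs)
  out[out == "missing"] <- NA
  out
}

# Render an IHC percent for a binary hormone-receptor reference status.
render_hr_percent <- function(ref_pos) {
  grid_pos <- c(1, 5, seq(10, 100, 10))
  w <- c(1, 2, 2, 3, 4, 5, 6, 8, 10, 14, 18, 22)
  ifelse(ref_pos, sample(grid_pos, length(ref_pos), TRUE, prob = w), 0)
}

#' Generate a synthetic cohort
#'
#' Per patient: a control-gene Ct (valid, weak-window or invalid region);
#' latent marker truths from the configured prevalences; delta-Ct from the
#' truth-conditional Gaussian mixture, back-solved into target Ct; an
#' IHC/ISH reference drawn conditionally on the latent call so the
#' discordance structure matches the configuration; clinical covariates; and
#' a distant-recurrence outcome from an exponential proportional-hazards
#' model with independent other-cause and administrative censoring.
#' Fully reproducible given `seed`.
#'
#' @param config a [default_config()] object.
#' @param seed integer RNG seed.
#' @return data.frame in the standard cohort schema (Ct, IHC, covariate and
#'   follow-up columns); latent truths are attached as attribute `latent`.
#' @export
generate_cohort <- function(config = default_config(), seed = 1L) {
  stopifnot(inherits(config, "strat4_config"))
  for (m in MARKERS) {
    mk <- config$markers[[m]]
    if (is.na(mk$prevalence) || mk$prevalence < 0 || mk$prevalence > 1)
      stopf("%s latent prevalence %.3f outside [0, 1]: infeasible configuration",
            m, mk$prevalence)
    if (!is.finite(mk$sd) || mk$sd <= 0)
      stopf("%s mixture SD must be > 0", m)
  }
  probs <- c(config$control$invalid_frac, config$control$window_frac,
             config$her2_render$missing_frac)
  if (any(probs < 0 | probs > 1))
    stopf("configuration probabilities must lie in [0, 1]")
  set.seed(seed)
  n <- config$n_patients
  ctl <- config$control
  region <- sample(c("valid", "window", "invalid"), n, replace = TRUE,
                   prob = c((1 - ctl$invalid_frac) * (1 - ctl$window_frac),
                            (1 - ctl$invalid_frac) * ctl$window_frac,
                            ctl$invalid_frac))
  ct_cyfip1 <- numeric(n)
  ct_cyfip1[region == "valid"] <- stats::runif(sum(region == "valid"),
                                               ctl$ct_valid[1], ctl$ct_valid[2])
  ct_cyfip1[region == "window"] <- stats::runif(sum(region == "window"),
                                                ctl$ct_window[1] + 1e-6, ctl$ct_window[2])
  ct_cyfip1[region == "invalid"] <- stats::runif(sum(region == "invalid"),
                                                 ctl$ct_invalid[1] + 1e-6, ctl$ct_invalid[2])

  truth <- list(); dct <- list(); latent_call <- list()
  out <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                    ct_cyfip1 = ct_cyfip1, stringsAsFactors = FALSE)
  for (m in MARKERS) {
    mk <- config$markers[[m]]
    tr <- stats::rbinom(n, 1, mk$prevalence)
    d <- stats::rnorm(n, ifelse(tr == 1, mk$mu_pos, mk$mu_neg), mk$sd)
    truth[[m]] <- tr; dct[[m]] <- d
    latent_call[[m]] <- d >= mk$cutoff
    out[[paste0("ct_", tolower(m))]] <- ct_cyfip1 - d
  }

  # IHC reference, conditional on the latent call
  ref_pos <- function(m) {
    p <- config$markers[[m]]$ref_pos_given
    stats::rbinom(n, 1, ifelse(latent_call[[m]], p[["call_pos"]], p[["call_neg"]])) == 1
  }
  er_pos <- ref_pos("ESR1"); pr_pos <- ref_pos("PGR"); her2_pos <- ref_pos("ERBB2")
  out$er_percent <- render_hr_percent(er_pos)
  out$pr_percent <- render_hr_percent(pr_pos)

  mk <- config$markers$MKI67
  p_int <- ifelse(latent_call$MKI67, mk$ref_int_given[["call_pos"]],
                  mk$ref_int_given[["call_neg"]])
  is_int <- stats::rbinom(n, 1, p_int) == 1
  p_high <- ifelse(latent_call$MKI67, mk$ref_high_given_nonint[["call_pos"]],
                   mk$ref_high_given_nonint[["call_neg"]])
  is_high <- !is_int & stats::rbinom(n, 1, p_high) == 1
  ki67 <- numeric(n)
  ki67[is_int] <- sample(c(10, 20), sum(is_int), TRUE, prob = c(0.6, 0.4))
  ki67[is_high] <- sample(seq(30, 100, 10), sum(is_high), TRUE,
                          prob = c(8, 6, 5, 4, 3, 2, 1, 1))
  low <- !is_int & !is_high
  ki67[low] <- sample(c(0, 1, 5), sum(low), TRUE, prob = c(0.25, 0.3, 0.45))
  out$ki67_percent <- ki67

  hr2 <- config$her2_render
  her2_ihc <- character(n); ratio <- rep(NA_real_, n); copies <- rep(NA_real_, n)
  p3 <- stats::runif(n) < hr2$p_3plus_given_pos
  her2_ihc[her2_pos & p3] <- "3+"
  eqpos <- her2_pos & !p3
  her2_ihc[eqpos] <- "2+"
  ratio[eqpos] <- stats::runif(sum(eqpos), hr2$ratio_pos[1], hr2$ratio_pos[2])
  u <- stats::runif(n)
  neg0 <- !her2_pos & u < hr2$p_0_given_neg
  neg2 <- !her2_pos & u > 1 - hr2$p_2plus_given_neg
  neg1 <- !her2_pos & !neg0 & !neg2
  her2_ihc[neg0] <- "0"; her2_ihc[neg1] <- "1+"; her2_ihc[neg2] <- "2+"
  ratio[neg2] <- stats::runif(sum(neg2), hr2$ratio_neg[1], hr2$ratio_neg[2])
  mis <- stats::runif(n) < hr2$missing_frac
  her2_ihc[mis] <- "2+"; ratio[mis] <- NA; copies[mis] <- NA
  out$her2_ihc <- her2_ihc; out$ish_ratio <- ratio; out$ish_copies <- copies

  cv <- config$covariates
  lo <- stats::pnorm(cv$age_range[1], cv$age_mean, cv$age_sd)
  hi <- stats::pnorm(cv$age_range[2], cv$age_mean, cv$age_sd)
  out$age <- stats::qnorm(stats::runif(n, lo, hi), cv$age_mean, cv$age_sd)
  out$pt_category <- sample_levels(n, cv$pt_probs)
  out$nodal <- sample_levels(n, cv$nodal_probs)
  out$grade <- sample_levels(n, cv$grade_probs)
  out$arm <- sample_levels(n, cv$arm_probs)

  hz <- config$hazard
  b <- hz$log_hr
  lp <- b[["ESR1"]] * truth$ESR1 + b[["PGR"]] * truth$PGR +
    b[["ERBB2"]] * truth$ERBB2 + b[["MKI67"]] * truth$MKI67 +
    b[["age"]] * (out$age - hz$age_center)
  lp <- lp + ifelse(is.na(out$pt_category), 0,
                    ifelse(out$pt_category == "pT2", b[["pT2"]],
                           ifelse(out$pt_category == "pT3", b[["pT3"]], 0)))
  lp <- lp + ifelse(is.na(out$nodal), 0,
                    ifelse(out$nodal == "1-3", b[["nodal_1_3"]],
                           ifelse(out$nodal == "4-10", b[["nodal_4_10"]],
                                  ifelse(out$nodal == ">10", b[["nodal_gt10"]], 0))))
  lp <- lp + ifelse(is.na(out$grade), 0,
                    ifelse(out$grade == "G2", b[["G2"]],
                           ifelse(out$grade == "G3", b[["G3"]],
                                  ifelse(out$grade == "GX", b[["GX"]], 0))))
  t_dr <- stats::rexp(n, hz$baseline * exp(lp))
  t_other <- stats::rexp(n, hz$other_event_rate)
  c_adm <- stats::runif(n, hz$censor_range[1], hz$censor_range[2])
  tmin <- pmin(t_dr, t_other, c_adm)
  out$followup_time <- tmin
  out$event_type <- ifelse(t_dr <= tmin, "distant_recurrence",
                           ifelse(t_other <= tmin,
                                  ifelse(stats::runif(n) < 0.5, "death",
                                         "secondary_carcinoma"),
                                  "none"))
  attr(out, "latent") <- data.frame(sample_id = out$sample_id,
                                    truth_esr1 = truth$ESR1,
                                    truth_pgr = truth$PGR,
                                    truth_erbb2 = truth$ERBB2,
                                    truth_mki67 = truth$MKI67,
                                    linear_predictor = lp)
  out
}

# Template cohort row classifying every marker call-positive and every
# reference positive (focal cells override their own fields).
fixture_base_row <- function(thresholds) {
  ctc <- 28
  row <- list(ct_cyfip1 = ctc)
  for (m in MARKERS)
    row[[paste0("ct_", tolower(m))]] <- ctc - (thresholds$delta_ct_cutoff[[m]] + 2)
  c(row, list(er_percent = 90, pr_percent = 90, ki67_percent = 90,
              her2_ihc = "3+", ish_ratio = NA_real_, ish_copies = NA_real_))
}

#' Expand a 2x2 fixture specification into classifiable records
#'
#' Emits `a + b + c + d` cohort records whose Ct and IHC field values
#' deterministically classify into the intended 2x2 cell for the focal
#' marker (other markers get benign concordant-positive templates). The
#' expansion is verified by running the full classify-and-tabulate pipeline;
#' any template misclassification is a hard error, guarding against drift in
#' the call logic.
#'
#' @param spec list with `marker` and counts `a`, `b`, `c`, `d`.
#' @param thresholds a [strat4_thresholds()] object.
#' @return data.frame of cohort records (`sample_id` plus Ct and IHC columns).
#' @export
#' @examples
#' rec <- expand_two_by_two_fixture(list(marker = "ESR1", a = 2, b = 0, c = 1, d = 1))
#' build_two_by_two(classify_cohort(rec), classify_reference(rec), "ESR1")
expand_two_by_two_fixture <- function(spec, thresholds = strat4_thresholds()) {
  marker <- match_marker(spec$marker)
  counts <- c(a = spec$a, b = spec$b, c = spec$c, d = spec$d)
  if (any(is.na(counts)) || any(counts < 0))
    stopf("fixture counts must be non-negative")
  base <- fixture_base_row(thresholds)
  cut <- thresholds$delta_ct_cutoff[[marker]]
  ct_call <- function(pos) base$ct_cyfip1 - (cut + if (pos) 1 else -1)
  set_ref <- function(row, pos) {
    if (marker == "ESR1") row$er_percent <- if (pos) 90 else 0
    else if (marker == "PGR") row$pr_percent <- if (pos) 90 else 0
    else if (marker == "MKI67") row$ki67_percent <- if (pos) 90 else 0
    else row$her2_ihc <- if (pos) "3+" else "1+"
    row
  }
  cell <- function(ref_pos, call_pos) {
    row <- base
    row[[paste0("ct_", tolower(marker))]] <- ct_call(call_pos)
    set_ref(row, ref_pos)
  }
  templates <- list(a = cell(TRUE, TRUE), b = cell(FALSE, TRUE),
                    c = cell(TRUE, FALSE), d = cell(FALSE, FALSE))
  rows <- do.call(rbind, lapply(names(counts), function(cl) {
    k <- counts[[cl]]
    if (k == 0) return(NULL)
    df <- as.data.frame(templates[[cl]], stringsAsFactors = FALSE)
    df[rep(1L, k), , drop = FALSE]
  }))
  if (is.null(rows)) stopf("fixture has zero total count")
  rows <- cbind(sample_id = sprintf("%s%05d", marker, seq_len(nrow(rows))),
                rows, stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  got <- build_two_by_two(classify_cohort(rows, thresholds),
                          classify_reference(rows), marker)
  if (!identical(c(got$a, got$b, got$c, got$d),
                 as.integer(counts[c("a", "b", "c", "d")])))
    stopf("fixture template misclassified for %s: expected (%s), pipeline yields (%d,%d,%d,%d)",
          marker, paste(counts, collapse = ","), got$a, got$b, got$c, got$d)
  rows
}
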
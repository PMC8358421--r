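#' Default delta-Ct thresholds and control-gene cut-offs
#'
#' The assay calls a target gene overexpressed (positive) when its delta-Ct
#' (control-gene Ct minus target-gene Ct) meets or exceeds a marker-specific
#' cut-off. The control gene (CYFIP1) governs validity: a control Ct above
#' `control_validity_ct` means inadequate tumour material (all four calls
#' invalid); a sub-cut-off PGR or MKi67 result with control Ct in
#' (`control_confident_negative_ct`, `control_validity_ct`] cannot be
#' confidently called negative and is reported indeterminate.
#'
#' @param delta_ct_cutoff named numeric vector of positivity cut-offs in
#'   delta-Ct units, one per marker (ESR1, PGR, ERBB2, MKI67). Comparison is
#'   inclusive (`>=`).
#' @param control_validity_ct control-gene Ct above which the sample is
#'   invalid for all markers. Default 35.
#' @param control_confident_negative_ct control-gene Ct at or below which a
#'   sub-cut-off PGR/MKi67 result is a confident negative. Default 31.
#' @return an object of class `strat4_thresholds`.
#' @export
#' @examples
#' strat4_thresholds()
strat4_thresholds <- function(delta_ct_cutoff = c(ESR1 = -1.0, PGR = -3.5,
                                                  ERBB2 = -1.0, MKI67 = -4.0),
                              control_validity_ct = 35,
                              control_confident_negative_ct = 31) {
  delta_ct_cutoff <- delta_ct_cutoff[MARKERS]
  if (anyNA(delta_ct_cutoff) || !all(is.finite(delta_ct_cutoff)))
    stopf("delta_ct_cutoff must supply a finite cut-off for each of %s",
          paste(MARKERS, collapse = ", "))
  if (!is.finite(control_validity_ct) || !is.finite(control_confident_negative_ct))
    stopf("control Ct cut-offs must be finite")
  if (control_confident_negative_ct >= control_validity_ct)
    stopf("control_confident_negative_ct must be < control_validity_ct")
  structure(list(delta_ct_cutoff = delta_ct_cutoff,
                 control_validity_ct = control_validity_ct,
                 control_confident_negative_ct = control_confident_negative_ct),
            class = "strat4_thresholds")
}

#' @export
print.strat4_thresholds <- function(x, ...) {
  cat("STRAT4 call thresholds\n")
  cat("  delta-Ct positivity cut-offs (>=):\n")
  for (m in MARKERS)
    cat(sprintf("    %-5s %5.1f\n", m, x$delta_ct_cutoff[[m]]))
  cat(sprintf("  control validity Ct (invalid if >): %g\n", x$control_validity_ct))
  cat(sprintf("  confident-negative control Ct (<=): %g\n",
              x$control_confident_negative_ct))
  invisible(x)
}

#' Delta-Ct of a target gene relative to the control gene
#'
#' `delta_ct = ct_control - ct_target`. Higher values mean higher relative
#' target mRNA expression (the target crossed threshold earlier). A target
#' reported "not detected" (`NA`) yields `-Inf`: absent amplification sits
#' below every positivity cut-off.
#'
#' @param ct_control control-gene Ct (finite, > 0).
#' @param ct_target target-gene Ct, or `NA` for "not detected".
#' @return numeric delta-Ct (possibly `-Inf`). Vectorised.
#' @export
delta_ct <- function(ct_control, ct_target) {
  if (any(!is.finite(ct_control) | ct_control <= 0))
    stopf("ct_control must be finite and positive; missing control follows the invalid pathway, not delta_ct()")
  if (any(is.finite(ct_target) & ct_target <= 0))
    stopf("ct_target must be positive when present")
  out <- ct_control - ct_target
  out[is.na(ct_target)] <- -Inf
  out
}

#' Classify one marker from its delta-Ct and the control-gene Ct
#'
#' Rules, applied in order:
#' \enumerate{
#'   \item control Ct > validity cut-off (or missing) -> `invalid`;
#'   \item delta-Ct >= marker cut-off (inclusive) -> `positive`;
#'   \item otherwise, ESR1/ERBB2 -> `negative`; PGR/MKi67 -> `negative` when
#'     the control Ct is at or below the confident-negative cut-off, else
#'     `indeterminate` (control Ct in the (31, 35] window is too weak to call
#'     a sub-cut-off result negative).
#' }
#'
#' @param marker one of `"ESR1"`, `"PGR"`, `"ERBB2"`, `"MKI67"`.
#' @param delta_ct delta-Ct value(s); `-Inf` allowed, `NA` only with an
#'   invalid/missing control.
#' @param ct_control control-gene Ct value(s); `NA` means missing.
#' @param thresholds a [strat4_thresholds()] object.
#' @return character vector of statuses in
#'   `{"positive","negative","invalid","indeterminate"}`.
#' @export
#' @examples
#' classify_marker("ESR1", -1.0, 30)   # boundary is positive
#' classify_marker("PGR",  -3.6, 32)   # indeterminate window
classify_marker <- function(marker, delta_ct, ct_control,
                            thresholds = strat4_thresholds()) {
  marker <- match_marker(marker)
  stopifnot(length(marker) == 1L)
  n <- max(length(delta_ct), length(ct_control))
  delta_ct <- rep_len(delta_ct, n)
  ct_control <- rep_len(ct_control, n)
  cut <- thresholds$delta_ct_cutoff[[marker]]
  invalid <- is.na(ct_control) | ct_control > thresholds$control_validity_ct
  if (any(is.na(delta_ct) & !invalid))
    stopf("delta_ct may be missing only when the control is missing/invalid")
  status <- rep(NA_character_, n)
  status[invalid] <- "invalid"
  pos <- !invalid & delta_ct >= cut
  status[pos] <- "positive"
  below <- !invalid & !pos
  if (marker %in% c("PGR", "MKI67")) {
    weak <- below & ct_control > thresholds$control_confident_negative_ct
    status[below & !weak] <- "negative"
    status[weak] <- "indeterminate"
  } else {
    status[below] <- "negative"
  }
  status
}

#' Classify a full Ct panel into per-marker STRAT4 calls
#'
#' @param panel a list or one-row data.frame with fields `ct_cyfip1`,
#'   `ct_esr1`, `ct_pgr`, `ct_erbb2`, `ct_mki67` (NA = not detected/missing).
#' @param thresholds a [strat4_thresholds()] object.
#' @return a data.frame with one row per marker: `marker`, `delta_ct`,
#'   `status`.
#' @export
#' @examples
#' classify_panel(list(ct_cyfip1 = 30, ct_esr1 = 29, ct_pgr = 34,
#'                     ct_erbb2 = 29, ct_mki67 = 29))
classify_panel <- function(panel, thresholds = strat4_thresholds()) {
  need <- c("ct_cyfip1", "ct_esr1", "ct_pgr", "ct_erbb2", "ct_mki67")
  if (!all(need %in% names(panel)))
    stopf("panel is missing field(s): %s",
          paste(setdiff(need, names(panel)), collapse = ", "))
  ctc <- panel[["ct_cyfip1"]]
  if (length(ctc) != 1L)
    stopf("classify_panel() takes a single panel; use classify_cohort() for tables")
  valid_ctrl <- !is.na(ctc) && ctc <= thresholds$control_validity_ct
  res <- lapply(MARKERS, function(m) {
    ctt <- panel[[paste0("ct_", tolower(m))]]
    if (valid_ctrl) {
      d <- delta_ct(ctc, ctt)
      s <- classify_marker(m, d, ctc, thresholds)
    } else {
      d <- NA_real_
      s <- "invalid"
    }
    data.frame(marker = m, delta_ct = d, status = s,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify every sample of a cohort table
#'
#' Vectorised over rows of a cohort table in the standard schema
#' (`sample_id`, `ct_cyfip1`, `ct_esr1`, `ct_pgr`, `ct_erbb2`, `ct_mki67`;
#' empty/NA Ct = not detected or missing).
#'
#' @param cohort data.frame with the Ct columns above.
#' @param thresholds a [strat4_thresholds()] object.
#' @return data.frame with `sample_id` and, per marker, `delta_ct_<m>` and
#'   `status_<m>` columns (lower-case marker suffixes).
#' @export
classify_cohort <- function(cohort, thresholds = strat4_thresholds()) {
  need <- c("ct_cyfip1", "ct_esr1", "ct_pgr", "ct_erbb2", "ct_mki67")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stopf("cohort is missing column(s): %s", paste(miss, collapse = ", "))
  id <- cohort[["sample_id"]] %||% seq_len(nrow(cohort))
  bad <- vapply(need, function(cl) {
    v <- cohort[[cl]]
    any(is.finite(v) & v <= 0)
  }, logical(1))
  if (any(bad))
    stopf("non-positive Ct values in column(s): %s",
          paste(need[bad], collapse = ", "))
  ctc <- cohort[["ct_cyfip1"]]
  invalid <- is.na(ctc) | ctc > thresholds$control_validity_ct
  out <- data.frame(sample_id = id, stringsAsFactors = FALSE)
  for (m in MARKERS) {
    ctt <- cohort[[paste0("ct_", tolower(m))]]
    d <- rep(NA_real_, nrow(cohort))
    d[!invalid] <- delta_ct(ctc[!invalid], ctt[!invalid])
    s <- rep("invalid", nrow(cohort))
    if (any(!invalid))
      s[!invalid] <- classify_marker(m, d[!invalid], ctc[!invalid], thresholds)
    out[[paste0("delta_ct_", tolower(m))]] <- d
    out[[paste0("status_", tolower(m))]] <- s
  }
  out
}
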
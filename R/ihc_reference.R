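# Central-pathology reference classification from IHC / ISH readings.

# Reporting grid for percent-stained nuclei: readings are documented at 1%,
# 5%, then decade resolution.
PERCENT_GRID <- c(0, 1, 5, seq(10, 100, by = 10))

#' Snap a raw percent-stained value onto the pathology reporting grid
#'
#' Scores are reported on the grid `{0, 1, 5, 10, 20, ..., 100}`. The raw
#' value maps to the nearest grid value; exact ties round up. Idempotent on
#' grid values.
#'
#' @param raw_percent numeric in \[0, 100\] (NA passed through).
#' @return numeric vector of grid values.
#' @export
#' @examples
#' normalize_percent(c(0.4, 3, 17, 25))
normalize_percent <- function(raw_percent) {
  ok <- is.na(raw_percent) | (raw_percent >= 0 & raw_percent <= 100)
  if (!all(ok))
    stopf("percent values must lie in [0, 100]; offending value(s): %s",
          paste(utils::head(raw_percent[!ok], 5), collapse = ", "))
  vapply(raw_percent, function(p) {
    if (is.na(p)) return(NA_real_)
    d <- abs(PERCENT_GRID - p)
    # ties round up: among minimal distances take the largest grid value
    cand <- PERCENT_GRID[d == min(d)]
    max(cand)
  }, numeric(1))
}

#' Hormone receptor (ER/PR) status from percent-stained nuclei
#'
#' Positive at >= 1\% stained nuclei, regardless of staining intensity.
#'
#' @param percent normalized percent on the reporting grid (NA allowed).
#' @return character: `"positive"`, `"negative"` or `NA`.
#' @export
classify_hormone_receptor <- function(percent) {
  ok <- is.na(percent) | (percent >= 0 & percent <= 100)
  if (!all(ok)) stopf("percent values must lie in [0, 100]")
  ifelse(is.na(percent), NA_character_,
         ifelse(percent >= 1, "positive", "negative"))
}

#' Ki67 proliferation group from percent-stained nuclei
#'
#' `<=5`\% low, `10--20`\% intermediate, `>=30`\% high. Values must sit on
#' the reporting grid (use [normalize_percent()] first); there is no grid
#' value between 20 and 30, so the grouping is exhaustive.
#'
#' @param percent normalized percent on the reporting grid (NA allowed).
#' @return character: `"low"`, `"intermediate"`, `"high"` or `NA`.
#' @export
group_ki67 <- function(percent) {
  off <- !is.na(percent) & !(percent %in% PERCENT_GRID)
  if (any(off))
    stopf("Ki67 percent off the reporting grid: %s (normalize_percent() first)",
          paste(utils::head(percent[off], 5), collapse = ", "))
  ifelse(is.na(percent), NA_character_,
         ifelse(percent <= 5, "low",
                ifelse(percent <= 20, "intermediate", "high")))
}

#' HER2 status from IHC score with ISH reflex for equivocal (2+) cases
#'
#' IHC 3+ is positive and 0/1+ negative outright; 2+ reflexes to in situ
#' hybridisation and is positive when the ISH ratio is >= 2.0 or the mean
#' ERBB2 copy number is >= 6.0 per cell, negative when the available ISH
#' criteria all fail, and missing when no ISH result exists. ISH values are
#' never consulted for non-2+ scores.
#'
#' @param ihc_score character vector in `{"0","1+","2+","3+"}` (NA = missing).
#' @param ish_ratio ISH ratio (>= 0) or NA.
#' @param ish_copies mean ERBB2 copies per cell (>= 0) or NA.
#' @return character: `"positive"`, `"negative"` or `NA` (missing).
#' @export
#' @examples
#' classify_her2("2+", ish_ratio = 2.0)              # positive
#' classify_her2("2+", ish_ratio = 1.5, ish_copies = 6)  # positive
classify_her2 <- function(ihc_score, ish_ratio = NA_real_, ish_copies = NA_real_) {
  n <- max(length(ihc_score), length(ish_ratio), length(ish_copies))
  ihc_score <- rep_len(as.character(ihc_score), n)
  ish_ratio <- rep_len(ish_ratio, n)
  ish_copies <- rep_len(ish_copies, n)
  known <- c("0", "1+", "2+", "3+")
  if (!all(is.na(ihc_score) | ihc_score %in% known))
    stopf("her2 IHC score must be one of %s", paste(known, collapse = ", "))
  if (any(!is.na(ish_ratio) & ish_ratio < 0) ||
      any(!is.na(ish_copies) & ish_copies < 0))
    stopf("ISH ratio/copy number cannot be negative")
  out <- rep(NA_character_, n)
  out[ihc_score %in% c("0", "1+")] <- "negative"
  out[ihc_score == "3+"] <- "positive"
  eq <- !is.na(ihc_score) & ihc_score == "2+"
  amp <- (!is.na(ish_ratio) & ish_ratio >= 2.0) |
         (!is.na(ish_copies) & ish_copies >= 6.0)
  has_ish <- !is.na(ish_ratio) | !is.na(ish_copies)
  out[eq & amp] <- "positive"
  out[eq & has_ish & !amp] <- "negative"
  out  # 2+ without ISH, or missing score, stays NA (missing)
}

#' Reference classification for every sample of a cohort
#'
#' Applies [normalize_percent()], [classify_hormone_receptor()],
#' [group_ki67()] and [classify_her2()] over the IHC columns of a cohort
#' table (`er_percent`, `pr_percent`, `ki67_percent`, `her2_ihc`,
#' `ish_ratio`, `ish_copies`).
#'
#' @param cohort data.frame with the IHC columns above.
#' @return data.frame: `sample_id`, `er`, `pr`, `her2` (positive/negative/NA),
#'   `ki67_group` (low/intermediate/high/NA), `ki67_binary`
#'   (`"le20"`/`"gt20"`/NA — the >20\% vs <=20\% dichotomy).
#' @export
classify_reference <- function(cohort) {
  need <- c("er_percent", "pr_percent", "ki67_percent", "her2_ihc")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stopf("cohort is missing column(s): %s", paste(miss, collapse = ", "))
  id <- cohort[["sample_id"]] %||% seq_len(nrow(cohort))
  kg <- group_ki67(normalize_percent(cohort$ki67_percent))
  data.frame(
    sample_id = id,
    er = classify_hormone_receptor(normalize_percent(cohort$er_percent)),
    pr = classify_hormone_receptor(normalize_percent(cohort$pr_percent)),
    her2 = classify_her2(cohort$her2_ihc,
                         cohort$ish_ratio %||% NA_real_,
                         cohort$ish_copies %||% NA_real_),
    ki67_group = kg,
    ki67_binary = ifelse(is.na(kg), NA_character_,
                         ifelse(kg == "high", "gt20", "le20")),
    stringsAsFactors = FALSE
  )
}
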
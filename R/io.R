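# Delimited-table IO and the end-to-end pipeline.

COHORT_NUMERIC <- c("ct_cyfip1", "ct_esr1", "ct_pgr", "ct_erbb2", "ct_mki67",
                    "er_percent", "pr_percent", "ki67_percent",
                    "ish_ratio", "ish_copies", "age", "followup_time")
COHORT_CHARACTER <- c("sample_id", "her2_ihc", "pt_category", "nodal",
                      "grade", "arm", "event_type")

#' Read and validate a cohort table
#'
#' Comma-separated, UTF-8, header row. Empty cells become declared missing
#' states (`NA`). Numeric columns are validated cell by cell; offending
#' cells are reported with their line number and column name. Unknown extra
#' columns are accepted with a warning (forward compatibility); a header
#' sharing no schema column aborts.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = c("", "NA"))
  known <- c(COHORT_NUMERIC, COHORT_CHARACTER)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warnf("ignoring unknown column(s): %s", paste(unknown, collapse = ", "))
  present <- intersect(known, names(raw))
  if (!length(present))
    stopf("no recognised cohort columns in header; expected some of: %s",
          paste(utils::head(known, 5), collapse = ", "))
  errors <- character(0)
  for (cl in intersect(COHORT_NUMERIC, names(raw))) {
    v <- raw[[cl]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      errors <- c(errors, sprintf("line %d, column %s: '%s' is not numeric",
                                  bad + 1L, cl, v[bad]))
    raw[[cl]] <- num
  }
  if (length(errors))
    stopf("cohort validation failed:\n%s",
          paste(utils::head(errors, 20), collapse = "\n"))
  raw
}

#' Pipeline configuration
#'
#' Defaults reproduce the study's analysis conventions without any
#' override.
#'
#' @param thresholds a [strat4_thresholds()] object.
#' @param conf.level confidence level for all intervals.
#' @param ties Cox tie handling.
#' @param targets performance targets.
#' @param seed RNG seed (used only by stages that simulate).
#' @param verbose emit progress messages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = strat4_thresholds(),
                            conf.level = 0.95, ties = "efron",
                            targets = performance_targets(),
                            seed = 1L, verbose = TRUE) {
  structure(list(thresholds = thresholds, conf.level = conf.level,
                 ties = ties, targets = targets, seed = seed,
                 verbose = verbose), class = "pipeline_config")
}

# Per-sample exclusion log for one marker, mirroring build_two_by_two().
exclusion_log <- function(calls, reference, marker) {
  marker <- match_marker(marker)
  df <- merge(calls, reference, by = "sample_id", sort = TRUE)
  status <- df[[paste0("status_", tolower(marker))]]
  reason <- rep(NA_character_, nrow(df))
  reason[status == "invalid"] <- "invalid"
  reason[is.na(reason) & status == "indeterminate"] <- "indeterminate"
  if (marker == "MKI67") {
    inter <- is.na(reason) & !is.na(df$ki67_group) & df$ki67_group == "intermediate"
    reason[inter] <- "intermediate_ki67"
    ref_missing <- is.na(df$ki67_group)
  } else {
    ref_missing <- is.na(df[[REF_OF[[marker]]]])
  }
  reason[is.na(reason) & ref_missing] <- "missing_reference"
  keep <- !is.na(reason)
  data.frame(sample_id = df$sample_id[keep],
             marker = rep(marker, sum(keep)),
             reason = reason[keep], stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a cohort table
#'
#' Stages, in order: delta-Ct classification; IHC/ISH reference
#' classification; per-marker concordance with performance-target gates;
#' time-to-distant-recurrence models and Kaplan-Meier coordinates (when
#' follow-up columns are present). Every excluded sample is logged with its
#' id and reason. Deterministic given inputs and config; output files use
#' fixed ordering and formatting.
#'
#' @param input cohort data.frame, or path to a CSV readable by
#'   [read_cohort()].
#' @param output_dir directory for the artifact bundle (created if needed);
#'   `NULL` writes nothing and just returns the results.
#' @param config a [pipeline_config()] object.
#' @return (invisibly) list: `calls`, `reference`, `concordance`, `gates`,
#'   `exclusion_log`, and, if follow-up data exist, `dr_models`, `km`.
#' @export
run_pipeline <- function(input, output_dir = NULL, config = pipeline_config()) {
  cohort <- if (is.character(input)) read_cohort(input) else input
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stopf("empty or invalid cohort input")
  say <- function(...) if (config$verbose) message(sprintf(...))

  say("classifying %d samples", nrow(cohort))
  calls <- classify_cohort(cohort, config$thresholds)
  reference <- classify_reference(cohort)
  fit <- concordance(calls, reference, conf.level = config$conf.level,
                     targets = config$targets)
  excl <- do.call(rbind, lapply(MARKERS, function(m)
    exclusion_log(calls, reference, m)))

  res <- list(calls = calls, reference = reference, concordance = fit,
              gates = fit$gates, exclusion_log = excl)

  has_fu <- all(c("followup_time", "event_type") %in% names(cohort)) &&
    any(!is.na(cohort$followup_time))
  if (has_fu) {
    say("fitting distant-recurrence models")
    res$dr_models <- run_dr_models(cohort, config$thresholds, config$ties)
    tt <- time_to_dr(cohort)
    res$km <- list(overall = km_curve(tt$duration, tt$event))
    for (m in MARKERS) {
      s <- calls[[paste0("status_", tolower(m))]]
      for (lv in c("positive", "negative")) {
        i <- s == lv
        if (sum(i) > 0)
          res$km[[paste0(tolower(m), "_", lv)]] <-
            km_curve(tt$duration[i], tt$event[i])
      }
    }
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) utils::write.csv(df, file.path(output_dir, name),
                                              row.names = FALSE)
    wr(calls, "calls.csv")
    wr(reference, "reference.csv")
    wr(as.data.frame(fit), "concordance.csv")
    wr(fit$gates, "gates.csv")
    wr(excl, "exclusions.csv")
    writeLines(sprintf("%s\t%s\t%s", excl$sample_id, excl$marker, excl$reason),
               file.path(output_dir, "exclusions.log"))
    if (has_fu) {
      uni <- do.call(rbind, lapply(names(res$dr_models$univariable), function(v) {
        f <- res$dr_models$univariable[[v]]
        data.frame(covariate = v, term = names(f$coefficients),
                   hr = f$hr, lower = f$lower, upper = f$upper,
                   p.value = f$p.value, stringsAsFactors = FALSE)
      }))
      if (!is.null(uni)) wr(uni, "survival_univariable.csv")
      km_df <- do.call(rbind, lapply(names(res$km), function(nm) {
        steps <- res$km[[nm]]$steps
        if (nrow(steps) == 0) return(NULL)
        cbind(stratum = nm, steps)
      }))
      if (!is.null(km_df)) wr(km_df, "km_coordinates.csv")
    }
    rpt <- file.path(output_dir, "report.txt")
    sink(rpt); on.exit(sink(), add = TRUE)
    print(fit)
    if (has_fu) print(res$dr_models)
    sink(); on.exit()
    say("artifacts written to %s", output_dir)
  }
  invisible(res)
}
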
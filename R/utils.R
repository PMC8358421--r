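# Internal helpers shared across modules.

#' Round half away from zero
#'
#' SAS-style rounding, used for all percent/kappa/HR rendering
#' (base::round() rounds half to even, which disagrees at e.g. 0.5).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Format a proportion as a percent string at 1 decimal, half-up.
fmt_pct <- function(p, digits = 1) {
  ifelse(is.na(p), "NA", formatC(round_half_up(100 * p, digits),
                                 format = "f", digits = digits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Marker vocabulary: mRNA target names and their protein reference columns.
MARKERS <- c("ESR1", "PGR", "ERBB2", "MKI67")
REF_OF  <- c(ESR1 = "er", PGR = "pr", ERBB2 = "her2", MKI67 = "ki67")

match_marker <- function(marker) {
  m <- toupper(marker)
  m[m == "MKI67"] <- "MKI67"
  if (!all(m %in% MARKERS))
    stopf("unknown marker '%s' (expected one of %s)",
          paste(setdiff(m, MARKERS), collapse = ", "),
          paste(MARKERS, collapse = ", "))
  m
}
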
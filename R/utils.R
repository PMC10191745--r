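#' admpreg: pregnancy cohorts and antidiabetic-medication utilisation from
#' insurance claims
#'
#' Reconstructs pregnancy episodes from DRG/TARMED delivery codes, imputes
#' gestational windows, classifies ATC A10 dispensation patterns into
#' pregestational continuer/switcher, GDM and discontinuer groups, and
#' reports per-10,000 prevalence with exact binomial confidence intervals.
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Presentation-layer rounding used for all reported rates and percentages:
#' ties round up (2.45 -> 2.5), unlike [base::round()]'s round-half-even.
#' Internal arithmetic is always carried at full precision; this is applied
#' only when a value is reported.
#'
#' @param x numeric vector (non-negative in all pipeline uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(2.45, 2.44, 85.25), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Deterministic sub-seed derivation: one user-facing seed fans out to
# independent streams per component, kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 2011L + (as.integer(stream) %% 1000L) * 7L
}

stop_admpreg <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "admpreg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

as_date_safe <- function(x) {
  suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
}

empty_df <- function(...) {
  cols <- list(...)
  structure(cols, class = "data.frame", row.names = integer(0))
}
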
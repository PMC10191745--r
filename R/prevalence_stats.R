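# Prevalence estimation: per-10,000 rates with exact binomial confidence
# intervals, percentage helpers, calendar-year stratification, and the
# cohort description table.

binom_ci <- function(x, n, conf = 0.95, method = "clopper-pearson") {
  alpha <- 1 - conf
  if (method == "clopper-pearson") {
    lo <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
    hi <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  } else { # wilson (score) interval, no continuity correction
    z <- stats::qnorm(1 - alpha / 2)
    p <- x / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- pmax(0, ctr - hw)
    hi <- pmin(1, ctr + hw)
  }
  cbind(lower = lo, upper = hi)
}

#' Per-10,000 prevalence with 95% confidence interval
#'
#' Prevalence is the number of exposed pregnancies divided by the number of
#' enrolled pregnancies, reported per 10,000 with an exact (Clopper-Pearson)
#' 95% binomial confidence interval on the same scale. Reported values are
#' rounded half-up to one decimal; internal arithmetic is exact.
#'
#' @param numerator,denominator counts, `denominator > 0`.
#' @param conf confidence level.
#' @param config a [code_config()]; `config$ci_method` selects
#'   Clopper-Pearson (default) or Wilson.
#' @param stratum label carried through to the output (year or "overall").
#' @return one-row data.frame: `stratum`, `numerator`, `denominator`,
#'   `rate_per_10k`, `percent`, `ci_low`, `ci_high` (per-10,000 scale).
#' @export
#' @examples
#' prevalence_per_10k(27, 10000)
prevalence_per_10k <- function(numerator, denominator, conf = 0.95,
                               config = code_config(), stratum = "overall") {
  if (any(denominator <= 0)) {
    stop_admpreg("prevalence undefined: denominator must be positive",
                 "admpreg_undefined_estimate")
  }
  if (any(numerator < 0 | numerator > denominator)) {
    stop_admpreg("numerator must lie in [0, denominator]",
                 "admpreg_contract_error")
  }
  ci <- binom_ci(numerator, denominator, conf, config$ci_method)
  out <- data.frame(
    stratum = as.character(stratum),
    numerator = numerator,
    denominator = denominator,
    rate_per_10k = round_half_up(10000 * numerator / denominator, 1),
    percent = round_half_up(100 * numerator / denominator, 1),
    ci_low = round_half_up(10000 * ci[, "lower"], 1),
    ci_high = round_half_up(10000 * ci[, "upper"], 1),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Percentage of a part in a whole, one decimal
#'
#' Presentation helper for ratio arithmetic on already-reported per-10,000
#' rates (e.g. 25.9/36.5 = 71.0%). Rounds half-up to one decimal.
#'
#' @param part,whole non-negative numerics, `whole > 0`.
#' @return percentage rounded to one decimal.
#' @export
#' @examples
#' proportion_pct(25.9, 36.5) # 71.0
proportion_pct <- function(part, whole) {
  if (any(whole <= 0)) {
    stop_admpreg("proportion_pct: whole must be positive",
                 "admpreg_contract_error")
  }
  if (any(part < 0)) {
    stop_admpreg("proportion_pct: part must be non-negative",
                 "admpreg_contract_error")
  }
  round_half_up(100 * part / whole, 1)
}

#' Prevalence of each utilisation group by calendar year
#'
#' Denominators are all deliveries in the year; numerators are episodes with
#' the group label. An `overall` stratum pools all years. Years with zero
#' deliveries are omitted.
#'
#' @param classification classification table from [classify_cohort()]
#'   (needs `delivery_year` and `group`).
#' @param years optional integer vector restricting/ordering the year strata;
#'   defaults to the years present.
#' @param groups group labels to tabulate (default: all observed).
#' @param config a [code_config()].
#' @return data.frame with one row per (stratum, group) and the
#'   [prevalence_per_10k()] columns.
#' @export
stratify_by_year <- function(classification, years = NULL, groups = NULL,
                             config = code_config()) {
  years <- years %||% sort(unique(classification$delivery_year))
  groups <- groups %||% sort(unique(classification$group))
  rows <- list()
  add <- function(stratum, sub) {
    den <- nrow(sub)
    if (den == 0) return()
    for (g in groups) {
      est <- prevalence_per_10k(sum(sub$group == g), den,
                                config = config, stratum = stratum)
      est$group <- g
      rows[[length(rows) + 1L]] <<- est
    }
  }
  for (y in years) {
    add(as.character(y),
        classification[classification$delivery_year == y, , drop = FALSE])
  }
  add("overall",
      classification[classification$delivery_year %in% years, , drop = FALSE])
  out <- do.call(rbind, rows)
  out[c("stratum", "group", "numerator", "denominator", "rate_per_10k",
        "percent", "ci_low", "ci_high")]
}

#' Cohort description table
#'
#' Deliveries, mean maternal age at delivery with range, and caesarean
#' section count and percentage, per calendar year and overall. Age columns
#' are omitted when no ages are available.
#'
#' @param episodes episode table from [build_episodes()].
#' @return data.frame with one row per year plus an `overall` row.
#' @export
cohort_summary <- function(episodes) {
  strata <- c(as.character(sort(unique(episodes$delivery_year))), "overall")
  have_age <- any(!is.na(episodes$maternal_age_at_delivery))
  rows <- lapply(strata, function(s) {
    sub <- if (s == "overall") episodes else
      episodes[episodes$delivery_year == as.integer(s), , drop = FALSE]
    n <- nrow(sub)
    row <- data.frame(stratum = s, n_deliveries = n,
                      stringsAsFactors = FALSE)
    if (have_age) {
      age <- sub$maternal_age_at_delivery
      age <- age[!is.na(age)]
      row$mean_age <- round_half_up(mean(age), 1)
      row$min_age <- round_half_up(min(age), 1)
      row$max_age <- round_half_up(max(age), 1)
    }
    row$caesarean_n <- sum(sub$caesarean)
    row$caesarean_pct <- proportion_pct(sum(sub$caesarean), n)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
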
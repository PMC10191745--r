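# Claims data model: the three raw record streams, the code-list
# configuration, delimited-text readers/writers, and ATC drug-class mapping.

ATC_GRAMMAR <- "^[A-Za-z][0-9]{2}([A-Za-z]([A-Za-z]([0-9]{2})?)?)?$|^[A-Za-z]$"

#' Validate ATC code syntax
#'
#' WHO ATC codes are hierarchical: anatomical letter (A), therapeutic level
#' (A10), pharmacological level (A10B), chemical level (A10BA), substance
#' level (A10BA02). Any truncation at a level boundary is a valid code.
#'
#' @param atc character vector of candidate codes.
#' @return logical vector.
#' @export
is_valid_atc <- function(atc) {
  !is.na(atc) & grepl(ATC_GRAMMAR, atc)
}

#' Code-list configuration
#'
#' Holds the billing-code lists that drive delivery identification and the
#' ATC prefix map that drives drug-class assignment. The shipped defaults are
#' synthetic placeholder codes (the real Swiss DRG/TARMED delivery code lists
#' are proprietary); real analyses supply their own lists via
#' [read_code_config()] or this constructor.
#'
#' @param delivery_codes data.frame with columns `code_system`
#'   (`"DRG"`/`"TARMED"`), `code`, `term_status`
#'   (`"full_term"`, `"preterm"`, `"unspecified"`).
#' @param caesarean_codes data.frame with `code_system`, `code`; must be a
#'   subset of delivery codes for caesarean flagging to apply.
#' @param termination_codes data.frame with `code_system`, `code`: codes for
#'   miscarriage or elective/medical termination. Pregnancies ending in these
#'   are excluded from the cohort.
#' @param fertility_atc character vector of ATC prefixes counted as fertility
#'   treatment for the comedication flag.
#' @param adm_class_map data.frame with `prefix`, `class`; longest matching
#'   prefix wins (so A10A beats A10). Default maps A10A to `insulin`, A10B to
#'   `blood_glucose_lowering`, and remaining A10 to `other_adm`.
#' @param cluster_rule `"anchor"` (default: codes join a cluster when within
#'   30 days of its first code) or `"chain"` (transitive 30-day chaining).
#' @param ignore_rule_codes `"drg_only"` (default; the 31--300-day ignore
#'   rule fires only on DRG codes, other late codes are merged with a
#'   diagnostic) or `"both"`.
#' @param cluster_window_days width of the same-pregnancy collapsing window.
#' @param separation_days minimum spacing between distinct deliveries.
#' @param pre_lmp_days,post_delivery_days continuous-enrollment requirement
#'   before the LMP and after delivery (both default 252 days = 9 months).
#' @param ci_method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @return an object of class `code_config`.
#' @export
code_config <- function(delivery_codes = default_delivery_codes(),
                        caesarean_codes = default_caesarean_codes(),
                        termination_codes = default_termination_codes(),
                        fertility_atc = c("G03GA", "G03GB", "H01CC", "L02AE"),
                        adm_class_map = default_adm_class_map(),
                        cluster_rule = c("anchor", "chain"),
                        ignore_rule_codes = c("drg_only", "both"),
                        cluster_window_days = 30L,
                        separation_days = 300L,
                        pre_lmp_days = 252L,
                        post_delivery_days = 252L,
                        ci_method = c("clopper-pearson", "wilson")) {
  cluster_rule <- match.arg(cluster_rule)
  ignore_rule_codes <- match.arg(ignore_rule_codes)
  ci_method <- match.arg(ci_method)
  if (!all(delivery_codes$term_status %in%
             c("full_term", "preterm", "unspecified"))) {
    stop_admpreg("delivery_codes$term_status must be full_term, preterm or unspecified",
                 "admpreg_config_error")
  }
  key <- function(df) paste(df$code_system, df$code)
  if (any(key(termination_codes) %in% key(delivery_codes))) {
    stop_admpreg("a code appears in both delivery_codes and termination_codes",
                 "admpreg_config_error")
  }
  if (!all(is_valid_atc(adm_class_map$prefix))) {
    stop_admpreg("adm_class_map contains a malformed ATC prefix",
                 "admpreg_config_error")
  }
  structure(list(
    delivery_codes = delivery_codes,
    caesarean_codes = caesarean_codes,
    termination_codes = termination_codes,
    fertility_atc = toupper(fertility_atc),
    adm_class_map = adm_class_map,
    cluster_rule = cluster_rule,
    ignore_rule_codes = ignore_rule_codes,
    cluster_window_days = as.integer(cluster_window_days),
    separation_days = as.integer(separation_days),
    pre_lmp_days = as.integer(pre_lmp_days),
    post_delivery_days = as.integer(post_delivery_days),
    ci_method = ci_method
  ), class = "code_config")
}

# Synthetic placeholder delivery codes; NOT the proprietary Swiss lists.
default_delivery_codes <- function() {
  data.frame(
    code_system = c("DRG", "DRG", "DRG", "DRG", "DRG", "TARMED", "TARMED"),
    code = c("O60A", "O60B", "O60C", "O01A", "O01C", "DEL01", "DELCS"),
    term_status = c("full_term", "unspecified", "preterm",
                    "full_term", "preterm", "unspecified", "unspecified"),
    stringsAsFactors = FALSE
  )
}

default_caesarean_codes <- function() {
  data.frame(code_system = c("DRG", "DRG", "TARMED"),
             code = c("O01A", "O01C", "DELCS"),
             stringsAsFactors = FALSE)
}

default_termination_codes <- function() {
  data.frame(code_system = c("DRG", "TARMED"),
             code = c("O40Z", "TERM1"),
             stringsAsFactors = FALSE)
}

default_adm_class_map <- function() {
  data.frame(prefix = c("A10A", "A10B", "A10"),
             class = c("insulin", "blood_glucose_lowering", "other_adm"),
             stringsAsFactors = FALSE)
}

#' Read or write a code-list configuration as YAML
#'
#' @param path file path.
#' @return `read_code_config()` returns a `code_config`;
#'   `write_code_config()` returns `path` invisibly.
#' @export
read_code_config <- function(path) {
  y <- yaml::read_yaml(path)
  to_df <- function(x) do.call(rbind.data.frame, c(x, stringsAsFactors = FALSE))
  args <- list()
  for (nm in c("delivery_codes", "caesarean_codes", "termination_codes",
               "adm_class_map")) {
    if (!is.null(y[[nm]])) args[[nm]] <- to_df(y[[nm]])
  }
  for (nm in c("fertility_atc", "cluster_rule", "ignore_rule_codes",
               "cluster_window_days", "separation_days", "pre_lmp_days",
               "post_delivery_days", "ci_method")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(code_config, args)
}

#' @rdname read_code_config
#' @param config a `code_config` object.
#' @export
write_code_config <- function(config, path) {
  df_to_rows <- function(df) unname(apply(df, 1, as.list))
  y <- list(
    delivery_codes = df_to_rows(config$delivery_codes),
    caesarean_codes = df_to_rows(config$caesarean_codes),
    termination_codes = df_to_rows(config$termination_codes),
    fertility_atc = config$fertility_atc,
    adm_class_map = df_to_rows(config$adm_class_map),
    cluster_rule = config$cluster_rule,
    ignore_rule_codes = config$ignore_rule_codes,
    cluster_window_days = config$cluster_window_days,
    separation_days = config$separation_days,
    pre_lmp_days = config$pre_lmp_days,
    post_delivery_days = config$post_delivery_days,
    ci_method = config$ci_method
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Map an ATC code to an antidiabetic drug class
#'
#' Case-insensitive longest-prefix match against the configured class map.
#' With the default map, insulins and analogues (A10A) map to `insulin`,
#' blood glucose-lowering drugs (A10B, oral agents plus non-insulin
#' injectables) to `blood_glucose_lowering`, any other A10 code to
#' `other_adm`, and everything outside A10 to `non_adm`.
#'
#' @param atc_code character vector of syntactically valid ATC codes.
#' @param config a [code_config()].
#' @return character vector of class labels, one per input code.
#' @export
#' @examples
#' cfg <- code_config()
#' classify_atc(c("A10AB05", "A10BA02", "C07AB02"), cfg)
classify_atc <- function(atc_code, config = code_config()) {
  atc <- toupper(atc_code)
  bad <- !is_valid_atc(atc)
  if (any(bad)) {
    stop_admpreg(sprintf("malformed ATC code(s): %s",
                         paste(unique(atc_code[bad]), collapse = ", ")),
                 "admpreg_validation_error")
  }
  map <- config$adm_class_map
  map <- map[order(-nchar(map$prefix)), , drop = FALSE]
  out <- rep("non_adm", length(atc))
  unmatched <- rep(TRUE, length(atc))
  for (i in seq_len(nrow(map))) {
    hit <- unmatched & startsWith(atc, toupper(map$prefix[i]))
    out[hit] <- map$class[i]
    unmatched[hit] <- FALSE
  }
  out
}

# ---- readers / writers -----------------------------------------------------

claims_schema <- list(
  services = c("person_id", "date", "code_system", "code"),
  dispensations = c("person_id", "date", "atc_code"),
  enrollment = c("person_id", "start", "end")
)

read_claims_table <- function(path, type) {
  cols <- claims_schema[[type]]
  if (!file.exists(path)) {
    stop_admpreg(sprintf("file not found: %s", path), "admpreg_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_admpreg(sprintf("%s table %s is missing required column(s): %s",
                         type, path, paste(missing, collapse = ", ")),
                 "admpreg_config_error")
  }
  df <- df[cols]
  diags <- empty_df(row = integer(0), problem = character(0))
  flag <- function(rows, what) {
    if (any(rows)) {
      w <- if (length(what) == 1L) rep(what, sum(rows)) else what[rows]
      diags <<- rbind(diags, data.frame(row = which(rows), problem = w))
    }
    rows
  }
  bad <- rep(FALSE, nrow(df))
  for (dc in intersect(c("date", "start", "end"), cols)) {
    parsed <- as_date_safe(df[[dc]])
    bad <- bad | flag(is.na(parsed) & !bad,
                      sprintf("unparseable %s '%s'", dc, df[[dc]]))
    df[[dc]] <- parsed
  }
  if (type == "services") {
    bad <- bad | flag(!df$code_system %in% c("DRG", "TARMED") & !bad,
                      sprintf("unknown code_system '%s'", df$code_system))
    bad <- bad | flag(!nzchar(df$code) & !bad, "empty code")
  }
  if (type == "dispensations") {
    bad <- bad | flag(!is_valid_atc(df$atc_code) & !bad,
                      sprintf("malformed atc_code '%s'", df$atc_code))
  }
  if (type == "enrollment" && nrow(df)) {
    bad <- bad | flag(!is.na(df$start) & !is.na(df$end) & df$start > df$end & !bad,
                      "start after end")
  }
  df <- df[!bad, , drop = FALSE]
  ord_col <- if (type == "enrollment") "start" else "date"
  df <- df[order(df$person_id, df[[ord_col]],
                 df[[cols[length(cols)]]]), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "diagnostics") <- diags
  df
}

#' Read the three claims tables
#'
#' Reads CSV tables of medical service records, outpatient dispensations, and
#' enrollment spans. Rows that fail validation (unparseable dates, unknown
#' code systems, malformed ATC codes) are dropped and reported row-numbered in
#' the `diagnostics` element rather than aborting the read; a missing required
#' column is a configuration error and aborts.
#'
#' @param services_path,dispensations_path,enrollment_path CSV file paths.
#'   Required columns: services `person_id,date,code_system,code`;
#'   dispensations `person_id,date,atc_code`; enrollment
#'   `person_id,start,end`. Dates ISO-8601.
#' @param config a [code_config()] (reserved for format options).
#' @return list with `services`, `dispensations`, `enrollment` data.frames
#'   (sorted by person and date) and a `diagnostics` data.frame with columns
#'   `table`, `row`, `problem`.
#' @export
read_claims <- function(services_path, dispensations_path, enrollment_path,
                        config = code_config()) {
  tabs <- list(
    services = read_claims_table(services_path, "services"),
    dispensations = read_claims_table(dispensations_path, "dispensations"),
    enrollment = read_claims_table(enrollment_path, "enrollment")
  )
  diags <- do.call(rbind, lapply(names(tabs), function(nm) {
    d <- attr(tabs[[nm]], "diagnostics")
    if (nrow(d)) cbind(table = nm, d) else NULL
  }))
  c(tabs, list(diagnostics = diags %||%
                 empty_df(table = character(0), row = integer(0),
                          problem = character(0))))
}

#' Write a claims table in canonical form
#'
#' Canonical column order, ISO-8601 dates, deterministic row order
#' (person, date, code). `read_claims()` after `write_claims()` is the
#' identity on canonicalised tables.
#'
#' @param records a services, dispensations, or enrollment data.frame.
#' @param path output CSV path.
#' @param type one of `"services"`, `"dispensations"`, `"enrollment"`;
#'   inferred from the columns when omitted.
#' @return `path`, invisibly.
#' @export
write_claims <- function(records, path, type = NULL) {
  if (is.null(type)) {
    type <- names(claims_schema)[vapply(
      claims_schema, function(cols) all(cols %in% names(records)), logical(1))]
    if (length(type) != 1) {
      stop_admpreg("cannot infer table type from columns; pass `type`",
                   "admpreg_config_error")
    }
  }
  cols <- claims_schema[[type]]
  df <- as.data.frame(records)[cols]
  for (dc in intersect(c("date", "start", "end"), cols)) {
    df[[dc]] <- format(as.Date(df[[dc]]), "%Y-%m-%d")
  }
  ord_col <- if (type == "enrollment") "start" else "date"
  df <- df[order(df$person_id, df[[ord_col]], df[[cols[length(cols)]]]), ,
           drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_admpreg(sprintf("cannot write %s: %s", path,
                         conditionMessage(ok)), "admpreg_io_error")
  }
  invisible(path)
}
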
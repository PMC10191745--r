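# Delivery identification: filter raw service records down to delivery codes,
# then collapse them into dated, term-classified delivery events under the
# 30-day same-pregnancy rule, DRG date priority, the 31-300-day
# ignore/relocation rule, and the 300-day separation requirement.

#' Extract delivery codes from service records
#'
#' Keeps only service records whose (code system, code) pair is a configured
#' delivery code, annotated with that code's term status. Termination and
#' miscarriage codes are returned separately (attribute
#' `"termination_records"`) so that affected delivery events can be excluded
#' downstream.
#'
#' @param services services data.frame (`person_id`, `date`, `code_system`,
#'   `code`), sorted by person and date.
#' @param config a [code_config()].
#' @return data.frame of raw delivery codes with a `term_status` column,
#'   carrying the termination records as an attribute.
#' @export
extract_delivery_codes <- function(services, config = code_config()) {
  dc <- config$delivery_codes
  key <- paste(services$code_system, services$code)
  idx <- match(key, paste(dc$code_system, dc$code))
  out <- services[!is.na(idx), c("person_id", "date", "code_system", "code"),
                  drop = FALSE]
  out$term_status <- dc$term_status[idx[!is.na(idx)]]
  rownames(out) <- NULL
  term <- services[key %in% paste(config$termination_codes$code_system,
                                  config$termination_codes$code), ,
                   drop = FALSE]
  rownames(term) <- NULL
  attr(out, "termination_records") <- term
  out
}

new_event <- function(members, config) {
  has_drg <- members$code_system == "DRG"
  date <- if (any(has_drg)) min(members$date[has_drg]) else min(members$date)
  term <- if (any(has_drg & members$term_status == "preterm")) {
    "preterm"
  } else {
    "full_term"
  }
  caes_key <- paste(config$caesarean_codes$code_system,
                    config$caesarean_codes$code)
  list(
    date = date,
    term_status = term,
    had_drg = any(has_drg),
    had_tarmed = any(!has_drg),
    caesarean = any(paste(members$code_system, members$code) %in% caes_key),
    members = members
  )
}

cluster_codes <- function(codes, window, rule) {
  n <- nrow(codes)
  id <- integer(n)
  cur <- 0L
  anchor <- ref <- as.Date(NA)
  for (i in seq_len(n)) {
    d <- codes$date[i]
    base <- if (rule == "anchor") anchor else ref
    if (cur == 0L || as.integer(d - base) > window) {
      cur <- cur + 1L
      anchor <- d
    }
    ref <- d
    id[i] <- cur
  }
  id
}

collapse_one_person <- function(codes, config) {
  window <- config$cluster_window_days
  sep <- config$separation_days
  ord <- order(codes$date, codes$code_system != "DRG", codes$code)
  if (any(diff(as.integer(codes$date)) < 0)) {
    stop_admpreg("delivery codes must be sorted by date within person",
                 "admpreg_contract_error")
  }
  codes <- codes[ord, , drop = FALSE]
  audit <- list()
  note <- function(members, rule, detail = "") {
    audit[[length(audit) + 1L]] <<- data.frame(
      person_id = members$person_id, date = members$date,
      code_system = members$code_system, code = members$code,
      rule = rule, detail = detail, stringsAsFactors = FALSE)
  }

  cl <- cluster_codes(codes, window, config$cluster_rule)
  events <- lapply(split(codes, cl), new_event, config = config)

  out <- list()
  cur <- events[[1]]
  for (k in seq_along(events)[-1]) {
    e <- events[[k]]
    gap <- as.integer(e$date - cur$date)
    if (gap > sep) {
      out[[length(out) + 1L]] <- cur
      cur <- e
      next
    }
    off <- as.integer(e$members$date - cur$date)
    is_drg <- e$members$code_system == "DRG"
    if (!cur$had_drg && any(is_drg)) {
      # TARMED-only event corrected by a later DRG: relocate the delivery
      # date to the DRG code and re-derive the term status.
      old <- cur$date
      cur <- new_event(rbind(cur$members, e$members), config)
      note(e$members[is_drg, , drop = FALSE],
           if (min(off[is_drg]) > window) "relocated_tarmed_to_drg"
           else "drg_priority",
           sprintf("event date moved %s -> %s", old, cur$date))
      next
    }
    # rule (c): DRG codes (window, sep] days after a DRG-dated delivery are
    # ignored; the same window applies to TARMED when configured
    ignorable <- is_drg & off > window & off <= sep
    if (config$ignore_rule_codes == "both") {
      ignorable <- off > window & off <= sep
    }
    if (any(ignorable)) {
      note(e$members[ignorable, , drop = FALSE], "ignored_drg_31_300",
           sprintf("within %d days of delivery %s", sep, cur$date))
    }
    if (all(ignorable)) next
    residual <- new_event(e$members[!ignorable, , drop = FALSE], config)
    if (as.integer(residual$date - cur$date) > sep) {
      # discarding re-dated the cluster beyond the separation threshold:
      # what remains is a distinct delivery
      out[[length(out) + 1L]] <- cur
      cur <- residual
    } else {
      # rule (d): a residual event closer than the separation threshold is
      # not a distinct delivery; merge into the earlier event
      note(residual$members, "merged_lt_separation",
           sprintf("merged into event %s", cur$date))
      cur <- new_event(rbind(cur$members, residual$members), config)
    }
  }
  out[[length(out) + 1L]] <- cur
  list(events = out, audit = audit)
}

#' Collapse raw delivery codes into delivery events
#'
#' Implements the delivery-date rules for one person: (a) codes within 30
#' days of a cluster's first code mark the same pregnancy; (b) the event date
#' is the earliest code date, or the earliest DRG date when an inpatient DRG
#' code is present (DRG priority); (c) a DRG code recorded 31--300 days after
#' an event that already has a DRG code is ignored, but when the event was
#' dated by a TARMED code alone, the event date is relocated to the DRG code
#' and the term status re-derived; (d) residual events closer than the
#' 300-day separation are merged into the earlier event with a diagnostic;
#' (e) an event is preterm iff any member DRG code maps to preterm
#' (unspecified counts as full term, as does a TARMED-only event).
#'
#' Every input code is either a member of exactly one returned event or
#' appears in the audit log with the rule that discarded it.
#'
#' @param codes raw delivery codes for a single person (see
#'   [extract_delivery_codes()]), sorted by date.
#' @param config a [code_config()].
#' @return data.frame of delivery events (`person_id`, `event_id`,
#'   `delivery_date`, `term_status`, `had_drg`, `had_tarmed`, `caesarean`,
#'   `n_codes`) with attributes `"members"` (code-to-event assignment) and
#'   `"audit"` (discarded/moved codes with rule identifiers).
#' @export
collapse_delivery_events <- function(codes, config = code_config()) {
  empty_audit <- empty_df(
    person_id = character(0), date = as.Date(character(0)),
    code_system = character(0), code = character(0),
    rule = character(0), detail = character(0))
  if (nrow(codes) == 0L) {
    out <- empty_df(
      person_id = character(0), event_id = character(0),
      delivery_date = as.Date(character(0)), term_status = character(0),
      had_drg = logical(0), had_tarmed = logical(0), caesarean = logical(0),
      n_codes = integer(0))
    attr(out, "members") <- empty_audit[c("person_id", "date", "code_system",
                                          "code")]
    attr(out, "audit") <- empty_audit
    return(out)
  }
  if (length(unique(codes$person_id)) > 1L) {
    stop_admpreg("collapse_delivery_events expects codes for one person",
                 "admpreg_contract_error")
  }
  res <- collapse_one_person(codes, config)
  person <- codes$person_id[1]
  events <- do.call(rbind, lapply(seq_along(res$events), function(i) {
    ev <- res$events[[i]]
    data.frame(person_id = person,
               event_id = sprintf("%s_e%02d", person, i),
               delivery_date = ev$date, term_status = ev$term_status,
               had_drg = ev$had_drg, had_tarmed = ev$had_tarmed,
               caesarean = ev$caesarean, n_codes = nrow(ev$members),
               stringsAsFactors = FALSE)
  }))
  members <- do.call(rbind, lapply(seq_along(res$events), function(i) {
    m <- res$events[[i]]$members
    m$event_id <- sprintf("%s_e%02d", person, i)
    m
  }))
  audit <- if (length(res$audit)) do.call(rbind, res$audit) else empty_audit
  attr(events, "members") <- members
  attr(events, "audit") <- audit
  events
}

#' Identify delivery events for all persons in a services table
#'
#' Applies [extract_delivery_codes()] and [collapse_delivery_events()] across
#' the whole services table, and excludes delivery events with a
#' termination/miscarriage code recorded within the same-pregnancy window of
#' the delivery date (the cohort follows completed deliveries only).
#'
#' @inheritParams extract_delivery_codes
#' @return list with `events` (all persons' delivery events), `audit`
#'   (discarded/moved/excluded codes), and `n_codes_in` (raw delivery codes
#'   seen, for row-count conservation checks).
#' @export
identify_deliveries <- function(services, config = code_config()) {
  codes <- extract_delivery_codes(services, config)
  term_rec <- attr(codes, "termination_records")
  codes <- codes[order(codes$person_id, codes$date), , drop = FALSE]

  # fast path: a person whose codes all lie within one collapsing window
  # forms exactly one event; only the rest needs the full rule machinery
  first <- !duplicated(codes$person_id)
  pgrp <- cumsum(first)
  spread <- stats::ave(as.numeric(codes$date), pgrp,
                       FUN = function(x) max(x) - min(x))
  simple <- spread <= config$cluster_window_days
  sc <- codes[simple, , drop = FALSE]
  events_fast <- NULL
  if (nrow(sc)) {
    g <- cumsum(!duplicated(sc$person_id))
    is_drg <- sc$code_system == "DRG"
    caes_key <- paste(config$caesarean_codes$code_system,
                      config$caesarean_codes$code)
    day <- as.numeric(sc$date)
    min_any <- tapply(day, g, min)
    min_drg <- tapply(ifelse(is_drg, day, Inf), g, min)
    had_drg <- is.finite(min_drg)
    preterm <- tapply(is_drg & sc$term_status == "preterm", g, any)
    events_fast <- data.frame(
      person_id = sc$person_id[!duplicated(sc$person_id)],
      event_id = paste0(sc$person_id[!duplicated(sc$person_id)], "_e01"),
      delivery_date = as.Date(ifelse(had_drg, min_drg, min_any),
                              origin = "1970-01-01"),
      term_status = ifelse(preterm, "preterm", "full_term"),
      had_drg = unname(had_drg),
      had_tarmed = unname(tapply(!is_drg, g, any)),
      caesarean = unname(tapply(paste(sc$code_system, sc$code) %in% caes_key,
                                g, any)),
      n_codes = unname(as.integer(table(g))),
      stringsAsFactors = FALSE)
  }
  hard <- codes[!simple, , drop = FALSE]
  pieces <- lapply(split(hard, hard$person_id, drop = TRUE),
                   collapse_delivery_events, config = config)
  events <- do.call(rbind, c(list(events_fast), unname(pieces)))
  audit <- do.call(rbind, lapply(pieces, attr, "audit"))
  if (is.null(events) || nrow(events) == 0L) {
    events <- collapse_delivery_events(
      codes[integer(0), , drop = FALSE], config)
    audit <- attr(events, "audit")
  }
  if (is.null(audit)) {
    audit <- attr(collapse_delivery_events(
      codes[integer(0), , drop = FALSE], config), "audit")
  }
  events <- events[order(events$person_id, events$delivery_date), ,
                   drop = FALSE]
  rownames(events) <- NULL
  # termination exclusion: a termination code within the collapsing window of
  # a delivery date marks that pregnancy as not ending in a delivery
  if (nrow(term_rec) && nrow(events)) {
    drop <- rep(FALSE, nrow(events))
    for (i in seq_len(nrow(events))) {
      tt <- term_rec[term_rec$person_id == events$person_id[i], , drop = FALSE]
      if (nrow(tt) && any(abs(as.integer(tt$date - events$delivery_date[i])) <=
                            config$cluster_window_days)) {
        drop[i] <- TRUE
      }
    }
    if (any(drop)) {
      ex <- events[drop, , drop = FALSE]
      audit <- rbind(audit, data.frame(
        person_id = ex$person_id, date = ex$delivery_date,
        code_system = "", code = "", rule = "termination_excluded",
        detail = "termination code within collapsing window of delivery",
        stringsAsFactors = FALSE))
      events <- events[!drop, , drop = FALSE]
      rownames(events) <- NULL
    }
  }
  rownames(audit) <- NULL
  list(events = events, audit = audit, n_codes_in = nrow(codes))
}
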
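# Pregnancy timing: impute the last menstrual period from the delivery date
# and term status, lay out the prepregnancy/T1/T2/T3 windows, and apply the
# continuous-enrollment filter.

#' Estimate the last menstrual period
#'
#' Claims data record neither gestational age nor the pregnancy start, so the
#' LMP is imputed from the delivery date: 270 days before delivery for
#' full-term pregnancies, 245 days for pregnancies with a preterm delivery
#' code.
#'
#' @param delivery_date Date vector.
#' @param term_status `"full_term"` or `"preterm"` (recycled).
#' @return Date vector of imputed LMPs.
#' @export
#' @examples
#' estimate_lmp(as.Date("2015-10-01"), "full_term") # 2015-01-04
#' estimate_lmp(as.Date("2015-10-01"), "preterm")   # 2015-01-29
estimate_lmp <- function(delivery_date, term_status) {
  if (!all(term_status %in% c("full_term", "preterm"))) {
    stop_admpreg("term_status must be 'full_term' or 'preterm'",
                 "admpreg_contract_error")
  }
  delivery_date - ifelse(term_status == "preterm", 245L, 270L)
}

#' Build pregnancy episodes from delivery events
#'
#' Lays out the four analysis windows around each delivery. The LMP is day 0
#' of pregnancy and all intervals are closed: T1 = days 0--89,
#' T2 = days 90--179, T3 = day 180 to delivery (day 269 full term, day 245
#' preterm), and the prepregnancy baseline covers the 252 days (9 months)
#' before the LMP. The windows tile `[LMP - 252, delivery]` with no gaps or
#' overlaps.
#'
#' @param events delivery events from [collapse_delivery_events()] /
#'   [identify_deliveries()].
#' @param birth_years optional data.frame (`person_id`, `birth_year`) used to
#'   derive maternal age at delivery.
#' @param config a [code_config()] (prepregnancy length).
#' @return data.frame with one row per episode: identifiers, delivery date,
#'   term status, `lmp`, window boundary columns
#'   (`prepregnancy_start/end`, `t1_start/end`, `t2_start/end`,
#'   `t3_start/end`), `delivery_year`, `caesarean`, and
#'   `maternal_age_at_delivery` (NA when no birth year is supplied). Episodes
#'   whose pregnancy window starts before the data period can be flagged
#'   downstream via `prepregnancy_start`.
#' @export
build_episodes <- function(events, birth_years = NULL,
                           config = code_config()) {
  lmp <- estimate_lmp(events$delivery_date, events$term_status)
  ep <- data.frame(
    person_id = events$person_id,
    episode_id = events$event_id,
    delivery_date = events$delivery_date,
    term_status = events$term_status,
    caesarean = events$caesarean,
    lmp = lmp,
    prepregnancy_start = lmp - config$pre_lmp_days,
    prepregnancy_end = lmp - 1L,
    t1_start = lmp,
    t1_end = lmp + 89L,
    t2_start = lmp + 90L,
    t2_end = lmp + 179L,
    t3_start = lmp + 180L,
    t3_end = events$delivery_date,
    delivery_year = as.integer(format(events$delivery_date, "%Y")),
    stringsAsFactors = FALSE
  )
  ep$maternal_age_at_delivery <- NA_real_
  if (!is.null(birth_years)) {
    m <- match(ep$person_id, birth_years$person_id)
    ep$maternal_age_at_delivery <- ep$delivery_year - birth_years$birth_year[m]
  }
  rownames(ep) <- NULL
  ep
}

#' @rdname build_episodes
#' @param event a single-row delivery event.
#' @param birth_year optional integer.
#' @export
build_episode <- function(event, birth_year = NULL,
                          config = code_config()) {
  by <- if (is.null(birth_year)) NULL else {
    data.frame(person_id = event$person_id, birth_year = birth_year)
  }
  build_episodes(event, by, config)
}

# merge overlapping/abutting enrollment spans for one person into disjoint
# intervals (abutting = next start <= current end + 1 day)
merge_spans <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (as.integer(start[i] - me) <= 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = as.Date(c(out_s, ms), origin = "1970-01-01"),
       end = as.Date(c(out_e, me), origin = "1970-01-01"))
}

#' Filter episodes on continuous enrollment
#'
#' An episode enters the cohort only when the person is continuously covered
#' from 9 months (252 days) before the imputed LMP to 9 months after the
#' delivery. Coverage is the union of the person's enrollment spans; spans
#' that abut (one ends the day before the next starts) count as continuous.
#'
#' @param episodes episode table from [build_episodes()].
#' @param spans enrollment data.frame (`person_id`, `start`, `end`), sorted
#'   per person.
#' @param config a [code_config()] (post-delivery requirement).
#' @return list with `kept` and `dropped` episode tables; `dropped` carries a
#'   `first_uncovered_day` diagnostic column.
#' @export
filter_continuous_enrollment <- function(episodes, spans,
                                         config = code_config()) {
  if (nrow(episodes) == 0L) {
    return(list(kept = episodes,
                dropped = cbind(episodes,
                                first_uncovered_day = as.Date(character(0)))))
  }
  span_by_person <- split(spans, spans$person_id, drop = TRUE)
  first_uncovered <- as.Date(rep(NA, nrow(episodes)))
  for (i in seq_len(nrow(episodes))) {
    w_start <- episodes$prepregnancy_start[i]
    w_end <- episodes$delivery_date[i] + config$post_delivery_days
    sp <- span_by_person[[episodes$person_id[i]]]
    if (is.null(sp) || nrow(sp) == 0L) {
      first_uncovered[i] <- w_start
      next
    }
    m <- merge_spans(sp$start, sp$end)
    day <- w_start
    for (j in seq_along(m$start)) {
      if (m$start[j] > day) break
      if (m$end[j] >= day) day <- m$end[j] + 1L
    }
    if (day <= w_end) first_uncovered[i] <- day
  }
  dropped <- episodes[!is.na(first_uncovered), , drop = FALSE]
  if (nrow(dropped)) {
    dropped$first_uncovered_day <- first_uncovered[!is.na(first_uncovered)]
  } else {
    dropped$first_uncovered_day <- as.Date(character(0))
  }
  kept <- episodes[is.na(first_uncovered), , drop = FALSE]
  rownames(kept) <- rownames(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}
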
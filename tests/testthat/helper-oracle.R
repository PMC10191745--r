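# Independent brute-force reference implementations used as oracles.
# These restate the delivery-collapsing and window-assignment rules directly,
# one code / one day at a time, independent of the package's vectorised and
# event-based code paths.

# Reference delivery collapsing: processes codes one at a time in date order
# (DRG before TARMED on ties), buffering an open 30-day cluster; when a code
# falls outside the open cluster, the buffered cluster is resolved against
# the current event by walking the rule list literally, code by code.
# Returns a data.frame comparable to collapse_delivery_events().
oracle_collapse <- function(codes, config = code_config()) {
  window <- config$cluster_window_days
  sep <- config$separation_days
  caes_key <- paste(config$caesarean_codes$code_system,
                    config$caesarean_codes$code)
  codes <- codes[order(codes$date, codes$code_system != "DRG", codes$code), ,
                 drop = FALSE]
  ev_date <- function(members) {
    drg <- members$code_system == "DRG"
    if (any(drg)) min(members$date[drg]) else min(members$date)
  }
  done <- list()
  current <- NULL   # members of the established delivery event
  buffer <- NULL    # members of the open 30-day cluster, not yet resolved

  resolve <- function() {
    # fold the buffered cluster into the event sequence per rules (b)-(e)
    if (is.null(current)) {
      current <<- buffer
      return(invisible())
    }
    cur_date <- ev_date(current)
    cl_date <- ev_date(buffer)
    if (as.integer(cl_date - cur_date) > sep) {
      done[[length(done) + 1L]] <<- current
      current <<- buffer
      return(invisible())
    }
    cur_has_drg <- any(current$code_system == "DRG")
    if (!cur_has_drg && any(buffer$code_system == "DRG")) {
      current <<- rbind(current, buffer) # relocation: date via ev_date
      return(invisible())
    }
    kept <- NULL
    for (i in seq_len(nrow(buffer))) {
      code <- buffer[i, , drop = FALSE]
      off <- as.integer(code$date - cur_date)
      drg_like <- code$code_system == "DRG" ||
        config$ignore_rule_codes == "both"
      if (cur_has_drg && drg_like && off > window && off <= sep) {
        next # ignored
      }
      kept <- rbind(kept, code)
    }
    if (is.null(kept)) return(invisible())
    if (as.integer(ev_date(kept) - cur_date) > sep) {
      done[[length(done) + 1L]] <<- current
      current <<- kept
    } else {
      current <<- rbind(current, kept)
    }
    invisible()
  }

  for (i in seq_len(nrow(codes))) {
    code <- codes[i, , drop = FALSE]
    if (is.null(buffer)) {
      buffer <- code
    } else if (as.integer(code$date - buffer$date[1]) <= window) {
      buffer <- rbind(buffer, code) # rule (a): same pregnancy
    } else {
      resolve()
      buffer <- code
    }
  }
  if (!is.null(buffer)) resolve()
  if (!is.null(current)) done[[length(done) + 1L]] <- current
  do.call(rbind, lapply(done, function(m) {
    drg <- m$code_system == "DRG"
    data.frame(
      person_id = m$person_id[1],
      delivery_date = ev_date(m),
      term_status = if (any(drg & m$term_status == "preterm")) "preterm"
      else "full_term",
      had_drg = any(drg),
      had_tarmed = any(!drg),
      caesarean = any(paste(m$code_system, m$code) %in% caes_key),
      n_codes = nrow(m),
      stringsAsFactors = FALSE)
  }))
}

# Brute-force set-membership delivery-code filter.
oracle_extract <- function(services, config = code_config()) {
  keep <- logical(nrow(services))
  for (i in seq_len(nrow(services))) {
    dc <- config$delivery_codes
    keep[i] <- any(dc$code_system == services$code_system[i] &
                     dc$code == services$code[i])
  }
  services[keep, , drop = FALSE]
}

# Day-by-day window assignment for a dispensation date within one episode.
oracle_window <- function(date, episode) {
  all_days <- seq(episode$prepregnancy_start, episode$delivery_date, by = 1)
  if (!date %in% all_days) return(NA_character_)
  for (w in list(c("prepregnancy_start", "prepregnancy_end", "prepregnancy"),
                 c("t1_start", "t1_end", "t1"),
                 c("t2_start", "t2_end", "t2"),
                 c("t3_start", "t3_end", "t3"))) {
    if (date %in% seq(episode[[w[1]]], episode[[w[2]]], by = 1)) return(w[3])
  }
  NA_character_
}

# Random raw delivery-code streams exercising duplicate, stray, relocation
# and boundary-spacing patterns for the oracle-equivalence suite.
random_code_stream <- function(person = "px", config = code_config()) {
  drg_codes <- config$delivery_codes[config$delivery_codes$code_system ==
                                       "DRG", ]
  tar_codes <- config$delivery_codes[config$delivery_codes$code_system ==
                                       "TARMED", ]
  n <- sample(1:8, 1)
  gaps <- sample(c(0:40, 95:105, 140:160, 290:310, 400:450), n,
                 replace = TRUE)
  dates <- as.Date("2013-06-01") + cumsum(gaps)
  is_drg <- runif(n) < 0.6
  data.frame(
    person_id = person,
    date = dates,
    code_system = ifelse(is_drg, "DRG", "TARMED"),
    code = ifelse(is_drg,
                  sample(drg_codes$code, n, replace = TRUE),
                  sample(tar_codes$code, n, replace = TRUE)),
    stringsAsFactors = FALSE)
}
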
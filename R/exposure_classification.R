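# Exposure classification: per-window antidiabetic-medication profiles,
# utilisation-group assignment (pregestational continuer/switcher, GDM,
# discontinuer), and the fertility-comedication flag.

WINDOWS <- c("prepregnancy", "t1", "t2", "t3")

GROUP_LABELS <- c("pregestational_continuer", "pregestational_switcher",
                  "gdm", "discontinuer", "t1_only", "unexposed")

# window membership for dispensation dates relative to one episode row;
# returns a factor-like character vector, NA when outside all windows
window_of <- function(dates, episode) {
  out <- rep(NA_character_, length(dates))
  out[dates >= episode$prepregnancy_start &
        dates <= episode$prepregnancy_end] <- "prepregnancy"
  out[dates >= episode$t1_start & dates <= episode$t1_end] <- "t1"
  out[dates >= episode$t2_start & dates <= episode$t2_end] <- "t2"
  out[dates >= episode$t3_start & dates <= episode$t3_end] <- "t3"
  out
}

#' Build the ADM exposure profile of one pregnancy episode
#'
#' Exposure is at least one outpatient dispensation of an antidiabetic
#' medication (ATC A10) during a window of interest. A dispensation
#' contributes to the window containing its date (closed intervals; a
#' dispensation on the delivery date counts toward T3); dispensations after
#' the delivery date and non-ADM codes are ignored.
#'
#' @param episode single-row episode (see [build_episodes()]).
#' @param dispensations dispensation records of the episode's person.
#' @param config a [code_config()].
#' @return an object of class `exposure_profile`: per-window character
#'   vectors of ADM class labels (`classes`) and of dispensed ATC substances
#'   (`substances`), plus flags `exposed_prepregnancy`, `exposed_t2_or_later`
#'   and `first_exposure_window`.
#' @export
build_exposure_profile <- function(episode, dispensations,
                                   config = code_config()) {
  stopifnot(length(episode$person_id) == 1L)
  d <- dispensations[dispensations$person_id == episode$person_id, ,
                     drop = FALSE]
  d <- d[d$date <= episode$delivery_date, , drop = FALSE]
  win <- if (nrow(d)) window_of(d$date, episode) else character(0)
  cls <- if (nrow(d)) {
    d$adm_class %||% classify_atc(d$atc_code, config)
  } else {
    character(0)
  }
  keep <- !is.na(win) & cls != "non_adm"
  d <- d[keep, , drop = FALSE]
  win <- win[keep]; cls <- cls[keep]
  classes <- lapply(WINDOWS, function(w) sort(unique(cls[win == w])))
  substances <- lapply(WINDOWS, function(w) {
    sort(unique(toupper(d$atc_code[win == w])))
  })
  names(classes) <- names(substances) <- WINDOWS
  n_by_win <- vapply(classes, length, integer(1))
  first <- if (any(n_by_win > 0)) WINDOWS[which(n_by_win > 0)[1]] else NA_character_
  structure(list(
    episode_id = episode$episode_id,
    person_id = episode$person_id,
    classes = classes,
    substances = substances,
    exposed_prepregnancy = n_by_win[["prepregnancy"]] > 0,
    exposed_t2_or_later = n_by_win[["t2"]] > 0 || n_by_win[["t3"]] > 0,
    first_exposure_window = first
  ), class = "exposure_profile")
}

#' Assign a pregnancy to an ADM utilisation group
#'
#' The three principal utilisation groups are: pregestational diabetes
#' (dispensation in the prepregnancy period and in or after T2), GDM (first
#' dispensation in or after T2), and discontinuers (prepregnancy dispensation
#' with none in or after T2). Pregestational episodes are subdivided into
#' continuers (some ADM class dispensed both before pregnancy and in/after
#' T2) and switchers (disjoint class sets). Episodes outside these
#' definitions are `unexposed` (no ADM at all) or `t1_only` (exposure
#' beginning in T1 without prepregnancy exposure; subtype `t1_first` when
#' exposure continues in or after T2).
#'
#' @param profile an [build_exposure_profile()] result.
#' @return character group label with attribute `subtype` for `t1_only`.
#' @export
assign_group <- function(profile) {
  pre <- profile$classes$prepregnancy
  post <- union(profile$classes$t2, profile$classes$t3)
  t1 <- profile$classes$t1
  if (length(pre) == 0 && length(t1) == 0 && length(post) == 0) {
    return("unexposed")
  }
  if (length(pre) > 0 && length(post) == 0) {
    return("discontinuer")
  }
  if (length(pre) > 0) {
    return(if (length(intersect(pre, post)) > 0) "pregestational_continuer"
           else "pregestational_switcher")
  }
  if (length(t1) == 0) {
    return("gdm")
  }
  structure("t1_only",
            subtype = if (length(post) > 0) "t1_first" else "t1_exclusive")
}

#' Flag fertility-treatment comedication in the prepregnancy period
#'
#' @param profile an `exposure_profile` (window boundaries come from its
#'   episode, passed as `episode`).
#' @param episode the single-row episode the profile belongs to.
#' @param dispensations dispensation records of the person (all codes, not
#'   only ADM).
#' @param config a [code_config()] with a non-empty `fertility_atc`.
#' @return TRUE iff any prepregnancy-window dispensation matches a configured
#'   fertility-treatment ATC prefix.
#' @export
flag_fertility_comedication <- function(profile, episode, dispensations,
                                        config = code_config()) {
  if (length(config$fertility_atc) == 0) {
    stop_admpreg("config$fertility_atc is empty", "admpreg_config_error")
  }
  d <- dispensations[dispensations$person_id == profile$person_id, ,
                     drop = FALSE]
  d <- d[d$date >= episode$prepregnancy_start &
           d$date <= episode$prepregnancy_end, , drop = FALSE]
  if (nrow(d) == 0L) return(FALSE)
  atc <- toupper(d$atc_code)
  any(vapply(config$fertility_atc,
             function(p) any(startsWith(atc, p)), logical(1)))
}

#' Classify all episodes of a cohort
#'
#' Vectorised driver over [build_exposure_profile()] / [assign_group()] /
#' [flag_fertility_comedication()]: one row per episode with per-window class
#' sets (comma-joined), the group label, subtype, and the fertility flag.
#'
#' @param episodes episode table.
#' @param dispensations full dispensation table.
#' @param config a [code_config()].
#' @return list with `classification` data.frame and `profiles` (list of
#'   `exposure_profile` objects, named by episode id).
#' @export
classify_cohort <- function(episodes, dispensations,
                            config = code_config()) {
  n <- nrow(episodes)
  # pre-classify all dispensations once; per-episode work is then cheap
  disp <- dispensations
  disp$adm_class <- if (nrow(disp)) classify_atc(disp$atc_code, config) else
    character(0)
  disp_by_person <- split(disp, disp$person_id, drop = TRUE)
  none <- disp[integer(0), , drop = FALSE]
  ep_cols <- lapply(episodes, identity)
  profiles <- vector("list", n)
  group <- subtype <- character(n)
  win_str <- matrix("", n, 4)
  fert <- logical(n)
  for (i in seq_len(n)) {
    ep <- lapply(ep_cols, `[`, i)
    d <- disp_by_person[[ep$person_id]] %||% none
    pr <- build_exposure_profile(ep, d, config)
    g <- assign_group(pr)
    profiles[[i]] <- pr
    group[i] <- as.character(g)
    subtype[i] <- attr(g, "subtype") %||% NA_character_
    win_str[i, ] <- vapply(pr$classes, paste, character(1), collapse = ",")
    fert[i] <- flag_fertility_comedication(pr, ep, d, config)
  }
  classification <- data.frame(
    episode_id = episodes$episode_id %||% character(0),
    person_id = episodes$person_id %||% character(0),
    delivery_year = episodes$delivery_year %||% integer(0),
    group = group, subtype = subtype,
    pre_classes = win_str[, 1], t1_classes = win_str[, 2],
    t2_classes = win_str[, 3], t3_classes = win_str[, 4],
    fertility_comedication = fert,
    stringsAsFactors = FALSE)
  names(profiles) <- classification$episode_id
  rownames(classification) <- NULL
  list(classification = classification, profiles = profiles)
}

#' Substance distribution within a group and window
#'
#' For each 7-character ATC substance dispensed in `window` by episodes of
#' `group`, the share is the number of episodes with that substance divided
#' by the number of episodes in the group with any substance of the same ADM
#' class in that window, as a percentage (1 decimal).
#'
#' @param profiles list of `exposure_profile` objects (e.g. from
#'   [classify_cohort()]).
#' @param groups character vector of group labels parallel to `profiles`.
#' @param group the group to tabulate.
#' @param window one of `"prepregnancy"`, `"t1"`, `"t2"`, `"t3"`.
#' @param config a [code_config()].
#' @return data.frame (`substance`, `class`, `n`, `share_pct`); empty (zero
#'   rows) for an empty group.
#' @export
substance_distribution <- function(profiles, groups, group,
                                   window = "prepregnancy",
                                   config = code_config()) {
  stopifnot(window %in% WINDOWS)
  sel <- profiles[groups == group]
  empty <- empty_df(substance = character(0), class = character(0),
                    n = integer(0), share_pct = numeric(0))
  if (length(sel) == 0) return(empty)
  subs_by_ep <- lapply(sel, function(p) p$substances[[window]])
  all_subs <- sort(unique(unlist(subs_by_ep)))
  if (length(all_subs) == 0) return(empty)
  sub_class <- classify_atc(all_subs, config)
  # denominator: episodes with any substance of the same class in the window
  ep_has_class <- function(cl) {
    sum(vapply(subs_by_ep, function(s) {
      length(s) > 0 && any(classify_atc(s, config) == cl)
    }, logical(1)))
  }
  denom <- vapply(unique(sub_class), ep_has_class, numeric(1))
  n <- vapply(all_subs, function(s) {
    sum(vapply(subs_by_ep, function(x) s %in% x, logical(1)))
  }, numeric(1))
  data.frame(
    substance = all_subs,
    class = sub_class,
    n = as.integer(n),
    share_pct = round_half_up(100 * n / denom[sub_class], 1),
    row.names = NULL, stringsAsFactors = FALSE)
}
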
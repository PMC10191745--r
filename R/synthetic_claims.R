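# Seeded synthetic-claims generator with ground truth. Emulates the
# structure of the real (proprietary) claims streams: women with one or more
# deliveries >=300 days apart recorded through DRG/TARMED codes, enrollment
# spans covering the observation window, and ADM dispensations placed in the
# prepregnancy/T1/T2/T3 windows according to configurable group prevalences
# and drug-class mixes. All code values are synthetic placeholders.

#' Simulation configuration
#'
#' Default group prevalences, class mixes and substance mixes reproduce the
#' utilisation patterns reported for the Swiss claims cohort the pipeline is
#' designed for: pregestational diabetes 25.9/10,000 deliveries (85.3%
#' continuers), pharmacologically treated GDM 257.7/10,000, discontinuers
#' 10.7/10,000, caesarean rate 31.9%, mean maternal age 31.7. Noise rates
#' default to zero; turn them on (or call [inject_pathologies()]) to exercise
#' the duplicate-code, stray-DRG, TARMED-relocation and enrollment-gap rules.
#'
#' @param seed mandatory integer seed; the single source of randomness.
#' @param n_women number of women to simulate.
#' @param years two-element integer vector: first and last delivery year.
#' @param parity_probs named numeric: probability of 1, 2, ... deliveries.
#' @param preterm_prob probability a delivery is preterm.
#' @param caesarean_prob probability a delivery is a caesarean section.
#' @param mean_age,sd_age maternal age at first delivery (years).
#' @param group_prev_per_10k named numeric: expected episodes per 10,000
#'   deliveries in groups `pregestational`, `gdm`, `discontinuer`,
#'   `t1_only`; the remainder is unexposed. Must sum to <= 10,000.
#' @param continuer_share P(continuer | pregestational).
#' @param continuer_class_mix,gdm_class_mix,discontinuer_class_mix named
#'   numeric over `insulin_only`, `bgld_only`, `both` (normalised).
#' @param insulin_substances,bgld_substances named numeric weights over
#'   7-character ATC codes.
#' @param fertility_prob_bgld_discontinuer probability a
#'   blood-glucose-lowering discontinuer has a fertility-treatment
#'   dispensation in the prepregnancy window.
#' @param refill_days days between successive dispensations in a window.
#' @param noise list of rates: `duplicate_code` (extra delivery code within
#'   30 days), `stray_drg` (DRG code 31--300 days after a delivery),
#'   `tarmed_only` (delivery recorded by TARMED alone), `relocation`
#'   (TARMED-dated delivery later corrected by its DRG code),
#'   `enrollment_gap` (coverage gap inside the observation window).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_women = 1000L,
                       years = c(2012L, 2019L),
                       parity_probs = c(`1` = 0.78, `2` = 0.20, `3` = 0.02),
                       preterm_prob = 0.07,
                       caesarean_prob = 0.319,
                       mean_age = 31.7, sd_age = 4.5,
                       group_prev_per_10k = c(pregestational = 25.9,
                                              gdm = 257.7,
                                              discontinuer = 10.7,
                                              t1_only = 5),
                       continuer_share = 0.853,
                       continuer_class_mix = c(insulin_only = 0.882,
                                               bgld_only = 0.052,
                                               both = 0.065),
                       gdm_class_mix = c(insulin_only = 0.988,
                                         bgld_only = 0.010,
                                         both = 0.002),
                       discontinuer_class_mix = c(insulin_only = 0.233,
                                                  bgld_only = 0.757,
                                                  both = 0.010),
                       insulin_substances = c(A10AB05 = 0.423,
                                              A10AB04 = 0.209,
                                              A10AB01 = 0.150,
                                              A10AE05 = 0.120,
                                              A10AE04 = 0.098),
                       bgld_substances = c(A10BA02 = 0.661,
                                           A10BJ02 = 0.210,
                                           A10BK01 = 0.081,
                                           A10BH01 = 0.048),
                       fertility_prob_bgld_discontinuer = 0.321,
                       refill_days = 45L,
                       noise = list()) {
  if (missing(seed) || is.null(seed)) {
    stop_admpreg("sim_config: seed is mandatory", "admpreg_config_error")
  }
  noise_defaults <- list(duplicate_code = 0, stray_drg = 0, tarmed_only = 0,
                         relocation = 0, enrollment_gap = 0)
  noise <- utils::modifyList(noise_defaults, noise)
  probs <- c(preterm_prob, caesarean_prob, continuer_share,
             unlist(noise), parity_probs)
  if (any(probs < 0 | probs > 1)) {
    stop_admpreg("sim_config: probabilities must lie in [0, 1]",
                 "admpreg_config_error")
  }
  if (sum(group_prev_per_10k) > 10000) {
    stop_admpreg("sim_config: group prevalences exceed 10,000 per 10,000",
                 "admpreg_config_error")
  }
  max_parity <- max(as.integer(names(parity_probs)[parity_probs > 0]))
  total_days <- as.integer(as.Date(sprintf("%d-12-31", years[2])) -
                             as.Date(sprintf("%d-01-01", years[1])))
  if ((max_parity - 1L) * 530L >= total_days) {
    stop_admpreg(sprintf(
      "sim_config infeasible: parity %d needs %d days of delivery spacing but the year range %d-%d spans only %d days",
      max_parity, (max_parity - 1L) * 530L, years[1], years[2], total_days),
      "admpreg_generation_error")
  }
  structure(list(
    seed = as.integer(seed), n_women = as.integer(n_women),
    years = as.integer(years), parity_probs = parity_probs / sum(parity_probs),
    preterm_prob = preterm_prob, caesarean_prob = caesarean_prob,
    mean_age = mean_age, sd_age = sd_age,
    group_prev_per_10k = group_prev_per_10k,
    continuer_share = continuer_share,
    continuer_class_mix = continuer_class_mix / sum(continuer_class_mix),
    gdm_class_mix = gdm_class_mix / sum(gdm_class_mix),
    discontinuer_class_mix = discontinuer_class_mix /
      sum(discontinuer_class_mix),
    insulin_substances = insulin_substances / sum(insulin_substances),
    bgld_substances = bgld_substances / sum(bgld_substances),
    fertility_prob_bgld_discontinuer = fertility_prob_bgld_discontinuer,
    refill_days = as.integer(refill_days),
    noise = noise
  ), class = "sim_config")
}

# uniform integer days in [a, b], vectorised over a/b
draw_days <- function(a, b, n = length(a)) {
  a + floor(stats::runif(n) * (as.numeric(b - a) + 1))
}

sample_mix <- function(n, mix) {
  if (n == 0L) return(character(0))
  sample(names(mix), n, replace = TRUE, prob = mix)
}

#' Generate a synthetic claims cohort with ground truth
#'
#' Deterministic given `config$seed`. Deliveries of one woman are at least
#' 400 days apart; dispensations are drawn strictly inside their intended
#' window with a one-day margin from every boundary, so the ground-truth
#' window assignment is unambiguous. When any noise rate is positive,
#' [inject_pathologies()] is applied before returning.
#'
#' @param config a [sim_config()].
#' @return list with the three claims tables (`services`, `dispensations`,
#'   `enrollment`), `birth_years`, the ground-truth episode table `truth`
#'   (true delivery date, term status, LMP, group, per-window class sets,
#'   fertility flag, and expected pipeline behaviour for injected
#'   pathologies), and `injections` (one row per injected noise event).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_women
  person_id <- sprintf("W%06d", seq_len(n))
  parity <- as.integer(sample_mix(n, config$parity_probs))
  first_start <- as.Date(sprintf("%d-01-01", config$years[1]))
  last_end <- as.Date(sprintf("%d-12-31", config$years[2]))

  # delivery dates: first uniform in the study years, subsequent +530..780
  # days so that successive pregnancies' observation windows never overlap
  # (252-day prepregnancy + 270-day gestation = 522 days); deliveries that
  # would fall beyond the study window are dropped
  pid <- rep(person_id, parity)
  ord_in_woman <- unlist(lapply(parity, seq_len))
  d1 <- draw_days(rep(first_start, n), rep(last_end, n))
  n_gap <- max(1L, max(parity) - 1L)
  gaps <- matrix(530L + floor(stats::runif(n * n_gap) * 251), nrow = n)
  woman_idx <- rep(seq_len(n), parity)
  dd <- d1[woman_idx]
  extra <- which(ord_in_woman > 1L)
  for (k in extra) {
    dd[k] <- dd[k] + sum(gaps[woman_idx[k], seq_len(ord_in_woman[k] - 1L)])
  }
  keep <- dd <= last_end
  pid <- pid[keep]; dd <- dd[keep]
  m <- length(pid)

  ages <- pmin(pmax(stats::rnorm(n, config$mean_age, config$sd_age), 16), 50)
  birth_years <- data.frame(
    person_id = person_id,
    birth_year = as.integer(format(d1, "%Y")) - round(ages),
    stringsAsFactors = FALSE)

  preterm <- stats::runif(m) < config$preterm_prob
  caesarean <- stats::runif(m) < config$caesarean_prob
  tarmed_only <- stats::runif(m) < config$noise$tarmed_only
  # a TARMED-only delivery carries no term information; the imputation
  # defaults to full term, so the generator makes that the truth
  preterm[tarmed_only] <- FALSE
  term <- ifelse(preterm, "preterm", "full_term")

  grp_probs <- c(config$group_prev_per_10k / 10000,
                 unexposed = 1 - sum(config$group_prev_per_10k) / 10000)
  group <- sample_mix(m, grp_probs)
  subtype <- rep(NA_character_, m)
  is_pg <- group == "pregestational"
  subtype[is_pg] <- ifelse(stats::runif(sum(is_pg)) < config$continuer_share,
                           "continuer", "switcher")
  group[is_pg] <- paste0("pregestational_", subtype[is_pg])

  lmp <- estimate_lmp(dd, term)
  pp_start <- lmp - 252L

  # per-episode class exposure flags
  pre_ins <- pre_bgld <- t1_ins <- t1_bgld <- post_ins <- post_bgld <-
    rep(FALSE, m)
  pick_mix <- function(idx, mix) {
    cm <- sample_mix(length(idx), mix)
    list(ins = cm %in% c("insulin_only", "both"),
         bgld = cm %in% c("bgld_only", "both"))
  }
  ic <- which(group == "pregestational_continuer")
  cm <- pick_mix(ic, config$continuer_class_mix)
  pre_ins[ic] <- cm$ins; pre_bgld[ic] <- cm$bgld
  # continuers keep an overlapping class in or after T2; mixed prepregnancy
  # regimens continue on insulin
  post_ins[ic] <- cm$ins
  post_bgld[ic] <- cm$bgld & !cm$ins
  isw <- which(group == "pregestational_switcher")
  pre_bgld[isw] <- TRUE
  post_ins[isw] <- TRUE
  ig <- which(group == "gdm")
  cm <- pick_mix(ig, config$gdm_class_mix)
  post_ins[ig] <- cm$ins; post_bgld[ig] <- cm$bgld
  idc <- which(group == "discontinuer")
  cm <- pick_mix(idc, config$discontinuer_class_mix)
  pre_ins[idc] <- cm$ins; pre_bgld[idc] <- cm$bgld
  it1 <- which(group == "t1_only")
  t1_ins[it1] <- stats::runif(length(it1)) < 0.5
  t1_bgld[it1] <- !t1_ins[it1]

  sub_ins <- sample_mix(m, config$insulin_substances)
  sub_bgld <- sample_mix(m, config$bgld_substances)
  fert <- rep(FALSE, m)
  fert[idc] <- pre_bgld[idc] &
    stats::runif(length(idc)) < config$fertility_prob_bgld_discontinuer

  # dispensations: first fill uniform inside the window with 1-day margins,
  # refill refill_days later when it still fits
  disp <- list()
  add_disp <- function(idx, a, b, atc) {
    if (!length(idx)) return()
    first <- draw_days(a, b)
    refill <- first + config$refill_days
    ok <- refill <= b
    disp[[length(disp) + 1L]] <<- data.frame(
      person_id = c(pid[idx], pid[idx][ok]),
      date = c(first, refill[ok]),
      atc_code = c(atc, atc[ok]), stringsAsFactors = FALSE)
  }
  w <- which(pre_ins)
  add_disp(w, pp_start[w] + 1L, lmp[w] - 2L, sub_ins[w])
  w <- which(pre_bgld)
  add_disp(w, pp_start[w] + 1L, lmp[w] - 2L, sub_bgld[w])
  w <- which(t1_ins)
  add_disp(w, lmp[w] + 1L, lmp[w] + 88L, sub_ins[w])
  w <- which(t1_bgld)
  add_disp(w, lmp[w] + 1L, lmp[w] + 88L, sub_bgld[w])
  w <- which(post_ins)
  add_disp(w, lmp[w] + 91L, dd[w] - 1L, sub_ins[w])
  w <- which(post_bgld)
  add_disp(w, lmp[w] + 91L, dd[w] - 1L, sub_bgld[w])
  w <- which(fert)
  add_disp(w, pp_start[w] + 1L, lmp[w] - 2L, rep("G03GA01", length(w)))
  # non-ADM background dispensations
  n_bg <- max(1L, round(m * 0.3))
  bg_idx <- sample.int(m, n_bg, replace = TRUE)
  disp[[length(disp) + 1L]] <- data.frame(
    person_id = pid[bg_idx],
    date = draw_days(pp_start[bg_idx], dd[bg_idx]),
    atc_code = sample(c("C07AB02", "N02BE01", "J01CA04"), n_bg,
                      replace = TRUE),
    stringsAsFactors = FALSE)
  dispensations <- do.call(rbind, disp)

  # delivery service codes
  drg_code <- ifelse(caesarean, ifelse(preterm, "O01C", "O01A"),
                     ifelse(preterm, "O60C", "O60A"))
  tarmed_code <- ifelse(caesarean, "DELCS", "DEL01")
  sv <- list(data.frame(
    person_id = pid[!tarmed_only], date = dd[!tarmed_only],
    code_system = "DRG", code = drg_code[!tarmed_only],
    stringsAsFactors = FALSE))
  if (any(tarmed_only)) {
    sv[[2]] <- data.frame(
      person_id = pid[tarmed_only], date = dd[tarmed_only],
      code_system = "TARMED", code = tarmed_code[tarmed_only],
      stringsAsFactors = FALSE)
  }
  services <- do.call(rbind, sv)

  # enrollment: one span per woman covering every episode window
  enr <- do.call(rbind, lapply(split(seq_len(m), pid), function(ix) {
    data.frame(person_id = pid[ix[1]],
               start = min(pp_start[ix]) - 30L,
               end = max(dd[ix]) + 282L, stringsAsFactors = FALSE)
  }))
  rownames(enr) <- NULL

  # derive true t2/t3 class sets from the emitted dispensations
  cls_all <- classify_atc(dispensations$atc_code, code_config())
  t2_classes <- t3_classes <- character(m)
  adm <- cls_all != "non_adm"
  dk <- dispensations[adm, , drop = FALSE]
  ck <- cls_all[adm]
  idx_by_person <- split(seq_len(nrow(dk)), dk$person_id)
  for (k in seq_len(m)) {
    rows <- idx_by_person[[pid[k]]]
    if (is.null(rows)) next
    dts <- dk$date[rows]
    in_ep <- dts >= pp_start[k] & dts <= dd[k]
    rows <- rows[in_ep]; dts <- dts[in_ep]
    t2 <- dts >= lmp[k] + 90L & dts <= lmp[k] + 179L
    t3 <- dts >= lmp[k] + 180L
    t2_classes[k] <- paste(sort(unique(ck[rows[t2]])), collapse = ",")
    t3_classes[k] <- paste(sort(unique(ck[rows[t3]])), collapse = ",")
  }

  cls_str <- function(ins, bgld) {
    out <- character(length(ins))
    out[ins & bgld] <- "blood_glucose_lowering,insulin"
    out[ins & !bgld] <- "insulin"
    out[!ins & bgld] <- "blood_glucose_lowering"
    out
  }
  truth <- data.frame(
    person_id = pid,
    delivery_date = dd,
    term_status = term,
    lmp = lmp,
    delivery_year = as.integer(format(dd, "%Y")),
    caesarean = caesarean,
    group = group,
    subtype = subtype,
    pre_classes = cls_str(pre_ins, pre_bgld),
    t1_classes = cls_str(t1_ins, t1_bgld),
    t2_classes = t2_classes,
    t3_classes = t3_classes,
    fertility_comedication = fert,
    tarmed_only = tarmed_only,
    expected_audit = NA_character_,
    dropped_enrollment = FALSE,
    first_uncovered_day = as.Date(rep(NA, m)),
    stringsAsFactors = FALSE)

  out <- list(services = services, dispensations = dispensations,
              enrollment = enr, birth_years = birth_years, truth = truth,
              injections = empty_df(person_id = character(0),
                                    kind = character(0),
                                    date = as.Date(character(0)),
                                    delivery_date = as.Date(character(0))),
              config = config)
  if (any(unlist(config$noise[c("duplicate_code", "stray_drg",
                                "relocation", "enrollment_gap")]) > 0)) {
    out <- inject_pathologies(out, config)
  }
  out <- canonicalise_cohort(out)
  out
}

canonicalise_cohort <- function(cohort) {
  s <- cohort$services
  cohort$services <- s[order(s$person_id, s$date, s$code), , drop = FALSE]
  d <- cohort$dispensations
  cohort$dispensations <- d[order(d$person_id, d$date, d$atc_code), ,
                            drop = FALSE]
  e <- cohort$enrollment
  cohort$enrollment <- e[order(e$person_id, e$start), , drop = FALSE]
  t <- cohort$truth
  cohort$truth <- t[order(t$person_id, t$delivery_date), , drop = FALSE]
  for (nm in c("services", "dispensations", "enrollment", "truth")) {
    rownames(cohort[[nm]]) <- NULL
  }
  cohort
}

#' Inject pathological claim patterns
#'
#' Adds the noise events that exercise the delivery-collapsing and
#' enrollment rules: duplicate delivery codes within 30 days (absorbed by
#' collapsing), stray DRG codes 31--300 days after a DRG-dated delivery
#' (ignored), TARMED-dated deliveries corrected by a later DRG code
#' (delivery date relocated), and coverage gaps inside the observation
#' window (episode dropped by the enrollment filter). The ground truth is
#' updated with the expected pipeline behaviour, and each injected event is
#' appended to `injections` for record-for-record audit matching.
#'
#' @param cohort a [generate_cohort()] result (or the same structure).
#' @param config the [sim_config()] with positive noise rates.
#' @return the cohort with modified tables, updated `truth`, `injections`.
#' @export
inject_pathologies <- function(cohort, config) {
  truth <- cohort$truth
  services <- cohort$services
  enrollment <- cohort$enrollment
  inj <- list()
  m <- nrow(truth)
  drg_key <- paste(services$person_id[services$code_system == "DRG"],
                   services$date[services$code_system == "DRG"])
  drg_eligible <- paste(truth$person_id, truth$delivery_date) %in% drg_key

  # duplicate codes within the 30-day collapsing window
  dup <- which(stats::runif(m) < config$noise$duplicate_code)
  if (length(dup)) {
    date <- truth$delivery_date[dup] + draw_days(rep(1L, length(dup)),
                                                 rep(20L, length(dup)))
    services <- rbind(services, data.frame(
      person_id = truth$person_id[dup], date = date,
      code_system = "TARMED",
      code = ifelse(truth$caesarean[dup], "DELCS", "DEL01"),
      stringsAsFactors = FALSE))
    inj[[length(inj) + 1L]] <- data.frame(
      person_id = truth$person_id[dup], kind = "duplicate_code",
      date = date, delivery_date = truth$delivery_date[dup],
      stringsAsFactors = FALSE)
  }

  # stray DRG codes 31-300 days after a DRG-dated delivery: ignored
  stray <- which(drg_eligible & stats::runif(m) < config$noise$stray_drg)
  if (length(stray)) {
    date <- truth$delivery_date[stray] + draw_days(rep(40L, length(stray)),
                                                   rep(290L, length(stray)))
    services <- rbind(services, data.frame(
      person_id = truth$person_id[stray], date = date,
      code_system = "DRG", code = "O60B", stringsAsFactors = FALSE))
    truth$expected_audit[stray] <- "ignored_drg_31_300"
    inj[[length(inj) + 1L]] <- data.frame(
      person_id = truth$person_id[stray], kind = "stray_drg",
      date = date, delivery_date = truth$delivery_date[stray],
      stringsAsFactors = FALSE)
  }

  # TARMED-dated delivery later corrected by its DRG code: the pipeline must
  # relocate the delivery date onto the DRG code, i.e. onto the true date
  reloc <- which(drg_eligible & !truth$tarmed_only &
                   is.na(truth$expected_audit) &
                   stats::runif(m) < config$noise$relocation)
  if (length(reloc)) {
    offset <- draw_days(rep(35L, length(reloc)), rep(90L, length(reloc)))
    tarmed_date <- truth$delivery_date[reloc] - offset
    services <- rbind(services, data.frame(
      person_id = truth$person_id[reloc], date = tarmed_date,
      code_system = "TARMED",
      code = ifelse(truth$caesarean[reloc], "DELCS", "DEL01"),
      stringsAsFactors = FALSE))
    truth$expected_audit[reloc] <- "relocated_tarmed_to_drg"
    inj[[length(inj) + 1L]] <- data.frame(
      person_id = truth$person_id[reloc], kind = "relocation",
      date = tarmed_date, delivery_date = truth$delivery_date[reloc],
      stringsAsFactors = FALSE)
  }

  # enrollment gaps: single-episode women only, so the gap unambiguously
  # hits one episode's observation window
  n_ep <- table(truth$person_id)
  single <- truth$person_id %in% names(n_ep)[n_ep == 1L]
  gap <- which(single & is.na(truth$expected_audit) &
                 stats::runif(m) < config$noise$enrollment_gap)
  if (length(gap)) {
    gday <- truth$lmp[gap] - 252L +
      draw_days(rep(10L, length(gap)), rep(100L, length(gap)))
    glen <- draw_days(rep(3L, length(gap)), rep(10L, length(gap)))
    for (j in seq_along(gap)) {
      k <- gap[j]
      row <- which(enrollment$person_id == truth$person_id[k])[1]
      s <- enrollment$start[row]; e <- enrollment$end[row]
      enrollment <- enrollment[-row, , drop = FALSE]
      enrollment <- rbind(enrollment, data.frame(
        person_id = truth$person_id[k],
        start = c(s, gday[j] + glen[j]),
        end = c(gday[j] - 1L, e), stringsAsFactors = FALSE))
    }
    truth$dropped_enrollment[gap] <- TRUE
    truth$first_uncovered_day[gap] <- gday
    inj[[length(inj) + 1L]] <- data.frame(
      person_id = truth$person_id[gap], kind = "enrollment_gap",
      date = gday, delivery_date = truth$delivery_date[gap],
      stringsAsFactors = FALSE)
  }

  cohort$services <- services
  cohort$enrollment <- enrollment
  cohort$truth <- truth
  cohort$injections <- rbind(cohort$injections,
                             do.call(rbind, inj) %||% NULL)
  canonicalise_cohort(cohort)
}

#' Write the synthetic tables of a cohort to a directory
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(services = file.path(dir, "services.csv"),
             dispensations = file.path(dir, "dispensations.csv"),
             enrollment = file.path(dir, "enrollment.csv"))
  write_claims(cohort$services, paths["services"], "services")
  write_claims(cohort$dispensations, paths["dispensations"], "dispensations")
  write_claims(cohort$enrollment, paths["enrollment"], "enrollment")
  truth <- cohort$truth
  for (dc in c("delivery_date", "lmp", "first_uncovered_day")) {
    truth[[dc]] <- format(truth[[dc]], "%Y-%m-%d")
  }
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$birth_years, file.path(dir, "birth_years.csv"),
                   row.names = FALSE)
  invisible(paths)
}
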
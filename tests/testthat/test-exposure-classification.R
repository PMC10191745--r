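cfg <- code_config()

ep1 <- build_episodes(
  data.frame(person_id = "p1", event_id = "p1_e01",
             delivery_date = as.Date("2015-10-01"),
             term_status = "full_term", had_drg = TRUE, had_tarmed = FALSE,
             caesarean = FALSE, n_codes = 1L, stringsAsFactors = FALSE),
  config = cfg)

disp <- function(days_from_lmp, atc, person = "p1") {
  data.frame(person_id = person, date = ep1$lmp + days_from_lmp,
             atc_code = atc, stringsAsFactors = FALSE)
}

profile_of <- function(d) build_exposure_profile(ep1, d, cfg)

test_that("dispensations land in the window containing their date", {
  # day lmp+90 is the first day of T2, not the last of T1
  pr <- profile_of(disp(90, "A10BA02"))
  expect_equal(pr$classes$t2, "blood_glucose_lowering")
  expect_length(pr$classes$t1, 0)
  # window start of prepregnancy is inclusive
  pr2 <- profile_of(disp(-252, "A10AB05"))
  expect_equal(pr2$classes$prepregnancy, "insulin")
  expect_true(pr2$exposed_prepregnancy)
  # delivery day counts toward T3; later dispensations are ignored
  pr3 <- profile_of(rbind(disp(270, "A10AB05"), disp(271, "A10AB05")))
  expect_equal(pr3$classes$t3, "insulin")
  expect_equal(pr3$substances$t3, "A10AB05")
  pr4 <- profile_of(disp(271, "A10AB05"))
  expect_false(pr4$exposed_t2_or_later)
  # non-ADM dispensations never contribute
  pr5 <- profile_of(disp(100, "C07AB02"))
  expect_length(unlist(pr5$classes), 0)
})

test_that("window assignment equals brute-force day-by-day membership", {
  set.seed(51)
  for (rep in 1:40) {
    offs <- sample(-300:300, 6, replace = TRUE)
    d <- disp(offs, sample(c("A10AB05", "A10BA02", "A10BX02"), 6,
                           replace = TRUE))
    pr <- profile_of(d)
    ref <- vapply(seq_len(nrow(d)),
                  function(i) oracle_window(d$date[i], ep1), character(1))
    for (w in c("prepregnancy", "t1", "t2", "t3")) {
      want <- sort(unique(classify_atc(d$atc_code[!is.na(ref) & ref == w],
                                       cfg)))
      expect_equal(pr$classes[[w]], want)
    }
  }
})

test_that("group assignment implements the three utilisation groups", {
  g <- function(d) assign_group(profile_of(d))
  # continuer: insulin prepregnancy, insulin + BGLD in or after T2
  expect_equal(g(rbind(disp(-100, "A10AB05"), disp(200, "A10AB05"),
                       disp(210, "A10BA02"))), "pregestational_continuer")
  # continuer: insulin + BGLD prepregnancy, insulin only after T2
  expect_equal(g(rbind(disp(-100, "A10AB05"), disp(-90, "A10BA02"),
                       disp(200, "A10AB05"))), "pregestational_continuer")
  # switcher: BGLD prepregnancy, insulin only after T2
  expect_equal(g(rbind(disp(-100, "A10BA02"), disp(200, "A10AB05"))),
               "pregestational_switcher")
  # discontinuer: prepregnancy only
  expect_equal(g(disp(-100, "A10BA02")), "discontinuer")
  # prepregnancy + T1 exposure but nothing in or after T2 is still a
  # discontinuer under definition (3)
  expect_equal(g(rbind(disp(-100, "A10BA02"), disp(50, "A10BA02"))),
               "discontinuer")
  # gdm: first dispensation in T3
  expect_equal(g(disp(250, "A10AB05")), "gdm")
  # t1-only exposure is neither gdm nor discontinuer
  t1o <- g(disp(50, "A10AB05"))
  expect_equal(as.character(t1o), "t1_only")
  expect_equal(attr(t1o, "subtype"), "t1_exclusive")
  t1f <- g(rbind(disp(50, "A10AB05"), disp(200, "A10AB05")))
  expect_equal(as.character(t1f), "t1_only")
  expect_equal(attr(t1f, "subtype"), "t1_first")
  # no exposure at all
  expect_equal(g(disp(100, "C07AB02")), "unexposed")
})

test_that("switcher implies disjoint prepregnancy and post-T2 class sets", {
  set.seed(52)
  subs <- c("A10AB05", "A10AE04", "A10BA02", "A10BJ02", "A10BK01")
  for (rep in 1:150) {
    offs <- sample(c(-250:-1, 0:89, 90:269), sample(1:5, 1))
    d <- disp(offs, sample(subs, length(offs), replace = TRUE))
    pr <- profile_of(d)
    gl <- assign_group(pr)
    post <- union(pr$classes$t2, pr$classes$t3)
    if (gl == "pregestational_switcher") {
      expect_length(intersect(pr$classes$prepregnancy, post), 0)
    }
    if (gl == "pregestational_continuer") {
      expect_gt(length(intersect(pr$classes$prepregnancy, post)), 0)
    }
    expect_true(gl %in% c("pregestational_continuer",
                          "pregestational_switcher", "gdm", "discontinuer",
                          "t1_only", "unexposed"))
  }
})

test_that("fertility comedication is flagged in the prepregnancy window only", {
  d_pre <- disp(-100, "G03GA01")
  d_t3 <- disp(250, "G03GA01")
  pr <- profile_of(d_pre)
  expect_true(flag_fertility_comedication(pr, ep1, d_pre, cfg))
  expect_false(flag_fertility_comedication(profile_of(d_t3), ep1, d_t3, cfg))
  bad_cfg <- cfg
  bad_cfg$fertility_atc <- character(0)
  expect_error(flag_fertility_comedication(pr, ep1, d_pre, bad_cfg),
               class = "admpreg_config_error")
})

test_that("substance shares are computed within class and group", {
  # two continuers, both on metformin: share 100%
  eps <- rbind(ep1, ep1)
  eps$episode_id <- c("e1", "e2")
  eps$person_id <- c("p1", "p2")
  d <- rbind(disp(-100, "A10BA02", "p1"), disp(200, "A10BA02", "p1"),
             disp(-110, "A10BA02", "p2"), disp(210, "A10BA02", "p2"))
  cl <- classify_cohort(eps, d, cfg)
  tab <- substance_distribution(cl$profiles, cl$classification$group,
                                "pregestational_continuer", "prepregnancy",
                                cfg)
  expect_equal(tab$substance, "A10BA02")
  expect_equal(tab$share_pct, 100.0)
  # empty group: explicit empty table, no division error
  empty <- substance_distribution(cl$profiles, cl$classification$group,
                                  "gdm", "prepregnancy", cfg)
  expect_s3_class(empty, "data.frame")
  expect_equal(nrow(empty), 0)
})

test_that("a programmed 60/40 substance mix is recovered within 3 points", {
  set.seed(53)
  n <- 2000
  eps <- ep1[rep(1, n), ]
  eps$episode_id <- sprintf("e%04d", 1:n)
  eps$person_id <- sprintf("s%04d", 1:n)
  sub <- sample(c("A10BA02", "A10BB01"), n, replace = TRUE,
                prob = c(0.6, 0.4))
  d <- data.frame(person_id = eps$person_id, date = eps$lmp - 100,
                  atc_code = sub, stringsAsFactors = FALSE)
  cl <- classify_cohort(eps, d, cfg)
  tab <- substance_distribution(cl$profiles, cl$classification$group,
                                "discontinuer", "prepregnancy", cfg)
  expect_equal(sum(tab$n), n)
  met <- tab$share_pct[tab$substance == "A10BA02"]
  expect_lt(abs(met - 60), 3)
})
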
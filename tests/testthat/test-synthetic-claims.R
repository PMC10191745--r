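test_that("generation is deterministic given the seed", {
  a <- generate_cohort(sim_config(seed = 7, n_women = 60))
  b <- generate_cohort(sim_config(seed = 7, n_women = 60))
  expect_identical(a$services, b$services)
  expect_identical(a$dispensations, b$dispensations)
  expect_identical(a$enrollment, b$enrollment)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(sim_config(seed = 8, n_women = 60))
  expect_false(identical(a$services, c$services))
})

test_that("config validation catches impossible settings", {
  expect_error(sim_config(), class = "admpreg_config_error")
  expect_error(sim_config(seed = 1, preterm_prob = 1.4),
               class = "admpreg_config_error")
  expect_error(sim_config(seed = 1,
                          group_prev_per_10k = c(pregestational = 9000,
                                                 gdm = 2000,
                                                 discontinuer = 0,
                                                 t1_only = 0)),
               class = "admpreg_config_error")
  expect_error(sim_config(seed = 1, years = c(2012L, 2012L),
                          parity_probs = c(`1` = 0.5, `3` = 0.5)),
               class = "admpreg_generation_error")
})

test_that("deliveries of one woman are always >= 300 days apart", {
  co <- generate_cohort(sim_config(seed = 9, n_women = 300))
  by_person <- split(co$truth$delivery_date, co$truth$person_id)
  gaps <- unlist(lapply(by_person, function(d) diff(sort(as.integer(d)))))
  if (length(gaps)) expect_true(all(gaps >= 300))
})

test_that("dispensations sit strictly inside their intended windows", {
  co <- generate_cohort(sim_config(seed = 10, n_women = 200))
  tr <- co$truth
  adm <- co$dispensations[startsWith(co$dispensations$atc_code, "A10"), ]
  for (i in seq_len(nrow(adm))) {
    person_eps <- tr[tr$person_id == adm$person_id[i], , drop = FALSE]
    offs <- as.integer(adm$date[i] - person_eps$lmp)
    hit <- offs[offs >= -252 & offs <= as.integer(person_eps$delivery_date -
                                                    person_eps$lmp)]
    expect_length(hit, 1) # exactly one episode window owns the date
    # at least one day from every window boundary
    expect_false(hit %in% c(-252, -1, 0, 89, 90, 179, 180))
  }
})

test_that("zero-noise cohorts are recovered end-to-end at 100%", {
  co <- generate_cohort(sim_config(seed = 1, n_women = 100))
  res <- run_pipeline(sim_config(seed = 1, n_women = 100))
  expect_equal(nrow(res$dropped), 0)
  expect_equal(nrow(res$episodes), nrow(co$truth))
  cls <- res$classification
  ep <- res$episodes
  cls$delivery_date <- ep$delivery_date[match(cls$episode_id,
                                              ep$episode_id)]
  mm <- match(paste(cls$person_id, cls$delivery_date),
              paste(co$truth$person_id, co$truth$delivery_date))
  expect_false(anyNA(mm))
  expect_equal(cls$group, co$truth$group[mm])
  expect_equal(cls$pre_classes, co$truth$pre_classes[mm])
  expect_equal(cls$fertility_comedication,
               co$truth$fertility_comedication[mm])
  # imputed timing matches the generator's ground truth
  mm2 <- match(paste(ep$person_id, ep$delivery_date),
               paste(co$truth$person_id, co$truth$delivery_date))
  expect_equal(ep$lmp, co$truth$lmp[mm2])
  expect_equal(ep$term_status, co$truth$term_status[mm2])
})

test_that("duplicate delivery codes are absorbed without changing counts", {
  clean <- run_pipeline(sim_config(seed = 13, n_women = 150))
  noisy <- run_pipeline(sim_config(seed = 13, n_women = 150,
                                   noise = list(duplicate_code = 1)))
  expect_equal(nrow(noisy$episodes), nrow(clean$episodes))
  expect_equal(noisy$episodes$delivery_date, clean$episodes$delivery_date)
})

test_that("every injected pathology is matched by an audit record", {
  res <- run_pipeline(sim_config(
    seed = 14, n_women = 250,
    noise = list(stray_drg = 0.15, relocation = 0.1,
                 enrollment_gap = 0.08, duplicate_code = 0.1)))
  inj <- res$injections
  expect_gt(nrow(inj), 0)
  st <- inj[inj$kind == "stray_drg", ]
  au <- res$audit[res$audit$rule == "ignored_drg_31_300", ]
  expect_true(all(paste(st$person_id, st$date) %in%
                    paste(au$person_id, au$date)))
  expect_equal(nrow(st), nrow(au))

  re <- inj[inj$kind == "relocation", ]
  ar <- res$audit[res$audit$rule == "relocated_tarmed_to_drg", ]
  expect_true(all(paste(re$person_id, re$delivery_date) %in%
                    paste(ar$person_id, ar$date)))
  expect_equal(nrow(re), nrow(ar))

  eg <- inj[inj$kind == "enrollment_gap", ]
  expect_equal(nrow(res$dropped), nrow(eg))
  expect_true(all(paste(eg$person_id, eg$date) %in%
                    paste(res$dropped$person_id,
                          res$dropped$first_uncovered_day)))

  # classification of surviving episodes is still exact
  tr <- res$truth
  cls <- res$classification
  ep <- res$episodes
  cls$delivery_date <- ep$delivery_date[match(cls$episode_id,
                                              ep$episode_id)]
  mm <- match(paste(cls$person_id, cls$delivery_date),
              paste(tr$person_id, tr$delivery_date))
  expect_equal(cls$group, tr$group[mm])
})

test_that("written cohorts re-read identically", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(sim_config(seed = 15, n_women = 30))
  write_cohort(co, dir)
  again <- read_claims(file.path(dir, "services.csv"),
                       file.path(dir, "dispensations.csv"),
                       file.path(dir, "enrollment.csv"))
  expect_equal(again$services, co$services, ignore_attr = TRUE)
  expect_equal(nrow(again$diagnostics), 0)
})
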
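cfg <- code_config()

svc <- function(days, sys, code, person = "p1", origin = "2015-01-01") {
  data.frame(person_id = person, date = as.Date(origin) + days,
             code_system = sys, code = code, stringsAsFactors = FALSE)
}

test_that("delivery-code extraction keeps only configured codes", {
  s <- rbind(svc(0, "DRG", "O60A"), svc(1, "DRG", "X99Z"),
             svc(2, "TARMED", "DEL01"), svc(3, "TARMED", "CONS1"),
             svc(4, "DRG", "O60C"))
  got <- extract_delivery_codes(s, cfg)
  expect_equal(nrow(got), 3)
  expect_equal(got$term_status, c("full_term", "unspecified", "preterm"))
  expect_equal(nrow(extract_delivery_codes(svc(0, "DRG", "ZZZ"), cfg)), 0)
})

test_that("extraction equals brute-force set membership on random services", {
  set.seed(21)
  pool_sys <- c("DRG", "TARMED")
  pool_code <- c("O60A", "O60C", "O01A", "DEL01", "DELCS", "X99Z", "CONS1",
                 "O40Z")
  s <- data.frame(
    person_id = sample(sprintf("p%02d", 1:20), 1000, replace = TRUE),
    date = as.Date("2014-01-01") + sample(0:2000, 1000, replace = TRUE),
    code_system = sample(pool_sys, 1000, replace = TRUE),
    code = sample(pool_code, 1000, replace = TRUE),
    stringsAsFactors = FALSE)
  s <- s[order(s$person_id, s$date), ]
  got <- extract_delivery_codes(s, cfg)
  ref <- oracle_extract(s, cfg)
  expect_equal(nrow(got), nrow(ref))
  expect_equal(got$code, ref$code)
})

test_that("DRG date takes priority within a 30-day cluster", {
  codes <- extract_delivery_codes(
    rbind(svc(95, "TARMED", "DEL01"), svc(100, "DRG", "O60A")), cfg)
  ev <- collapse_delivery_events(codes, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$delivery_date, as.Date("2015-01-01") + 100)
  expect_true(ev$had_drg && ev$had_tarmed)
})

test_that("a DRG code 31-300 days after a TARMED-only event relocates it", {
  codes <- extract_delivery_codes(
    rbind(svc(0, "TARMED", "DEL01"), svc(120, "DRG", "O60C")), cfg)
  ev <- collapse_delivery_events(codes, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$delivery_date, as.Date("2015-01-01") + 120)
  expect_equal(ev$term_status, "preterm") # re-derived from the DRG code
  au <- attr(ev, "audit")
  expect_true("relocated_tarmed_to_drg" %in% au$rule)
})

test_that("a DRG code 31-300 days after a DRG-dated event is ignored", {
  codes <- extract_delivery_codes(
    rbind(svc(0, "DRG", "O60A"), svc(150, "DRG", "O60B")), cfg)
  ev <- collapse_delivery_events(codes, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$delivery_date, as.Date("2015-01-01"))
  au <- attr(ev, "audit")
  expect_equal(au$rule, "ignored_drg_31_300")
  expect_equal(au$date, as.Date("2015-01-01") + 150)
})

test_that("deliveries more than 300 days apart stay separate events", {
  codes <- extract_delivery_codes(
    rbind(svc(0, "DRG", "O60A"), svc(310, "DRG", "O60A")), cfg)
  ev <- collapse_delivery_events(codes, cfg)
  expect_equal(nrow(ev), 2)
  expect_true(all(diff(as.integer(ev$delivery_date)) >= 300))
})

test_that("collapsing matches the brute-force reference on random streams", {
  set.seed(31)
  for (rep in 1:200) {
    stream <- random_code_stream(sprintf("p%03d", rep), cfg)
    codes <- extract_delivery_codes(stream, cfg)
    if (nrow(codes) == 0) next
    got <- collapse_delivery_events(codes, cfg)
    ref <- oracle_collapse(codes, cfg)
    expect_equal(got$delivery_date, ref$delivery_date,
                 info = sprintf("stream %d dates", rep))
    expect_equal(got$term_status, ref$term_status,
                 info = sprintf("stream %d term", rep))
    expect_equal(got$had_drg, ref$had_drg)
    expect_equal(got$had_tarmed, ref$had_tarmed)
    expect_equal(got$caesarean, ref$caesarean)
    expect_equal(got$n_codes, ref$n_codes)
  }
})

test_that("every code is a member of one event or audited, and events are separated", {
  set.seed(32)
  for (rep in 1:60) {
    codes <- extract_delivery_codes(random_code_stream("pz", cfg), cfg)
    if (nrow(codes) == 0) next
    ev <- collapse_delivery_events(codes, cfg)
    members <- attr(ev, "members")
    audit <- attr(ev, "audit")
    discarded <- audit[audit$rule == "ignored_drg_31_300", , drop = FALSE]
    expect_equal(nrow(members) + nrow(discarded), nrow(codes))
    if (nrow(ev) > 1) {
      expect_true(all(diff(as.integer(ev$delivery_date)) >= 300))
    }
    # idempotence: re-collapsing the member codes reproduces the events
    again <- collapse_delivery_events(
      members[order(members$date), c("person_id", "date", "code_system",
                                     "code", "term_status")], cfg)
    expect_equal(again$delivery_date, ev$delivery_date)
    expect_equal(again$term_status, ev$term_status)
  }
})

test_that("unsorted input violates the contract", {
  codes <- extract_delivery_codes(
    rbind(svc(310, "DRG", "O60A"), svc(0, "DRG", "O60A")), cfg)
  codes <- codes[order(codes$date, decreasing = TRUE), ]
  expect_error(collapse_delivery_events(codes, cfg),
               class = "admpreg_contract_error")
})

test_that("termination codes exclude the surrounding delivery event", {
  s <- rbind(svc(0, "DRG", "O60A", "pa"), svc(5, "DRG", "O40Z", "pa"),
             svc(0, "DRG", "O60A", "pb"))
  got <- identify_deliveries(s, cfg)
  expect_equal(got$events$person_id, "pb")
  expect_true("termination_excluded" %in% got$audit$rule)
})

test_that("whole-table identification agrees with per-person collapsing", {
  set.seed(33)
  streams <- do.call(rbind, lapply(1:40, function(i) {
    random_code_stream(sprintf("q%03d", i), cfg)
  }))
  streams <- streams[order(streams$person_id, streams$date), ]
  got <- identify_deliveries(streams, cfg)
  codes <- extract_delivery_codes(streams, cfg)
  ref <- do.call(rbind, lapply(split(codes, codes$person_id), function(x) {
    oracle_collapse(x, cfg)
  }))
  expect_equal(got$events$delivery_date, ref$delivery_date,
               ignore_attr = TRUE)
  expect_equal(got$events$term_status, ref$term_status, ignore_attr = TRUE)
  expect_equal(got$events$n_codes, ref$n_codes, ignore_attr = TRUE)
})
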
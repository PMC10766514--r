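test_that("blank_outliers removes only out-of-range records and is idempotent", {
  meas <- data.frame(patient_id = "p1", day = c(1L, 2L, 3L, 4L),
                     feature = c("temperature", "temperature", "ALT", "temperature"),
                     value = c(98.6, 36.5, 5000, 43))
  rng <- list(temperature = c(34, 43))
  out <- blank_outliers(meas, rng)
  expect_equal(nrow(out), 3L)                      # 98.6 dropped
  expect_true(all(out$value[out$feature == "temperature"] <= 43))
  expect_true(5000 %in% out$value)                 # no range for ALT: kept
  expect_equal(blank_outliers(out, rng), out)      # idempotent
  expect_error(blank_outliers(meas, list(temperature = c(43, 34))),
               "malformed")
})

test_that("aggregate_daily averages same-day records and masks absences", {
  meas <- data.frame(patient_id = c("a", "a", "a", "b"),
                     day = c(7L, 7L, 8L, 2L),
                     feature = "hr", value = c(10, 14, 5, 60))
  p <- aggregate_daily(meas, horizon = 10L)
  expect_equal(p$values["a", "hr", 7], 12)
  expect_equal(p$mask["a", "hr", 7], 1)
  expect_equal(p$mask["a", "hr", 9], 0)            # never measured
  expect_true(is.na(p$values["b", "hr", 9]))
  # brute-force mean oracle on random same-day records
  set.seed(3)
  v <- rnorm(5)
  meas2 <- data.frame(patient_id = "x", day = 4L, feature = "f", value = v)
  p2 <- aggregate_daily(meas2, horizon = 5L)
  expect_equal(p2$values["x", "f", 4], sum(v) / 5)
  # mask count equals number of distinct (patient, feature, day) triples
  expect_equal(sum(p$mask), 3)
})

test_that("sample_and_hold carries values forward a bounded number of days", {
  meas <- data.frame(patient_id = "p", day = 5L, feature = "f", value = 2.5)
  p <- aggregate_daily(meas, horizon = 12L)
  h <- sample_and_hold(p, hold_days = 3L)
  expect_equal(unname(h$values["p", "f", 5:8]), rep(2.5, 4))   # held 3 days
  expect_equal(unname(h$mask["p", "f", 9]), 0)                 # expired
  # newer observation takes precedence over held values
  meas2 <- rbind(meas, data.frame(patient_id = "p", day = 7L,
                                  feature = "f", value = 9))
  h2 <- sample_and_hold(aggregate_daily(meas2, horizon = 12L), 3L)
  expect_equal(unname(h2$values["p", "f", 6]), 2.5)
  expect_equal(unname(h2$values["p", "f", 7:10]), rep(9, 4))
  expect_equal(unname(h2$mask["p", "f", 11]), 0)
  # hold_days = 0 is the identity; mask count never decreases
  expect_identical(sample_and_hold(p, 0L), p)
  expect_gte(sum(h2$mask), sum(p$mask))
  # the hold never crosses the last observed day
  h3 <- sample_and_hold(p, 3L, last_observed = c(p = 6L))
  expect_equal(unname(h3$mask["p", "f", 7]), 0)
  expect_equal(unname(h3$values["p", "f", 6]), 2.5)
})

test_that("assemble_cohort aligns components and rejects id mismatches", {
  meas <- data.frame(patient_id = rep(c("a", "b", "c"), 2),
                     day = rep(c(1L, 2L), each = 3),
                     feature = "f", value = rnorm(6))
  panel <- aggregate_daily(meas, horizon = 5L)
  peri <- data.frame(patient_id = c("c", "a", "b"), g = c("x", "y", "x"))
  outcomes <- data.frame(patient_id = c("a", "b", "c"),
                         onset_day = c(2L, NA, NA),
                         last_observed_day = 5L)
  cohort <- assemble_cohort(panel, peri, outcomes)
  expect_s3_class(cohort, "dagoat_cohort")
  expect_equal(cohort$peri$patient_id, c("a", "b", "c"))  # reordered
  expect_equal(cohort$peri$g, c("y", "x", "x"))
  expect_error(assemble_cohort(panel, peri[1:2, ], outcomes), "mismatch.*a|a.*mismatch")
  # degenerate empty cohort is valid
  empty <- aggregate_daily(meas[0, ], patient_ids = character(0),
                           feature_names = "f", horizon = 5L)
  expect_equal(n_patients(assemble_cohort(
    empty, peri[0, , drop = FALSE],
    outcomes[0, , drop = FALSE])), 0L)
})

test_that("long-format CSV round-trips panel values and mask exactly", {
  set.seed(11)
  meas <- data.frame(patient_id = sample(c("a", "b"), 30, TRUE),
                     day = sample(1:10, 30, TRUE),
                     feature = sample(c("f1", "f2"), 30, TRUE),
                     value = rnorm(30))
  p <- aggregate_daily(meas, horizon = 10L)
  f <- tempfile(fileext = ".csv")
  write_panel_csv(p, f)
  p2 <- read_panel_csv(f, patient_ids = p$patient_ids,
                       feature_names = p$feature_names, horizon = 10L)
  expect_equal(p2$mask, p$mask)
  expect_equal(p2$values[p$mask == 1], p$values[p$mask == 1])
  unlink(f)
})

test_that("outcome table invariants are enforced", {
  expect_error(as_outcomes(data.frame(patient_id = "a", onset_day = 9L,
                                      last_observed_day = 5L)),
               "onset_day")
  expect_error(as_outcomes(data.frame(patient_id = c("a", "a"),
                                      onset_day = NA_integer_,
                                      last_observed_day = 5L)),
               "duplicate")
})
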
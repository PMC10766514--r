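test_that("AUROC and AUPRC match brute-force definitions", {
  # degenerate conventions
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auprc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auprc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)  # prevalence
  expect_true(is.na(auroc(1:3, c(1, 1, 1))))
  # random instances vs pairwise-concordance / exhaustive PR oracles
  set.seed(12)
  for (i in 1:60) {
    n <- sample(4:20, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, y), oracle_auroc(s, y))
    expect_equal(auprc(s, y), oracle_auprc(s, y))
  }
  # rank invariance under a monotone transform
  set.seed(13)
  s <- rnorm(30); y <- rbinom(30, 1, 0.3); if (sum(y) %in% c(0, 30)) y[1] <- 1L
  expect_equal(auroc(exp(s), y), auroc(s, y))
  expect_equal(auprc(exp(s), y), auprc(s, y))
})

test_that("bootstrap CI is degenerate-safe and brackets the point estimate", {
  set.seed(5)
  s <- c(rnorm(30), rnorm(30, 1.2))
  y <- rep(c(0, 1), each = 30)
  ci <- bootstrap_ci(auroc, s, y, B = 300L, seed = 2L)
  pt <- auroc(s, y)
  expect_lte(ci["lo"], pt); expect_gte(ci["hi"], pt)
  # perfectly separated data: CI collapses to 1
  ci2 <- bootstrap_ci(auroc, c(1, 1, 1, 9, 9, 9), c(0, 0, 0, 1, 1, 1),
                      B = 50L, seed = 3L)
  expect_equal(unname(ci2), c(1, 1))
})

test_that("daily metrics follow the moving-window labels", {
  cohort <- make_toy_cohort(n = 40L, horizon = 30L, seed = 41L)
  cfg <- dagoat_config(delta = 10L, horizon = 30L)
  model <- dagoat_fit(cohort, cfg)
  traj <- score_trajectories(model, cohort)
  dm <- daily_metrics(traj, cohort, cfg)
  t <- 8L
  lab <- window_labels(cohort, t, cfg$delta, cfg$horizon)
  use <- lab$at_risk & traj$valid[, t] == 1
  expect_equal(dm$auroc[t], auroc(traj$scores[use, t], lab$y[use]))
  expect_equal(dm$n_at_risk[t], sum(use))
  # a day with no positive cases leaves the metric undefined
  late <- which(dm$n_positive == 0)
  if (length(late)) expect_true(all(is.na(dm$auroc[late])))
})

test_that("two-by-two chi-square matches the textbook formula and printed example", {
  # continuity-corrected test on the published NRM attribution table
  res <- two_by_two_chisq(41, 23, 47, 36, continuity = TRUE)
  expect_equal(round(res$p, 3), 0.458)
  # equal-proportion table: statistic 0, p 1
  res0 <- two_by_two_chisq(20, 10, 40, 20)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # random tables vs independent formula computation
  set.seed(77)
  for (i in 1:25) {
    tb <- rmultinom(1, 80, c(.3, .2, .3, .2))
    for (cont in c(TRUE, FALSE)) {
      got <- two_by_two_chisq(tb[1], tb[2], tb[3], tb[4], continuity = cont)
      ora <- oracle_chisq_2x2(tb[1], tb[2], tb[3], tb[4], continuity = cont)
      expect_equal(got$statistic, ora$statistic, tolerance = 1e-10)
      expect_equal(got$p, ora$p, tolerance = 1e-10)
    }
  }
  expect_error(two_by_two_chisq(0, 0, 3, 4), "margin")
})

test_that("temporal CV makes expanding trains and partitioning validation blocks", {
  cohort <- make_toy_cohort(n = 10L, horizon = 15L, seed = 51L)
  plan <- temporal_cv(cohort, n_folds = 5L)
  expect_length(plan, 4L)
  sizes <- vapply(plan, function(f) length(f$validation), integer(1))
  expect_equal(sizes, rep(2L, 4L))
  train_sizes <- vapply(plan, function(f) length(f$train), integer(1))
  expect_true(all(diff(train_sizes) > 0))
  for (f in plan) expect_length(intersect(f$train, f$validation), 0L)
  all_val <- unlist(lapply(plan, `[[`, "validation"))
  expect_false(anyDuplicated(all_val) > 0)
  expect_setequal(c(plan[[1]]$train, all_val), cohort$panel$patient_ids)
  expect_error(temporal_cv(cohort, n_folds = 11L), "fewer patients")
})

test_that("sextile hazard ratio detects association and flags incalculable cases", {
  # null case: no association, HR near 1 at large n
  set.seed(61)
  n <- 3000L
  ids <- sprintf("h%04d", seq_len(n))
  onset <- ifelse(runif(n) < 0.2, sample(11:24, n, TRUE), NA_integer_)
  cohort <- list(outcomes = data.frame(patient_id = ids, onset_day = onset,
                                       last_observed_day = 100L),
                 panel = list(horizon = 100L))
  scores <- rnorm(n)
  res <- sextile_hazard_ratio(scores, cohort, t = 10L, dagoat_config())
  expect_false(res$incalculable)
  expect_gt(res$hr, 0.7); expect_lt(res$hr, 1.4)
  # informative scores produce HR > 1
  scores2 <- ifelse(!is.na(onset), rnorm(n, 1.5), rnorm(n))
  res2 <- sextile_hazard_ratio(scores2, cohort, t = 10L, dagoat_config())
  expect_gt(res2$hr, 1.5)
  # zero events in one group is incalculable, mirroring small-sample reports
  onset3 <- rep(NA_integer_, 30L)
  onset3[1:4] <- 15L
  cohort3 <- list(outcomes = data.frame(patient_id = sprintf("q%d", 1:30),
                                        onset_day = onset3,
                                        last_observed_day = 100L),
                  panel = list(horizon = 100L))
  s3 <- rep(0, 30); s3[1:4] <- 10   # all events in the high group
  res3 <- sextile_hazard_ratio(s3, cohort3, t = 10L, dagoat_config())
  expect_true(res3$incalculable)
})

test_that("data density counts available cells per feature", {
  meas <- expand.grid(patient_id = c("a", "b"), day = 1:30)
  meas$feature <- "full"; meas$value <- 1
  p <- aggregate_daily(meas, horizon = 40L)
  expect_equal(unname(data_density(p, 1:30)), 1)
  # random mask vs counting oracle
  set.seed(71)
  meas2 <- meas[runif(nrow(meas)) < 0.4, ]
  p2 <- aggregate_daily(meas2, patient_ids = c("a", "b"),
                        feature_names = "full", horizon = 40L)
  expect_equal(unname(data_density(p2, 1:30)), nrow(meas2) / (2 * 30))
})

test_that("feature importance credits the informative feature; ranking is stable", {
  cohort <- make_toy_cohort(n = 60L, horizon = 25L, seed = 81L, shift = 4)
  cfg <- dagoat_config(delta = 8L, horizon = 25L)
  imp <- feature_importance(cohort, cfg, n_folds = 4L)
  expect_true(all(abs(imp$importance[!is.na(imp$importance)]) <= 1))
  expect_equal(rank_features(imp)[1], "marker")
  expect_gt(imp$max_8_30["marker"], imp$max_8_30["noise"])
  # rank unchanged by importance outside days 8-30
  imp2 <- imp$importance
  imp2[, c(1:7)] <- 5
  expect_equal(rank_features(imp2), rank_features(imp$importance))
  # alphabetical tie-break on identical curves
  tied <- matrix(0.1, 2, 31, dimnames = list(c("zeta", "alpha"), NULL))
  expect_equal(rank_features(tied), c("alpha", "zeta"))
})

test_that("subset curve endpoints recover the prior-only and full models", {
  cohort <- make_toy_cohort(n = 40L, horizon = 20L, seed = 91L)
  cfg <- dagoat_config(delta = 7L, horizon = 20L)
  plan <- temporal_cv(cohort, 4L)
  ranked <- c("marker", "noise")
  sc <- subset_curve(cohort, cfg, ranked, n_features = c(0L, 2L), cv_plan = plan)
  full <- internal_validation_metrics <- dagoat:::internal_validation_metrics(
    cohort, cfg, plan)
  got_full <- sc[sc$n_features == 2L, ]
  expect_equal(got_full$auprc, full$auprc)
  # N = 0 scores are constant per patient (prior only): AUROC defined
  got0 <- sc[sc$n_features == 0L, ]
  expect_true(any(!is.na(got0$auroc)))
})
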
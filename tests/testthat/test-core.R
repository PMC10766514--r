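test_that("window labels implement risk set and moving-window outcome", {
  outcomes <- data.frame(patient_id = c("a", "b", "c", "d", "e"),
                         onset_day = c(10L, 11L, 25L, NA, NA),
                         last_observed_day = c(30L, 30L, 30L, 30L, 5L))
  cohort <- list(outcomes = outcomes, panel = list(horizon = 30L))
  lab <- window_labels(cohort, t = 10L, delta = 14L, horizon = 30L)
  expect_false(lab$at_risk[1])                 # onset at t: already onset
  expect_true(lab$at_risk[2]); expect_equal(lab$y[2], 1L)   # onset t+1
  # onset 25 = t + delta + 1: in the risk set but outside the window
  expect_true(lab$at_risk[3]); expect_equal(lab$y[3], 0L)
  expect_equal(lab$y[4], 0L)
  expect_false(lab$at_risk[5])                 # left observation before t
  # widening the window by one day captures that onset
  lab2 <- window_labels(cohort, t = 10L, delta = 15L, horizon = 30L)
  expect_equal(lab2$y[3], 1L)
})

test_that("best_cutoff maximizes mutual information with deterministic ties", {
  # perfect separation: midpoint between the classes, MI = H(Y)
  expect_equal(best_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1)), 2.5)
  # degenerate cases
  expect_true(is.na(best_cutoff(rep(5, 4), c(0, 1, 0, 1))))
  expect_true(is.na(best_cutoff(c(1, 2, 3), c(1, 1, 1))))
  # brute-force agreement on random instances
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    v <- round(rnorm(n), 1)          # ties among values are likely
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2 || length(unique(v)) < 2) next
    expect_equal(best_cutoff(v, y), oracle_best_cutoff(v, y))
  }
})

test_that("threshold pooling takes the 25th/75th percentiles of defined cutoffs", {
  cohort <- make_toy_cohort(n = 20L, horizon = 12L, seed = 2L)
  cfg <- dagoat_config(delta = 5L, horizon = 12L)
  th <- fit_thresholds(cohort, "marker", cfg)
  defined <- th$cutoffs[!is.na(th$cutoffs)]
  expect_gt(length(defined), 0)
  expect_equal(unname(stats::quantile(defined, c(.25, .75))), c(th$l, th$u))
  expect_lte(th$l, th$u)
})

test_that("bin probabilities are class-conditional observed fractions", {
  cohort <- make_toy_cohort(n = 30L, horizon = 20L, seed = 3L)
  cfg <- dagoat_config(delta = 7L, horizon = 20L)
  th <- fit_thresholds(cohort, "marker", cfg)
  probs <- fit_bin_probs(cohort, "marker", th$l, th$u, cfg)
  # counting oracle at an arbitrary day
  for (t in c(5L, 12L)) {
    lab <- window_labels(cohort, t, cfg$delta, cfg$horizon)
    obs <- lab$at_risk & cohort$panel$mask[, "marker", t] == 1
    x <- cohort$panel$values[obs, "marker", t]
    y <- lab$y[obs]
    if (any(y == 1))
      expect_equal(unname(probs["p1L", t]), mean(x[y == 1] < th$l))
    if (any(y == 0))
      expect_equal(unname(probs["p0H", t]), mean(x[y == 0] > th$u))
  }
  expect_true(all(probs[!is.na(probs)] >= 0 & probs[!is.na(probs)] <= 1))
})

test_that("spline smoothing preserves constants, extrapolates, reduces variation", {
  expect_equal(smooth_probs(rep(0.4, 50)), rep(0.4, 50))
  # defined only in the middle: full-horizon evaluation extrapolates
  raw <- rep(NA_real_, 100)
  raw[10:90] <- 0.2 + 0.001 * (10:90)
  sm <- smooth_probs(raw)
  expect_false(anyNA(sm))
  expect_length(sm, 100)
  # variation reduction on a noisy sinusoid
  set.seed(9)
  noisy <- 0.5 + 0.3 * sin(seq(0, 3 * pi, length.out = 80)) + rnorm(80, 0, 0.15)
  smn <- smooth_probs(noisy)
  tv <- function(z) sum(abs(diff(z)))
  expect_lt(tv(smn), tv(noisy))
  # sparse fall-backs
  sparse <- c(0.2, NA, 0.4, rep(NA, 17))
  expect_equal(smooth_probs(sparse), rep(0.3, 20))
  expect_true(all(is.na(smooth_probs(rep(NA_real_, 10)))))
})

test_that("theta is the log-ratio of gamma-floored bin probabilities", {
  mk_params <- function(p1L, p1H, p0L, p0H, horizon = 5L) {
    raw <- rbind(p1L = rep(p1L, horizon), p1H = rep(p1H, horizon),
                 p0L = rep(p0L, horizon), p0H = rep(p0H, horizon))
    list(l = -1, u = 1, raw = raw, smooth = raw, uninformative = FALSE)
  }
  par <- mk_params(0.5, 0.2, 0.15, 0.2)
  expect_equal(theta(-2, 1, par, gamma = 0.1), log(0.6 / 0.25))
  # spline undershoot is clamped at zero before the gamma floor
  par2 <- mk_params(-0.02, 0.2, 0.3, 0.2)
  expect_equal(theta(-2, 1, par2, gamma = 0.1), log(0.1 / 0.4))
  # identical class-conditional curves give zero in every bin
  par3 <- mk_params(0.3, 0.25, 0.3, 0.25)
  for (x in c(-2, 0, 2)) expect_equal(theta(x, 3, par3), 0)
  # antisymmetry under class swap
  par_sw <- mk_params(0.15, 0.2, 0.5, 0.2)
  for (x in c(-2, 0, 2))
    expect_equal(theta(x, 1, par_sw, gamma = 0.1),
                 -theta(x, 1, par, gamma = 0.1))
})

test_that("fitting is deterministic and tolerates all-missing features", {
  cohort <- make_toy_cohort(n = 30L, horizon = 20L, seed = 4L)
  cfg <- dagoat_config(delta = 7L, horizon = 20L)
  m1 <- dagoat_fit(cohort, cfg)
  m2 <- dagoat_fit(cohort, cfg)
  expect_equal(m1, m2)
  # a feature with no observations at all is uninformative, others unaffected
  p <- cohort$panel
  vals <- array(NA_real_, c(n_patients(cohort), 3, p$horizon))
  vals[, 1:2, ] <- p$values
  msk <- array(0, dim(vals))
  msk[, 1:2, ] <- p$mask
  panel3 <- dagoat:::new_panel(vals, msk, p$patient_ids,
                               c(p$feature_names, "empty"), p$horizon)
  cohort3 <- assemble_cohort(panel3, cohort$peri, cohort$outcomes)
  m3 <- dagoat_fit(cohort3, cfg)
  expect_true(m3$features$empty$uninformative)
  expect_equal(m3$features$marker[c("l", "u", "raw")],
               m1$features$marker[c("l", "u", "raw")])
  # zero events is a fit error
  no_ev <- cohort
  no_ev$outcomes$onset_day <- NA_integer_
  expect_error(dagoat_fit(no_ev, cfg), "no event")
})

test_that("scores sum theta over the observed moving window", {
  cohort <- make_toy_cohort(n = 24L, horizon = 15L, seed = 5L)
  cfg <- dagoat_config(delta = 6L, horizon = 15L)
  model <- dagoat_fit(cohort, cfg)
  traj <- score_trajectories(model, cohort)
  # manual summation oracle for a couple of patients and days
  for (i in c(1L, 7L)) for (t in c(1L, 8L, 15L)) {
    rho <- nb_log_odds(model$peri_prior, cohort$peri[i, , drop = FALSE])
    total <- rho
    for (k in seq_along(model$feature_names)) {
      par <- model$features[[k]]
      for (tau in seq.int(max(1L, t - cfg$delta + 1L), t)) {
        if (cohort$panel$mask[i, k, tau] != 1) next
        total <- total + theta(cohort$panel$values[i, k, tau], tau, par,
                               cfg$gamma, cfg$smoothing)
      }
    }
    expect_equal(traj$scores[i, t], total)
    expect_equal(dagoat_score(model, cohort$panel$values[i, , ],
                              cohort$panel$mask[i, , ],
                              cohort$peri[i, , drop = FALSE], t),
                 total)
  }
  # all-dynamic-data-missing patient scores to the prior alone
  blank_vals <- array(NA_real_, dim(cohort$panel$values))
  blank_mask <- array(0, dim(cohort$panel$mask))
  expect_equal(dagoat_score(model, blank_vals[1, , ], blank_mask[1, , ],
                            cohort$peri[1, , drop = FALSE], 10L),
               nb_log_odds(model$peri_prior, cohort$peri[1, , drop = FALSE]))
  # validity flag follows the risk set
  onset <- cohort$outcomes$onset_day
  i_ev <- which(!is.na(onset))[1]
  expect_true(all(traj$valid[i_ev, onset[i_ev]:15] == 0))
})

test_that("large gamma collapses the score to the peri prior", {
  cohort <- make_toy_cohort(n = 24L, horizon = 15L, seed = 6L)
  cfg <- dagoat_config(delta = 6L, gamma = 1e9, smoothing = FALSE, horizon = 15L)
  model <- dagoat_fit(cohort, cfg)
  traj <- score_trajectories(model, cohort)
  rho <- nb_log_odds(model$peri_prior, cohort$peri)
  expect_equal(traj$scores, matrix(rho, nrow(traj$scores), ncol(traj$scores)),
               tolerance = 1e-6)
})

test_that("scoring is translation-covariant in day bookkeeping", {
  cohort <- make_toy_cohort(n = 20L, horizon = 15L, seed = 7L)
  s <- 4L
  cfg <- dagoat_config(delta = 6L, horizon = 15L)
  cfg_s <- dagoat_config(delta = 6L, horizon = 15L + s)
  # shift all measurements and outcomes by +s days
  p <- cohort$panel
  vals <- array(NA_real_, c(n_patients(cohort), 2, p$horizon + s))
  msk <- array(0, dim(vals))
  vals[, , (s + 1):(p$horizon + s)] <- p$values
  msk[, , (s + 1):(p$horizon + s)] <- p$mask
  panel_s <- dagoat:::new_panel(vals, msk, p$patient_ids, p$feature_names,
                                p$horizon + s)
  out_s <- cohort$outcomes
  out_s$onset_day <- out_s$onset_day + s
  out_s$last_observed_day <- out_s$last_observed_day + s
  cohort_s <- assemble_cohort(panel_s, cohort$peri, out_s)
  m <- dagoat_fit(cohort, cfg)
  m_s <- dagoat_fit(cohort_s, cfg_s)
  traj <- score_trajectories(m, cohort)
  traj_s <- score_trajectories(m_s, cohort_s)
  # compare on days where the shifted window does not cross the pre-shift gap
  days <- (cfg$delta + 1):15
  expect_equal(traj_s$scores[, days + s], traj$scores[, days],
               tolerance = 1e-8)
})

test_that("model serialization reloads to identical scores", {
  cohort <- make_toy_cohort(n = 20L, horizon = 12L, seed = 8L)
  cfg <- dagoat_config(delta = 5L, horizon = 12L)
  model <- dagoat_fit(cohort, cfg)
  f <- tempfile(fileext = ".json")
  write_dagoat_model(model, f)
  model2 <- read_dagoat_model(f)
  expect_equal(score_trajectories(model2, cohort)$scores,
               score_trajectories(model, cohort)$scores)
  unlink(f)
  # feature mismatch at scoring is an explicit error
  cohort_wrong <- subset_cohort(cohort, features = "marker")
  expect_error(score_trajectories(model, cohort_wrong), "feature names")
})
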
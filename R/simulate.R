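#' Define a simulation scenario
#'
#' The data-generating process draws, for each individual, p binary
#' (low/high) feature trajectories over T days from a symmetric
#' two-state random walk; a time-varying effector table converts
#' trajectories into a relative risk, which is compared to a uniform
#' draw to decide the event. Three knobs are manipulated: complexity
#' (many vs few effector features), smoothness of the effector curves,
#' and the data missing rate.
#'
#' @param complexity `"complex"` (features 1-45 are effectors) or
#'   `"simple"` (features 1-5).
#' @param smoothness `"smooth"` (multiplicative Gaussian random-walk
#'   effector curves) or `"rough"` (i.i.d. uniform).
#' @param missing_rate fraction of feature-day cells marked missing
#'   (default 0; the high-missingness condition is 0.6).
#' @param n cohort size after downsampling (default 1000).
#' @param p number of features (default 50).
#' @param T_days series length in days (default 14).
#' @param prevalence fraction of positive cases after downsampling
#'   (default 0.15).
#' @return a list of class `sim_scenario`.
#' @export
sim_scenario <- function(complexity = c("complex", "simple"),
                         smoothness = c("smooth", "rough"),
                         missing_rate = 0, n = 1000L, p = 50L,
                         T_days = 14L, prevalence = 0.15) {
  complexity <- match.arg(complexity)
  smoothness <- match.arg(smoothness)
  stopifnot(missing_rate >= 0, missing_rate < 1,
            prevalence > 0, prevalence < 1, p >= 5L, T_days >= 1L)
  structure(list(complexity = complexity, smoothness = smoothness,
                 missing_rate = missing_rate, n = as.integer(n),
                 p = as.integer(p), T_days = as.integer(T_days),
                 prevalence = prevalence),
            class = "sim_scenario")
}

#' Two-state feature random walk
#'
#' Binary low/high series with stay probability 0.7 and switch
#' probability 0.3 per step; the initial state is low or high with
#' probability 1/2 each (the chain's stationary law).
#'
#' @param T_days series length.
#' @param n_series number of independent series to draw.
#' @param stay stay probability (default 0.7).
#' @return integer matrix (`n_series` x `T_days`) of 0 (low) / 1 (high).
#' @export
simulate_feature_walk <- function(T_days, n_series = 1L, stay = 0.7) {
  x <- matrix(0L, n_series, T_days)
  x[, 1] <- as.integer(stats::runif(n_series) < 0.5)
  if (T_days > 1L)
    for (t in 2:T_days) {
      switch_now <- stats::runif(n_series) < (1 - stay)
      x[, t] <- ifelse(switch_now, 1L - x[, t - 1L], x[, t - 1L])
    }
  x
}

#' Ground-truth effector table for a scenario
#'
#' Effector features get a time curve alpha_k(t): a multiplicative
#' Gaussian random walk (step mean 1, sd 0.05, started at 1) in the
#' smooth condition, or i.i.d. uniform(0, 1) draws in the rough
#' condition; each curve is then linearly rescaled so its minimum is
#' exactly 0.3 and its maximum exactly 0.7. The contribution of the
#' high state is theta_k(high, t) = log(alpha / (1 - alpha)) and the
#' low state mirrors it: theta_k(low, t) = -theta_k(high, t). Dummy
#' features have theta identically 0.
#'
#' @param scenario a `sim_scenario`.
#' @return list with `theta_high` (p x T matrix; dummy rows all 0),
#'   `alpha` (p x T; NA for dummies) and `effectors` (integer indices).
#' @export
build_effector_table <- function(scenario) {
  p <- scenario$p; Td <- scenario$T_days
  n_eff <- if (scenario$complexity == "complex") min(45L, p) else 5L
  effectors <- seq_len(n_eff)
  alpha <- matrix(NA_real_, p, Td)
  for (k in effectors) {
    a <- if (scenario$smoothness == "smooth")
      cumprod(c(1, stats::rnorm(Td - 1L, mean = 1, sd = 0.05)))
    else stats::runif(Td)
    if (Td == 1L || max(a) == min(a)) a <- rep(0.5, Td)
    else a <- 0.3 + (a - min(a)) / (max(a) - min(a)) * 0.4
    alpha[k, ] <- a
  }
  theta_high <- matrix(0, p, Td)
  theta_high[effectors, ] <- log(alpha[effectors, , drop = FALSE] /
                                   (1 - alpha[effectors, , drop = FALSE]))
  list(theta_high = theta_high, alpha = alpha, effectors = effectors)
}

# Relative risk phi_i = sum_t sum_k theta_k(x_ik(t), t) for a block of
# individuals; x is an (n x p x T) 0/1 array, theta_high a p x T matrix.
sim_phi <- function(x, theta_high) {
  n <- dim(x)[1]
  phi <- numeric(n)
  for (k in seq_len(dim(x)[2])) {
    xk <- x[, k, , drop = FALSE]; dim(xk) <- c(n, dim(x)[3])
    sign_k <- 2 * xk - 1  # low contributes -theta_high, high +theta_high
    phi <- phi + as.vector(sign_k %*% theta_high[k, ])
  }
  phi
}

#' Simulate a cohort under a scenario
#'
#' Individuals are generated in batches: feature walks, relative risk
#' phi via the effector table, and the event indicator as
#' `uniform(0,1) < phi` (so phi <= 0 can never produce an event and
#' phi >= 1 always does). The batch stream is downsampled without
#' replacement to exactly `round(n * prevalence)` positives and the
#' complementary number of negatives. Missingness is applied last,
#' uniformly at random over feature-day cells.
#'
#' @param scenario a `sim_scenario`.
#' @param seed integer seed.
#' @param max_batches oversampling cap: at most `max_batches * n`
#'   individuals are generated before giving up.
#' @return list of class `sim_cohort`: `x` (n x p x T 0/1 array),
#'   `mask` (same shape), `event` (0/1 vector), `phi` (realized relative
#'   risks), `truth` (effector table), `scenario`.
#' @export
simulate_cohort <- function(scenario, seed = 1L, max_batches = 100L) {
  set.seed(seed)
  truth <- build_effector_table(scenario)
  n <- scenario$n; p <- scenario$p; Td <- scenario$T_days
  need_pos <- as.integer(round(n * scenario$prevalence))
  need_neg <- n - need_pos
  pos_x <- list(); neg_x <- list()
  pos_phi <- list(); neg_phi <- list()
  got_pos <- 0L; got_neg <- 0L
  for (b in seq_len(max_batches)) {
    walks <- simulate_feature_walk(Td, n_series = n * p)
    x <- array(walks, c(n, p, Td))
    phi <- sim_phi(x, truth$theta_high)
    ev <- stats::runif(n) < phi
    if (got_pos < need_pos && any(ev)) {
      take <- which(ev)[seq_len(min(sum(ev), need_pos - got_pos))]
      pos_x[[length(pos_x) + 1L]] <- x[take, , , drop = FALSE]
      pos_phi[[length(pos_phi) + 1L]] <- phi[take]
      got_pos <- got_pos + length(take)
    }
    if (got_neg < need_neg && any(!ev)) {
      take <- which(!ev)[seq_len(min(sum(!ev), need_neg - got_neg))]
      neg_x[[length(neg_x) + 1L]] <- x[take, , , drop = FALSE]
      neg_phi[[length(neg_phi) + 1L]] <- phi[take]
      got_neg <- got_neg + length(take)
    }
    if (got_pos >= need_pos && got_neg >= need_neg) break
  }
  if (got_pos < need_pos || got_neg < need_neg)
    stop("simulate_cohort: oversampling budget exhausted (",
         got_pos, "/", need_pos, " positives, ",
         got_neg, "/", need_neg, " negatives)")
  bind3 <- function(lst) {
    out <- array(0L, c(sum(vapply(lst, function(a) dim(a)[1], integer(1))), p, Td))
    at <- 0L
    for (a in lst) {
      out[at + seq_len(dim(a)[1]), , ] <- a
      at <- at + dim(a)[1]
    }
    out
  }
  x <- bind3(c(pos_x, neg_x))
  phi <- c(unlist(pos_phi), unlist(neg_phi))
  event <- c(rep(1L, need_pos), rep(0L, need_neg))
  # shuffle so class blocks are not ordered
  ord <- sample.int(n)
  x <- x[ord, , , drop = FALSE]; phi <- phi[ord]; event <- event[ord]
  mask <- array(1, c(n, p, Td))
  if (scenario$missing_rate > 0) {
    drop <- stats::runif(n * p * Td) < scenario$missing_rate
    mask[drop] <- 0
  }
  structure(list(x = x, mask = mask, event = event, phi = phi,
                 truth = truth, scenario = scenario),
            class = "sim_cohort")
}

#' Convert a simulated cohort into a `dagoat_cohort`
#'
#' Binary states become numeric 0/1 panel values. Positives receive a
#' nominal onset day T + 1 so that, with `delta = T`, the moving-window
#' label equals the static event indicator on every day, matching the
#' simulation's single end-of-series outcome. The peri table is empty,
#' so the prior reduces to the class-prior log-odds.
#'
#' @param sim a `sim_cohort`.
#' @param ids optional patient id vector.
#' @return a `dagoat_cohort` with horizon T + delta territory handled by
#'   the label convention.
#' @export
sim_to_cohort <- function(sim, ids = NULL) {
  n <- dim(sim$x)[1]; p <- dim(sim$x)[2]; Td <- dim(sim$x)[3]
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  # panel gets one trailing all-missing day so the nominal onset day
  # T + 1 sits inside both the observation span and the label window
  values <- array(NA_real_, c(n, p, Td + 1L))
  values[, , seq_len(Td)] <- as.numeric(sim$x)
  mask <- array(0, c(n, p, Td + 1L))
  mask[, , seq_len(Td)] <- sim$mask
  values[mask == 0] <- NA_real_
  panel <- new_panel(values, mask, ids, sprintf("f%02d", seq_len(p)), Td + 1L)
  outcomes <- data.frame(
    patient_id = ids,
    onset_day = ifelse(sim$event == 1L, Td + 1L, NA_integer_),
    last_observed_day = Td + 1L)
  peri <- data.frame(patient_id = ids)
  assemble_cohort(panel, peri, outcomes)
}

#' Moving-window config matched to a simulated cohort
#'
#' delta = T and horizon = T + 1 so that day-T scores target onset at
#' T + 1 (the simulated event) and every earlier day carries the same
#' static label.
#'
#' @param sim a `sim_cohort`.
#' @param gamma,smoothing model settings.
#' @return a `dagoat_config`.
#' @export
sim_config <- function(sim, gamma = 0.1, smoothing = TRUE) {
  Td <- sim$scenario$T_days
  dagoat_config(delta = Td, gamma = gamma, smoothing = smoothing,
                horizon = Td + 1L)
}

#' Run the scenario grid
#'
#' For every scenario, replicate, and model: simulate a cohort, split
#' 80:20 at random into training and holdout, fit, and record holdout
#' AUROC and AUPRC of the end-of-series risk scores against the event
#' labels. Seeds are derived deterministically from the base seed,
#' scenario index and replicate.
#'
#' Models: `"dagoat"` (smoothing on), `"dagoat_nosmooth"`, `"xgboost"`
#' (flattened window, native missing handling), `"oracle"` (scores from
#' the true effector table over observed cells).
#'
#' @param scenarios list of `sim_scenario` objects.
#' @param models character vector of model names.
#' @param reps replicates per scenario.
#' @param seed base integer seed.
#' @return data frame: scenario knobs, `model`, `rep`, `auroc`, `auprc`.
#' @export
run_scenario_grid <- function(scenarios,
                              models = c("dagoat", "xgboost"),
                              reps = 5L, seed = 1L) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  rows <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    for (r in seq_len(reps)) {
      rep_seed <- as.integer((as.numeric(seed) * 997 + si * 131 + r * 7) %%
                               2147483647)
      sim <- simulate_cohort(sc, seed = rep_seed)
      cohort <- sim_to_cohort(sim)
      cfg <- sim_config(sim)
      n <- sc$n
      set.seed(rep_seed + 1L)
      test_idx <- sort(sample.int(n, round(0.2 * n)))
      train_idx <- setdiff(seq_len(n), test_idx)
      train <- subset_cohort(cohort, train_idx)
      test <- subset_cohort(cohort, test_idx)
      y_test <- sim$event[test_idx]
      for (mod in models) {
        s <- scenario_model_scores(mod, sim, train, test, cfg,
                                   seed = rep_seed + 2L,
                                   test_idx = test_idx)
        rows[[length(rows) + 1L]] <- data.frame(
          complexity = sc$complexity, smoothness = sc$smoothness,
          missing_rate = sc$missing_rate, n = sc$n, model = mod, rep = r,
          auroc = auroc(s, y_test), auprc = auprc(s, y_test))
      }
    }
  }
  do.call(rbind, rows)
}

# Holdout scores at the end-of-series day for one model.
scenario_model_scores <- function(model, sim, train, test, cfg, seed,
                                  test_idx) {
  Td <- sim$scenario$T_days
  if (model == "dagoat" || model == "dagoat_nosmooth") {
    cfg$smoothing <- model == "dagoat"
    fit <- dagoat_fit(train, cfg)
    traj <- score_trajectories(fit, test)
    return(traj$scores[, Td])
  }
  if (model == "xgboost") {
    scorer <- fit_benchmark("xgboost", train, t = Td, config = cfg,
                            seed = seed)
    if (is.null(scorer)) return(rep(NA_real_, n_patients(test)))
    return(scorer(test))
  }
  if (model == "oracle") {
    x <- sim$x[test_idx, , , drop = FALSE]
    m <- sim$mask[test_idx, , , drop = FALSE]
    n <- length(test_idx)
    phi <- numeric(n)
    th <- sim$truth$theta_high
    for (k in seq_len(dim(x)[2])) {
      xk <- x[, k, , drop = FALSE]; dim(xk) <- c(n, Td)
      mk <- m[, k, , drop = FALSE]; dim(mk) <- c(n, Td)
      contrib <- (2 * xk - 1) * matrix(th[k, ], n, Td, byrow = TRUE)
      phi <- phi + rowSums(contrib * mk)
    }
    return(phi)
  }
  stop("unknown model: ", model)
}

#' The eight-scenario grid
#'
#' All combinations of complexity (complex/simple), smoothness
#' (smooth/rough) and missing rate (0 / 0.6).
#'
#' @param n,prevalence cohort settings passed to each scenario.
#' @return list of eight `sim_scenario` objects.
#' @export
scenario_grid <- function(n = 1000L, prevalence = 0.15) {
  grid <- expand.grid(complexity = c("complex", "simple"),
                      smoothness = c("smooth", "rough"),
                      missing_rate = c(0, 0.6), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    sim_scenario(grid$complexity[i], grid$smoothness[i],
                 grid$missing_rate[i], n = n, prevalence = prevalence))
}
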
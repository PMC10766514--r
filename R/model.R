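#' Model configuration
#'
#' @param delta moving-window length in days (default 14): the score at
#'   day t targets event onset between t+1 and t+delta.
#' @param gamma nonnegative regularizer added to both numerator and
#'   denominator of every bin-probability ratio (default 0.1). Large
#'   gamma shrinks all dynamic contributions toward 0.
#' @param smoothing if `TRUE` (default), per-day bin probabilities are
#'   replaced by smoothing-spline estimates along the day axis.
#' @param horizon last day modelled (default 100).
#' @return a list of class `dagoat_config`.
#' @export
dagoat_config <- function(delta = 14L, gamma = 0.1, smoothing = TRUE,
                          horizon = 100L) {
  stopifnot(delta >= 1, gamma >= 0, horizon >= 1)
  structure(list(delta = as.integer(delta), gamma = as.numeric(gamma),
                 smoothing = isTRUE(smoothing), horizon = as.integer(horizon)),
            class = "dagoat_config")
}

#' Risk set and moving-window outcome labels at a given day
#'
#' A patient is in the risk set at day t if onset has not yet occurred
#' (no onset, or onset after t) and the patient is still under
#' observation (`last_observed_day >= t`). The binary label is 1 if
#' onset falls in the window `[t+1, min(t+delta, horizon)]`.
#'
#' @param cohort a `dagoat_cohort`.
#' @param t day (1-based).
#' @param delta window length.
#' @param horizon last day labels can refer to.
#' @return list with logical `at_risk` and integer `y` (NA outside the
#'   risk set), both in cohort patient order.
#' @export
window_labels <- function(cohort, t, delta,
                          horizon = cohort$panel$horizon) {
  o <- cohort$outcomes
  at_risk <- (is.na(o$onset_day) | o$onset_day > t) & o$last_observed_day >= t
  upper <- min(t + delta, horizon)
  y <- ifelse(!is.na(o$onset_day) & o$onset_day >= t + 1 & o$onset_day <= upper,
              1L, 0L)
  y[!at_risk] <- NA_integer_
  list(at_risk = at_risk, y = y)
}

# Shannon mutual information (nats) between a binary split and binary
# labels, from the 2x2 counts. Zero cells contribute zero by convention.
binary_mi <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  cells <- c(n11, n10, n01, n00)
  rows <- c(n11 + n10, n01 + n00)  # split margin
  cols <- c(n11 + n01, n10 + n00)  # label margin
  expct <- c(rows[1] * cols[1], rows[1] * cols[2],
             rows[2] * cols[1], rows[2] * cols[2]) / n
  pos <- cells > 0
  sum(cells[pos] / n * log(cells[pos] / expct[pos]))
}

#' Mutual-information-maximizing cutoff for one variable on one day
#'
#' Searches the candidate cutoffs (midpoints between consecutive sorted
#' distinct values) for the threshold c maximizing Shannon's mutual
#' information between the indicator `value > c` and the binary outcome.
#' Ties are broken toward the smallest candidate so fits are
#' deterministic.
#'
#' @param values numeric vector of observed values.
#' @param labels matched 0/1 outcome vector.
#' @return the cutoff, or `NA_real_` when undefined (fewer than two
#'   distinct values, or single-class labels).
#' @export
best_cutoff <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  v <- sort(unique(values))
  if (length(v) < 2L || length(unique(labels)) < 2L) return(NA_real_)
  cands <- (v[-1] + v[-length(v)]) / 2
  ord <- order(values)
  xs <- values[ord]; ys <- labels[ord]
  n <- length(xs); n1 <- sum(ys)
  # counts below each candidate via cumulative sums at distinct-value blocks
  cum1 <- cumsum(ys); cumn <- seq_len(n)
  # index of last observation <= each candidate
  pos <- findInterval(cands, xs)
  below1 <- cum1[pos]; below <- cumn[pos]
  mi <- vapply(seq_along(cands), function(j) {
    b1 <- below1[j]; b0 <- below[j] - b1
    a1 <- n1 - b1; a0 <- (n - below[j]) - a1
    binary_mi(a1, a0, b1, b0)  # above-cutoff split vs label
  }, numeric(1))
  cands[which.max(mi)]  # which.max returns the first (smallest) maximizer
}

#' Per-day cutoffs and pooled discretization thresholds for one feature
#'
#' For every day t, the cutoff maximizing mutual information between the
#' feature (among risk-set patients observed that day) and onset within
#' the next `delta` days is computed; the lower and upper discretization
#' thresholds l and u are the 25th and 75th percentiles (linear
#' interpolation) of the defined per-day cutoffs.
#'
#' @param cohort a `dagoat_cohort`.
#' @param feature feature name.
#' @param config a `dagoat_config`.
#' @return list with `l`, `u`, `cutoffs` (length-horizon numeric, NA
#'   where undefined) and `uninformative` flag (no day had a defined
#'   cutoff).
#' @export
fit_thresholds <- function(cohort, feature, config = dagoat_config()) {
  k <- match(feature, cohort$panel$feature_names)
  if (is.na(k)) stop("unknown feature: ", feature)
  horizon <- config$horizon
  cutoffs <- rep(NA_real_, horizon)
  for (t in seq_len(horizon)) {
    lab <- window_labels(cohort, t, config$delta, horizon)
    obs <- lab$at_risk & cohort$panel$mask[, k, t] == 1
    if (!any(obs)) next
    cutoffs[t] <- best_cutoff(cohort$panel$values[obs, k, t], lab$y[obs])
  }
  defined <- !is.na(cutoffs)
  if (!any(defined))
    return(list(l = NA_real_, u = NA_real_, cutoffs = cutoffs,
                uninformative = TRUE))
  qs <- stats::quantile(cutoffs[defined], c(0.25, 0.75), names = FALSE, type = 7)
  list(l = qs[1], u = qs[2], cutoffs = cutoffs, uninformative = FALSE)
}

#' Raw per-day conditional bin probabilities for one feature
#'
#' For each day t and among risk-set patients with the feature observed
#' that day, estimates P(x < l | Y), P(x > u | Y) for Y = 1 (onset in
#' the next delta days) and Y = 0. Days with no observed patient in a
#' class leave that class's probabilities undefined (`NA`).
#'
#' @inheritParams fit_thresholds
#' @param l,u discretization thresholds.
#' @return a 4 x horizon matrix with rows `p1L`, `p1H`, `p0L`, `p0H`.
#' @export
fit_bin_probs <- function(cohort, feature, l, u, config = dagoat_config()) {
  k <- match(feature, cohort$panel$feature_names)
  if (is.na(k)) stop("unknown feature: ", feature)
  horizon <- config$horizon
  out <- matrix(NA_real_, 4L, horizon,
                dimnames = list(c("p1L", "p1H", "p0L", "p0H"), NULL))
  for (t in seq_len(horizon)) {
    lab <- window_labels(cohort, t, config$delta, horizon)
    obs <- lab$at_risk & cohort$panel$mask[, k, t] == 1
    if (!any(obs)) next
    x <- cohort$panel$values[obs, k, t]
    y <- lab$y[obs]
    for (cls in c(1L, 0L)) {
      sel <- y == cls
      if (!any(sel)) next
      rows <- if (cls == 1L) c("p1L", "p1H") else c("p0L", "p0H")
      out[rows[1], t] <- mean(x[sel] < l)
      out[rows[2], t] <- mean(x[sel] > u)
    }
  }
  out
}

#' Smooth a per-day probability series along the day axis
#'
#' Fits a cubic smoothing spline (smoothness chosen by generalized
#' cross-validation) through the days where the raw series is defined
#' and evaluates it at every day 1..horizon, extrapolating beyond the
#' observed range. Values may stray outside [0, 1]; clamping happens
#' later, inside the contribution function. With fewer than four defined
#' days the series is replaced by the constant mean of the defined
#' values; with none, it stays all-`NA`.
#'
#' @param raw numeric vector (length horizon) with `NA` where undefined.
#' @param horizon number of days to evaluate.
#' @return numeric vector of length `horizon`.
#' @export
smooth_probs <- function(raw, horizon = length(raw)) {
  defined <- which(!is.na(raw))
  if (length(defined) == 0L) return(rep(NA_real_, horizon))
  if (length(defined) < 4L || length(unique(raw[defined])) == 1L)
    return(rep(mean(raw[defined]), horizon))
  fit <- tryCatch(
    stats::smooth.spline(defined, raw[defined], cv = FALSE, keep.data = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(rep(mean(raw[defined]), horizon))
  stats::predict(fit, seq_len(horizon))$y
}

#' Per-bin time-varying contribution of one dynamic feature
#'
#' The contribution of an observed value x at day t is the log-ratio of
#' gamma-floored class-conditional bin probabilities for the bin
#' containing x: low (x < l), middle (l <= x <= u, using
#' max(0, 1 - pL - pH) per class) or high (x > u). Spline estimates are
#' clamped at 0 before the gamma floor is added.
#'
#' @param x observed value.
#' @param t day.
#' @param params feature parameter list holding `l`, `u`, `raw`,
#'   `smooth` (4 x horizon matrices) and `uninformative`.
#' @param gamma regularizer.
#' @param smoothing use smoothed (`TRUE`) or raw (`FALSE`) probability
#'   series. Undefined raw probabilities yield a contribution of 0.
#' @return the contribution (0 for uninformative features or undefined
#'   probabilities).
#' @export
theta <- function(x, t, params, gamma = 0.1, smoothing = TRUE) {
  if (isTRUE(params$uninformative)) return(0)
  tab <- theta_table(params, gamma, smoothing)
  bin <- if (x < params$l) 1L else if (x <= params$u) 2L else 3L
  unname(tab[bin, t])
}

# 3 x horizon matrix of contributions (rows: low, mid, high bins).
# Undefined entries are 0: a feature-day with no probability estimate
# contributes nothing.
theta_table <- function(params, gamma, smoothing) {
  horizon <- ncol(params$raw)
  if (isTRUE(params$uninformative))
    return(matrix(0, 3L, horizon))
  p <- if (smoothing) params$smooth else params$raw
  p1L <- p["p1L", ]; p1H <- p["p1H", ]; p0L <- p["p0L", ]; p0H <- p["p0H", ]
  lr <- function(num, den) log((pmax(0, num) + gamma) / (pmax(0, den) + gamma))
  out <- rbind(low = lr(p1L, p0L),
               mid = lr(1 - p1L - p1H, 1 - p0L - p0H),
               high = lr(p1H, p0H))
  out[is.na(out)] <- 0
  out
}

#' Fit the daGOAT model
#'
#' Fitting proceeds in the order: (1) the peri-transplantation prior
#' rho(z) as the Naive Bayes log-odds against the static outcome "onset
#' within the horizon"; (2) per feature, the per-day mutual-information
#' cutoffs pooled into thresholds l, u; (3) per feature, raw per-day
#' conditional bin probabilities; (4) smoothing-spline versions of each
#' probability series. The fit is deterministic given cohort and config.
#'
#' @param cohort a `dagoat_cohort` with at least one event.
#' @param config a `dagoat_config`.
#' @param verbose message per-feature fit summaries.
#' @return an object of class `dagoat_model`.
#' @export
dagoat_fit <- function(cohort, config = dagoat_config(), verbose = FALSE) {
  stopifnot(inherits(cohort, "dagoat_cohort"))
  event <- !is.na(cohort$outcomes$onset_day) &
    cohort$outcomes$onset_day <= config$horizon
  if (!any(event)) stop("cannot fit: cohort contains no event")
  peri_prior <- if (all(event)) NULL else
    fit_nb(cohort$peri, as.integer(event))
  features <- vector("list", length(cohort$panel$feature_names))
  names(features) <- cohort$panel$feature_names
  for (feat in cohort$panel$feature_names) {
    th <- fit_thresholds(cohort, feat, config)
    if (th$uninformative) {
      features[[feat]] <- list(l = NA_real_, u = NA_real_,
                               cutoffs = th$cutoffs,
                               raw = matrix(NA_real_, 4L, config$horizon,
                                            dimnames = list(c("p1L", "p1H", "p0L", "p0H"), NULL)),
                               smooth = matrix(NA_real_, 4L, config$horizon,
                                               dimnames = list(c("p1L", "p1H", "p0L", "p0H"), NULL)),
                               uninformative = TRUE)
      if (verbose) message("dagoat_fit: feature '", feat, "' uninformative")
      next
    }
    raw <- fit_bin_probs(cohort, feat, th$l, th$u, config)
    smth <- t(apply(raw, 1, smooth_probs, horizon = config$horizon))
    dimnames(smth) <- dimnames(raw)
    features[[feat]] <- list(l = th$l, u = th$u, cutoffs = th$cutoffs,
                             raw = raw, smooth = smth, uninformative = FALSE)
    if (verbose)
      message(sprintf("dagoat_fit: '%s' l=%.4g u=%.4g (%d/%d days with cutoff)",
                      feat, th$l, th$u, sum(!is.na(th$cutoffs)), config$horizon))
  }
  structure(list(config = config, features = features,
                 feature_names = cohort$panel$feature_names,
                 peri_prior = peri_prior),
            class = "dagoat_model")
}

#' @export
print.dagoat_model <- function(x, ...) {
  n_un <- sum(vapply(x$features, function(f) isTRUE(f$uninformative), logical(1)))
  cat("dagoat_model:", length(x$features), "dynamic features (",
      n_un, "uninformative ), delta =", x$config$delta,
      ", gamma =", x$config$gamma,
      ", smoothing =", x$config$smoothing, "\n")
  invisible(x)
}

#' Score one patient at one day
#'
#' The risk score is the peri prior rho(z) plus the sum of per-feature
#' contributions over all observed (mask = 1) feature-day cells in the
#' window `[max(1, t - delta + 1), t]`; missing cells contribute exactly
#' 0.
#'
#' @param model a fitted `dagoat_model`.
#' @param values,mask feature x day matrices for one patient (rows in
#'   model feature order).
#' @param peri_row one-row data frame of peri features (or `NULL`).
#' @param t day at which to score.
#' @return the risk score phi(t).
#' @export
dagoat_score <- function(model, values, mask, peri_row = NULL, t) {
  stopifnot(t >= 1)
  cfg <- model$config
  rho <- if (is.null(model$peri_prior)) 0 else
    nb_log_odds(model$peri_prior, peri_row)
  window <- seq.int(max(1L, t - cfg$delta + 1L), min(t, cfg$horizon))
  total <- rho
  for (k in seq_along(model$feature_names)) {
    par <- model$features[[k]]
    if (isTRUE(par$uninformative)) next
    tab <- theta_table(par, cfg$gamma, cfg$smoothing)
    for (tau in window) {
      if (mask[k, tau] != 1) next
      x <- values[k, tau]
      bin <- if (x < par$l) 1L else if (x <= par$u) 2L else 3L
      total <- total + unname(tab[bin, tau])
    }
  }
  total
}

#' Score every patient on every day
#'
#' Vectorized scoring of a whole cohort: phi_i(t) for all patients and
#' days 1..horizon, plus the risk-set validity flag from
#' [window_labels()].
#'
#' @param model a fitted `dagoat_model`.
#' @param cohort a `dagoat_cohort` whose features match the model's.
#' @return an object of class `dagoat_trajectory`: list with `scores`
#'   and `valid` (patient x day matrices) and `patient_ids`.
#' @export
score_trajectories <- function(model, cohort) {
  if (!identical(model$feature_names, cohort$panel$feature_names))
    stop("feature names of model and cohort differ")
  cfg <- model$config
  np <- n_patients(cohort); horizon <- cfg$horizon
  if (cohort$panel$horizon < horizon)
    stop("cohort panel horizon (", cohort$panel$horizon,
         ") shorter than model horizon (", horizon, ")")
  rho <- if (is.null(model$peri_prior)) rep(0, np) else
    nb_log_odds(model$peri_prior, cohort$peri)
  # per-day summed contribution A[i, tau] over all features
  A <- matrix(0, np, horizon)
  for (k in seq_along(model$feature_names)) {
    par <- model$features[[k]]
    if (isTRUE(par$uninformative)) next
    tab <- theta_table(par, cfg$gamma, cfg$smoothing)
    vals <- cohort$panel$values[, k, seq_len(horizon), drop = FALSE]
    dim(vals) <- c(np, horizon)
    msk <- cohort$panel$mask[, k, seq_len(horizon), drop = FALSE]
    dim(msk) <- c(np, horizon)
    bin <- matrix(2L, np, horizon)
    bin[vals < par$l] <- 1L
    bin[vals > par$u] <- 3L
    day_idx <- matrix(rep(seq_len(horizon), each = np), np, horizon)
    contrib <- matrix(tab[cbind(as.vector(bin), as.vector(day_idx))], np, horizon)
    contrib[msk != 1 | is.na(vals)] <- 0
    A <- A + contrib
  }
  # windowed cumulative sum: phi(t) = rho + sum_{tau = t-delta+1}^{t} A[, tau]
  cs <- cbind(0, t(apply(A, 1, cumsum)))
  scores <- matrix(NA_real_, np, horizon)
  for (t in seq_len(horizon)) {
    lo <- max(1L, t - cfg$delta + 1L)
    scores[, t] <- rho + cs[, t + 1L] - cs[, lo]
  }
  valid <- matrix(0L, np, horizon)
  for (t in seq_len(horizon))
    valid[, t] <- as.integer(window_labels(cohort, t, cfg$delta, horizon)$at_risk)
  structure(list(scores = scores, valid = valid,
                 patient_ids = cohort$panel$patient_ids),
            class = "dagoat_trajectory")
}

#' @export
print.dagoat_trajectory <- function(x, ...) {
  cat("dagoat_trajectory:", nrow(x$scores), "patients x",
      ncol(x$scores), "days\n")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

#' Save / load a fitted model as JSON
#'
#' All numeric parameters are written with 17 significant digits so a
#' reloaded model reproduces scores exactly.
#'
#' @param model a `dagoat_model`.
#' @param path file path.
#' @return `write_dagoat_model` returns `path` invisibly;
#'   `read_dagoat_model` returns a `dagoat_model`.
#' @export
write_dagoat_model <- function(model, path) {
  ser <- list(
    config = unclass(model$config),
    feature_names = model$feature_names,
    features = lapply(model$features, function(f)
      list(l = f$l, u = f$u, cutoffs = f$cutoffs,
           raw = as.data.frame(t(f$raw)), smooth = as.data.frame(t(f$smooth)),
           uninformative = isTRUE(f$uninformative))),
    peri_prior = if (is.null(model$peri_prior)) NULL else
      serialize_nb(model$peri_prior))
  writeLines(jsonlite::toJSON(ser, digits = I(17), null = "null", na = "null",
                              auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_dagoat_model
#' @export
read_dagoat_model <- function(path) {
  ser <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- dagoat_config(ser$config$delta, ser$config$gamma,
                       ser$config$smoothing, ser$config$horizon)
  feats <- lapply(ser$features, function(f) {
    raw <- t(as.matrix(as.data.frame(f$raw)))
    smth <- t(as.matrix(as.data.frame(f$smooth)))
    rownames(raw) <- rownames(smth) <- c("p1L", "p1H", "p0L", "p0H")
    list(l = null2na(f$l), u = null2na(f$u),
         cutoffs = as.numeric(f$cutoffs),
         raw = raw, smooth = smth,
         uninformative = isTRUE(f$uninformative))
  })
  names(feats) <- ser$feature_names
  structure(list(config = cfg, features = feats,
                 feature_names = as.character(ser$feature_names),
                 peri_prior = if (is.null(ser$peri_prior)) NULL else
                   deserialize_nb(ser$peri_prior)),
            class = "dagoat_model")
}

null2na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
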
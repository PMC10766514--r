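#' Area under the ROC curve
#'
#' Rank-based AUROC with midrank handling of tied scores (equivalent to
#' the Mann-Whitney U statistic scaled to [0, 1]).
#'
#' @param scores numeric predictions (higher = riskier).
#' @param labels matched 0/1 outcomes.
#' @return AUROC in [0, 1], or `NA_real_` when only one class is
#'   present.
#' @export
auroc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision with step interpolation: thresholds are the
#' distinct score values in decreasing order, and each threshold
#' contributes its recall increment times the precision attained there.
#' Tied scores enter as one block. Constant scores therefore give the
#' outcome prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in [0, 1], or `NA_real_` when only one class is
#'   present.
#' @export
auprc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  n1 <- sum(labels == 1L)
  if (n1 == 0L || all(labels == 1L)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  block_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[block_end]
  pred_pos <- block_end
  precision <- tp / pred_pos
  recall <- tp / n1
  d_recall <- diff(c(0, recall))
  sum(d_recall * precision)
}

#' Percentile bootstrap confidence interval for a score-based metric
#'
#' Resamples patients with replacement; resamples containing a single
#' outcome class are skipped.
#'
#' @param metric function of `(scores, labels)` returning a scalar.
#' @param scores,labels data to resample.
#' @param B number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return named numeric `c(lo, hi)` (NA when no usable resample).
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 1000L, level = 0.95,
                         seed = 1L) {
  stopifnot(B >= 1)
  n <- length(scores)
  set.seed(seed)
  stats_b <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[idx])) < 2L) next
    stats_b[b] <- metric(scores[idx], labels[idx])
  }
  stats_b <- stats_b[!is.na(stats_b)]
  if (!length(stats_b)) return(c(lo = NA_real_, hi = NA_real_))
  alpha <- (1 - level) / 2
  q <- stats::quantile(stats_b, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Daily discrimination metrics along a risk trajectory
#'
#' For every day t, computes AUROC and AUPRC over risk-set patients,
#' with the moving-window outcome "onset within (t, t + delta]". Days
#' where only one class is present leave the metrics undefined.
#'
#' @param trajectory a `dagoat_trajectory`.
#' @param cohort the matching `dagoat_cohort`.
#' @param config a `dagoat_config`.
#' @param boot if `TRUE`, add percentile-bootstrap CI bounds per day.
#' @param B,level,seed bootstrap settings (see [bootstrap_ci()]).
#' @return data frame with one row per day: `day`, `n_at_risk`,
#'   `n_positive`, `auroc`, `auprc` (and `auroc_lo/hi`, `auprc_lo/hi`
#'   when `boot`).
#' @export
daily_metrics <- function(trajectory, cohort, config = dagoat_config(),
                          boot = FALSE, B = 1000L, level = 0.95, seed = 1L) {
  stopifnot(nrow(trajectory$scores) == n_patients(cohort))
  horizon <- min(ncol(trajectory$scores), config$horizon)
  out <- data.frame(day = seq_len(horizon), n_at_risk = 0L, n_positive = 0L,
                    auroc = NA_real_, auprc = NA_real_)
  if (boot)
    out[c("auroc_lo", "auroc_hi", "auprc_lo", "auprc_hi")] <- NA_real_
  for (t in seq_len(horizon)) {
    lab <- window_labels(cohort, t, config$delta, config$horizon)
    use <- lab$at_risk & trajectory$valid[, t] == 1 & !is.na(trajectory$scores[, t])
    y <- lab$y[use]; s <- trajectory$scores[use, t]
    out$n_at_risk[t] <- sum(use)
    out$n_positive[t] <- sum(y == 1L)
    out$auroc[t] <- auroc(s, y)
    out$auprc[t] <- auprc(s, y)
    if (boot && !is.na(out$auroc[t])) {
      ci1 <- bootstrap_ci(auroc, s, y, B = B, level = level, seed = seed + t)
      ci2 <- bootstrap_ci(auprc, s, y, B = B, level = level, seed = seed + t)
      out$auroc_lo[t] <- ci1[1]; out$auroc_hi[t] <- ci1[2]
      out$auprc_lo[t] <- ci2[1]; out$auprc_hi[t] <- ci2[2]
    }
  }
  out
}

#' Hazard ratio between top-sextile and bottom-5/6 risk groups
#'
#' Splits risk-set patients at the 5/6 quantile of their day-t scores
#' (strictly greater than the quantile puts a patient in the high-risk
#' group) and fits an unadjusted Cox proportional-hazards comparison of
#' onset within the ensuing `delta`-day window, censoring at window end
#' or loss to follow-up. When either group has zero events the ratio is
#' flagged incalculable.
#'
#' @param scores day-t risk scores, in cohort patient order.
#' @param cohort a `dagoat_cohort`.
#' @param t anchor day.
#' @param config a `dagoat_config`.
#' @return list with `hr`, `ci` (length-2), `n_high`, `n_low`,
#'   `events_high`, `events_low`, `incalculable` flag.
#' @export
sextile_hazard_ratio <- function(scores, cohort, t, config = dagoat_config()) {
  lab <- window_labels(cohort, t, config$delta, config$horizon)
  use <- lab$at_risk & !is.na(scores)
  if (sum(use) < 6L) return(list(hr = NA_real_, ci = c(NA_real_, NA_real_),
                                 incalculable = TRUE, reason = "fewer than 6 patients"))
  s <- scores[use]
  o <- cohort$outcomes[use, , drop = FALSE]
  cut <- stats::quantile(s, 5 / 6, names = FALSE, type = 7)
  high <- s > cut
  end <- pmin(t + config$delta, o$last_observed_day)
  onset_in <- !is.na(o$onset_day) & o$onset_day >= t + 1 &
    o$onset_day <= pmin(t + config$delta, o$last_observed_day)
  time <- ifelse(onset_in, o$onset_day - t, pmax(end - t, 1L))
  event <- as.integer(onset_in)
  res <- list(n_high = sum(high), n_low = sum(!high),
              events_high = sum(event[high]), events_low = sum(event[!high]))
  if (res$events_high == 0L || res$events_low == 0L || !any(high) || all(high))
    return(c(res, list(hr = NA_real_, ci = c(NA_real_, NA_real_),
                       incalculable = TRUE, reason = "zero events in a group")))
  fit <- survival::coxph(survival::Surv(time, event) ~ high)
  sm <- summary(fit)
  c(res, list(hr = unname(sm$conf.int[1, "exp(coef)"]),
              ci = unname(sm$conf.int[1, c("lower .95", "upper .95")]),
              incalculable = FALSE, reason = NA_character_))
}

#' Expanding-window temporal cross-validation plan
#'
#' Patients are taken in their cohort order (assumed temporal, for
#' example by transplant date). The cohort is divided into `n_folds`
#' consecutive blocks; fold j (j = 2..n_folds) trains on blocks 1..j-1
#' and validates on block j, so train sets strictly grow and validation
#' blocks partition everything after the seed block.
#'
#' @param cohort a `dagoat_cohort`.
#' @param n_folds number of temporal blocks (default 5).
#' @return list of `list(train = ids, validation = ids)` of length
#'   `n_folds - 1`.
#' @export
temporal_cv <- function(cohort, n_folds = 5L) {
  ids <- cohort$panel$patient_ids
  n <- length(ids)
  if (n < n_folds) stop("fewer patients (", n, ") than folds (", n_folds, ")")
  block <- cut(seq_len(n), n_folds, labels = FALSE)
  lapply(seq.int(2L, n_folds), function(j)
    list(train = ids[block < j], validation = ids[block == j]))
}

# Pooled out-of-fold daily metrics under a temporal CV plan. Each fold's
# model is fitted on its training block (optionally restricted to a
# feature subset and with smoothing toggled) and used to score its
# validation block over all days; the pooled out-of-fold scores feed
# daily AUROC/AUPRC.
internal_validation_metrics <- function(cohort, config = dagoat_config(),
                                        cv_plan = NULL, features = NULL,
                                        n_folds = 5L) {
  if (is.null(cv_plan)) cv_plan <- temporal_cv(cohort, n_folds)
  if (is.null(features)) features <- cohort$panel$feature_names
  np <- n_patients(cohort)
  scores <- matrix(NA_real_, np, config$horizon)
  valid <- matrix(0L, np, config$horizon)
  for (fold in cv_plan) {
    train <- subset_cohort(cohort, fold$train, features = features)
    model <- tryCatch(dagoat_fit(train, config), error = function(e) NULL)
    if (is.null(model)) next
    val <- subset_cohort(cohort, fold$validation, features = features)
    traj <- score_trajectories(model, val)
    rows <- match(fold$validation, cohort$panel$patient_ids)
    scores[rows, ] <- traj$scores
    valid[rows, ] <- traj$valid
  }
  traj <- structure(list(scores = scores, valid = valid,
                         patient_ids = cohort$panel$patient_ids),
                    class = "dagoat_trajectory")
  daily_metrics(traj, cohort, config)
}

#' Leave-one-feature-out importance timelines
#'
#' The importance of feature k at day t is the decrement in internally
#' validated AUPRC when the feature is ignored entirely (removed from
#' both fitting and scoring): `AUPRC_full(t) - AUPRC_without_k(t)`.
#' Importance is bounded in [-1, 1]. Also reports each feature's
#' maximum importance over days 8-30 and its average data density over
#' days 1-30.
#'
#' @param cohort a `dagoat_cohort`.
#' @param config a `dagoat_config`.
#' @param cv_plan temporal CV plan from [temporal_cv()] (default: 5
#'   folds).
#' @param n_folds folds used when `cv_plan` is `NULL`.
#' @return list of class `dagoat_importance`: `importance` (feature x
#'   day matrix), `max_8_30` (named vector), `density` (named vector),
#'   `full_metrics` (the full-model daily metrics).
#' @export
feature_importance <- function(cohort, config = dagoat_config(),
                               cv_plan = NULL, n_folds = 5L) {
  if (is.null(cv_plan)) cv_plan <- temporal_cv(cohort, n_folds)
  feats <- cohort$panel$feature_names
  full <- internal_validation_metrics(cohort, config, cv_plan)
  imp <- matrix(NA_real_, length(feats), config$horizon,
                dimnames = list(feats, NULL))
  for (f in feats) {
    rest <- internal_validation_metrics(cohort, config, cv_plan,
                                        features = setdiff(feats, f))
    imp[f, ] <- full$auprc - rest$auprc
  }
  rng <- seq.int(8L, min(30L, config$horizon))
  max_8_30 <- apply(imp[, rng, drop = FALSE], 1,
                    function(z) if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE))
  dens <- data_density(cohort$panel, seq_len(min(30L, cohort$panel$horizon)))
  structure(list(importance = imp, max_8_30 = max_8_30, density = dens,
                 full_metrics = full),
            class = "dagoat_importance")
}

#' Rank features by their maximum importance over days 8-30
#'
#' @param importance a `dagoat_importance` object (or a feature x day
#'   importance matrix).
#' @return character vector of feature names, best first; ties broken
#'   alphabetically.
#' @export
rank_features <- function(importance) {
  imp <- if (inherits(importance, "dagoat_importance"))
    importance$importance else importance
  rng <- seq.int(8L, min(30L, ncol(imp)))
  m <- apply(imp[, rng, drop = FALSE], 1,
             function(z) if (all(is.na(z))) -Inf else max(z, na.rm = TRUE))
  rownames(imp)[order(-m, rownames(imp))]
}

#' Average data density per dynamic feature
#'
#' The fraction of available (patient, day) cells per feature over a day
#' range, conventionally days 1-30 after sample-and-hold imputation.
#'
#' @param panel a `dagoat_panel` (apply [sample_and_hold()] first to
#'   match the augmented-data convention).
#' @param day_range integer days (default 1-30).
#' @return named numeric vector, one density in [0, 1] per feature.
#' @export
data_density <- function(panel, day_range = 1:30) {
  day_range <- day_range[day_range <= panel$horizon]
  m <- panel$mask[, , day_range, drop = FALSE]
  dens <- apply(m, 2, mean)
  names(dens) <- panel$feature_names
  dens
}

#' Pearson chi-square test on a 2x2 table with continuity correction
#'
#' With `continuity = TRUE` (the default), each observed count is
#' shifted toward its expected value by 0.5 (never past it) before the
#' Pearson statistic is formed; the p-value is the upper chi-square(1)
#' tail.
#'
#' @param a,b,c,d cell counts, row-wise: table `rbind(c(a, b), c(c, d))`.
#' @param continuity apply the continuity correction.
#' @return list with `statistic` and `p`.
#' @export
two_by_two_chisq <- function(a, b, c, d, continuity = TRUE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  tab <- matrix(counts, 2L, 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square undefined: zero row or column margin")
  ht <- stats::chisq.test(tab, correct = continuity)
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Paired smoothing ablation
#'
#' Runs the identical internally validated pipeline twice, toggling only
#' the smoothing flag, and returns the paired per-day metrics.
#'
#' @inheritParams feature_importance
#' @return list with data frames `smoothing_on` and `smoothing_off`.
#' @export
ablation_run <- function(cohort, config = dagoat_config(), cv_plan = NULL,
                         n_folds = 5L) {
  if (is.null(cv_plan)) cv_plan <- temporal_cv(cohort, n_folds)
  cfg_on <- config; cfg_on$smoothing <- TRUE
  cfg_off <- config; cfg_off$smoothing <- FALSE
  list(smoothing_on = internal_validation_metrics(cohort, cfg_on, cv_plan),
       smoothing_off = internal_validation_metrics(cohort, cfg_off, cv_plan))
}

#' Performance as a function of the number of top-ranked features
#'
#' Refits and rescores the model using only the top-N ranked dynamic
#' features, for each requested N, under the same internal-validation
#' plan. N = 0 is the peri-prior-only model.
#'
#' @param cohort a `dagoat_cohort`.
#' @param config a `dagoat_config`.
#' @param ranked character vector of features, best first (from
#'   [rank_features()]).
#' @param n_features integer vector of subset sizes (default: 0 to all).
#' @param cv_plan temporal CV plan.
#' @param n_folds folds used when `cv_plan` is `NULL`.
#' @return long data frame: `n_features`, `day`, `auroc`, `auprc`.
#' @export
subset_curve <- function(cohort, config = dagoat_config(), ranked,
                         n_features = NULL, cv_plan = NULL, n_folds = 5L) {
  if (is.null(cv_plan)) cv_plan <- temporal_cv(cohort, n_folds)
  if (is.null(n_features)) n_features <- seq.int(0L, length(ranked))
  out <- list()
  for (N in n_features) {
    feats <- if (N == 0L) character(0) else ranked[seq_len(N)]
    dm <- if (N == 0L) prior_only_metrics(cohort, config) else
      internal_validation_metrics(cohort, config, cv_plan, features = feats)
    out[[length(out) + 1L]] <- data.frame(n_features = N, day = dm$day,
                                          auroc = dm$auroc, auprc = dm$auprc)
  }
  do.call(rbind, out)
}

# Daily metrics for the peri-prior-only model under the same plan:
# every patient's score is the out-of-fold Naive Bayes log-odds,
# constant in time.
prior_only_metrics <- function(cohort, config, cv_plan = NULL, n_folds = 5L) {
  if (is.null(cv_plan)) cv_plan <- temporal_cv(cohort, n_folds)
  np <- n_patients(cohort)
  scores <- matrix(NA_real_, np, config$horizon)
  valid <- matrix(0L, np, config$horizon)
  for (fold in cv_plan) {
    tr_rows <- match(fold$train, cohort$panel$patient_ids)
    ev <- as.integer(!is.na(cohort$outcomes$onset_day[tr_rows]) &
                       cohort$outcomes$onset_day[tr_rows] <= config$horizon)
    if (length(unique(ev)) < 2L) next
    nb <- fit_nb(cohort$peri[tr_rows, , drop = FALSE], ev)
    rows <- match(fold$validation, cohort$panel$patient_ids)
    s <- nb_log_odds(nb, cohort$peri[rows, , drop = FALSE])
    scores[rows, ] <- matrix(s, length(rows), config$horizon)
    for (t in seq_len(config$horizon))
      valid[rows, t] <- as.integer(
        window_labels(cohort, t, config$delta, config$horizon)$at_risk[rows])
  }
  traj <- structure(list(scores = scores, valid = valid,
                         patient_ids = cohort$panel$patient_ids),
                    class = "dagoat_trajectory")
  daily_metrics(traj, cohort, config)
}
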
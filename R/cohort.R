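#' Validate a long-format measurement table
#'
#' Dynamic clinical data enter the pipeline as one row per measurement:
#' `patient_id`, `day` (1-based day post-transplant), `feature`, `value`.
#' A feature measured twice on one day simply occupies two rows.
#'
#' @param measurements data frame with columns `patient_id`, `day`,
#'   `feature`, `value`.
#' @return the validated data frame (invisibly coerced column types).
#' @export
as_measurements <- function(measurements) {
  required <- c("patient_id", "day", "feature", "value")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols))
    stop("measurement table lacks column(s): ", paste(missing_cols, collapse = ", "))
  m <- as.data.frame(measurements)[required]
  m$patient_id <- as.character(m$patient_id)
  m$feature <- as.character(m$feature)
  m$day <- as.integer(m$day)
  if (!is.numeric(measurements$value)) {
    v <- suppressWarnings(as.numeric(m$value))
    bad <- which(is.na(v) & !is.na(m$value))
    if (length(bad))
      stop("non-numeric measurement value in row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    m$value <- v
  }
  if (any(m$day < 1L, na.rm = TRUE))
    stop("measurement days must be >= 1 (1-based days post-transplant)")
  m
}

#' Blank physiologically implausible measurements
#'
#' Removes records whose value falls outside a per-feature plausibility
#' range (for example an impossibly high body temperature). Features
#' without a declared range pass through untouched. Ranges are closed:
#' values equal to a bound are kept.
#'
#' @param measurements long-format measurement table (see
#'   [as_measurements()]).
#' @param plausibility named list; each element a numeric `c(min, max)`
#'   keyed by feature name. Default `list()` blanks nothing.
#' @param verbose if `TRUE`, message the number of blanked records per
#'   feature.
#' @return the measurement table with out-of-range records removed.
#' @export
blank_outliers <- function(measurements, plausibility = list(), verbose = FALSE) {
  m <- as_measurements(measurements)
  if (!length(plausibility)) return(m)
  for (feat in names(plausibility)) {
    rng <- plausibility[[feat]]
    if (!is.numeric(rng) || length(rng) != 2L || anyNA(rng) || rng[1] > rng[2])
      stop("malformed plausibility range for feature '", feat,
           "': need numeric c(min, max) with min <= max")
  }
  drop <- rep(FALSE, nrow(m))
  for (feat in names(plausibility)) {
    rng <- plausibility[[feat]]
    sel <- m$feature == feat & (m$value < rng[1] | m$value > rng[2])
    if (verbose && any(sel))
      message("blank_outliers: dropping ", sum(sel), " record(s) of '", feat, "'")
    drop <- drop | sel
  }
  m[!drop, , drop = FALSE]
}

#' Construct a dynamic panel
#'
#' Internal constructor for the (patient x feature x day) value array and
#' its availability mask.
#'
#' @param values,mask numeric / 0-1 arrays of identical dimension
#'   `c(n_patients, n_features, horizon)`.
#' @param patient_ids,feature_names dimension labels.
#' @param horizon maximum day tracked.
#' @return an object of class `dagoat_panel`.
#' @keywords internal
new_panel <- function(values, mask, patient_ids, feature_names, horizon) {
  stopifnot(identical(dim(values), dim(mask)),
            dim(values)[1] == length(patient_ids),
            dim(values)[2] == length(feature_names),
            dim(values)[3] == horizon)
  dimnames(values) <- dimnames(mask) <-
    list(patient_ids, feature_names, as.character(seq_len(horizon)))
  structure(list(values = values, mask = mask,
                 patient_ids = as.character(patient_ids),
                 feature_names = as.character(feature_names),
                 horizon = as.integer(horizon)),
            class = "dagoat_panel")
}

#' @export
print.dagoat_panel <- function(x, ...) {
  cat("dagoat_panel:", length(x$patient_ids), "patients x",
      length(x$feature_names), "features x", x$horizon, "days;",
      sprintf("%.1f%% cells observed\n", 100 * mean(x$mask)))
  invisible(x)
}

#' Aggregate repeated same-day measurements into a daily panel
#'
#' When a dynamic variable is measured more than once on one day for one
#' patient, the day's arithmetic mean is used. The result is a dense
#' (patient x feature x day) array plus an availability mask: mask = 1
#' where at least one record exists, 0 otherwise.
#'
#' @inheritParams blank_outliers
#' @param patient_ids,feature_names optional explicit orderings; default
#'   is sorted unique values found in the data. Patients or features with
#'   no records are retained as all-missing rows when listed explicitly.
#' @param horizon maximum day kept (default 100); later records are
#'   dropped.
#' @return a `dagoat_panel`.
#' @export
aggregate_daily <- function(measurements, patient_ids = NULL,
                            feature_names = NULL, horizon = 100L) {
  m <- as_measurements(measurements)
  m <- m[m$day <= horizon, , drop = FALSE]
  if (is.null(patient_ids)) patient_ids <- sort(unique(m$patient_id))
  if (is.null(feature_names)) feature_names <- sort(unique(m$feature))
  horizon <- as.integer(horizon)
  np <- length(patient_ids); nf <- length(feature_names)
  values <- array(NA_real_, c(np, nf, horizon))
  mask <- array(0, c(np, nf, horizon))
  if (nrow(m)) {
    unknown <- setdiff(unique(m$patient_id), patient_ids)
    if (length(unknown))
      stop("measurements reference patients not in patient_ids: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    unknown_f <- setdiff(unique(m$feature), feature_names)
    if (length(unknown_f))
      stop("measurements reference unlisted features: ",
           paste(utils::head(unknown_f, 5L), collapse = ", "))
    i <- match(m$patient_id, patient_ids)
    k <- match(m$feature, feature_names)
    idx <- (m$day - 1L) * (np * nf) + (k - 1L) * np + i  # linear index
    sums <- rowsum(m$value, idx)
    cnts <- rowsum(rep(1, nrow(m)), idx)
    at <- as.integer(rownames(sums))
    values[at] <- sums / cnts
    mask[at] <- 1
  }
  new_panel(values, mask, patient_ids, feature_names, horizon)
}

#' Time-limited sample-and-hold imputation
#'
#' Carries every observed value forward for up to `hold_days` further
#' days, on the assumption that a measurement remains informative for a
#' short time after sampling. A newer observation always overrides a held
#' value; original observations are never altered. Holding can be capped
#' per patient at the last observed day so no values exist after a
#' patient leaves observation.
#'
#' @param panel a `dagoat_panel`.
#' @param hold_days days to carry a value forward (default 3; 0 is the
#'   identity).
#' @param last_observed optional named integer vector (by patient id):
#'   held values are not propagated past this day.
#' @return a `dagoat_panel` with held values filled in (mask = 1 where
#'   filled).
#' @export
sample_and_hold <- function(panel, hold_days = 3L, last_observed = NULL) {
  stopifnot(inherits(panel, "dagoat_panel"), hold_days >= 0)
  hold_days <- as.integer(hold_days)
  if (hold_days == 0L) return(panel)
  values <- panel$values; mask <- panel$mask
  horizon <- panel$horizon
  obs_mask <- panel$mask
  # day of most recent observation, propagated along the day axis
  for (d in seq_len(horizon)[-1]) {
    prev_ok <- mask[, , d - 1] == 1 & obs_mask[, , d] == 0
    # age of the value being carried: held values inherit their source day
    if (!any(prev_ok)) next
    values[, , d][prev_ok] <- values[, , d - 1][prev_ok]
    mask[, , d][prev_ok] <- 1
  }
  # enforce the hold limit: recompute source day of each carried value
  src <- array(NA_integer_, dim(mask))
  for (d in seq_len(horizon)) {
    cur <- obs_mask[, , d] == 1
    src[, , d][cur] <- d
    if (d > 1L) {
      carry <- !cur & mask[, , d] == 1
      src[, , d][carry] <- src[, , d - 1][carry]
    }
  }
  expired <- mask == 1 & obs_mask == 0 &
    (slice.index(mask, 3) - src) > hold_days
  values[expired] <- NA_real_
  mask[expired] <- 0
  if (!is.null(last_observed)) {
    lo <- last_observed[panel$patient_ids]
    if (anyNA(lo)) stop("last_observed lacks entries for some patients")
    day_idx <- slice.index(mask, 3)
    pat_lo <- array(lo[slice.index(mask, 1)], dim(mask))
    held_beyond <- mask == 1 & obs_mask == 0 & day_idx > pat_lo
    values[held_beyond] <- NA_real_
    mask[held_beyond] <- 0
  }
  new_panel(values, mask, panel$patient_ids, panel$feature_names, horizon)
}

#' Validate outcome table
#'
#' One row per patient: `patient_id`, `onset_day` (day severe aGVHD
#' treatment was initiated; `NA` if no onset), `last_observed_day`.
#'
#' @param outcomes data frame.
#' @return validated data frame.
#' @export
as_outcomes <- function(outcomes) {
  required <- c("patient_id", "onset_day", "last_observed_day")
  miss <- setdiff(required, names(outcomes))
  if (length(miss)) stop("outcome table lacks column(s): ", paste(miss, collapse = ", "))
  o <- as.data.frame(outcomes)[required]
  o$patient_id <- as.character(o$patient_id)
  o$onset_day <- as.integer(o$onset_day)
  o$last_observed_day <- as.integer(o$last_observed_day)
  if (anyDuplicated(o$patient_id)) stop("duplicate patient_id in outcome table")
  if (anyNA(o$last_observed_day) || any(o$last_observed_day < 1L))
    stop("last_observed_day must be a positive integer for every patient")
  has <- !is.na(o$onset_day)
  if (any(o$onset_day[has] < 1L) || any(o$onset_day[has] > o$last_observed_day[has]))
    stop("onset_day must satisfy 1 <= onset_day <= last_observed_day")
  o
}

#' Assemble panel, peri-transplantation table and outcomes into a cohort
#'
#' The three components must cover exactly the same patients; the peri
#' and outcome tables are reordered to the panel's patient order.
#'
#' @param panel a `dagoat_panel`.
#' @param peri data frame with a `patient_id` column plus categorical
#'   peri-transplantation features (characters/factors). May have zero
#'   feature columns.
#' @param outcomes outcome table (see [as_outcomes()]).
#' @return an object of class `dagoat_cohort` with elements `panel`,
#'   `peri`, `outcomes`.
#' @export
assemble_cohort <- function(panel, peri, outcomes) {
  stopifnot(inherits(panel, "dagoat_panel"))
  outcomes <- as_outcomes(outcomes)
  if (!"patient_id" %in% names(peri)) stop("peri table lacks patient_id column")
  peri <- as.data.frame(peri)
  peri$patient_id <- as.character(peri$patient_id)
  if (anyDuplicated(peri$patient_id)) stop("duplicate patient_id in peri table")
  ids <- panel$patient_ids
  miss_peri <- setdiff(ids, peri$patient_id)
  miss_out <- setdiff(ids, outcomes$patient_id)
  extra <- unique(c(setdiff(peri$patient_id, ids), setdiff(outcomes$patient_id, ids)))
  if (length(miss_peri) || length(miss_out) || length(extra))
    stop("patient id mismatch across cohort components: ",
         paste(utils::head(unique(c(miss_peri, miss_out, extra)), 10L), collapse = ", "))
  peri <- peri[match(ids, peri$patient_id), , drop = FALSE]
  outcomes <- outcomes[match(ids, outcomes$patient_id), , drop = FALSE]
  rownames(peri) <- rownames(outcomes) <- NULL
  for (col in setdiff(names(peri), "patient_id"))
    peri[[col]] <- as.character(peri[[col]])
  structure(list(panel = panel, peri = peri, outcomes = outcomes),
            class = "dagoat_cohort")
}

#' @export
print.dagoat_cohort <- function(x, ...) {
  n_ev <- sum(!is.na(x$outcomes$onset_day))
  cat("dagoat_cohort:", length(x$panel$patient_ids), "patients,",
      length(x$panel$feature_names), "dynamic features,",
      ncol(x$peri) - 1L, "peri features,", n_ev, "events\n")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a `dagoat_cohort`.
#' @return integer.
#' @export
n_patients <- function(cohort) length(cohort$panel$patient_ids)

#' Subset a cohort by patient ids or indices
#'
#' @param cohort a `dagoat_cohort`.
#' @param patients character ids or integer indices.
#' @param features optional character vector of dynamic features to keep.
#' @return a `dagoat_cohort`.
#' @export
subset_cohort <- function(cohort, patients = NULL, features = NULL) {
  p <- cohort$panel
  if (is.null(patients)) patients <- seq_along(p$patient_ids)
  if (is.character(patients)) {
    patients <- match(patients, p$patient_ids)
    if (anyNA(patients)) stop("unknown patient id(s) in subset")
  }
  if (is.null(features)) features <- p$feature_names
  kf <- match(features, p$feature_names)
  if (anyNA(kf)) stop("unknown feature(s) in subset")
  panel <- new_panel(p$values[patients, kf, , drop = FALSE],
                     p$mask[patients, kf, , drop = FALSE],
                     p$patient_ids[patients], features, p$horizon)
  assemble_cohort(panel, cohort$peri[patients, , drop = FALSE],
                  cohort$outcomes[patients, , drop = FALSE])
}

# ---- on-disk formats -------------------------------------------------------

#' Write / read a dynamic panel as long-format CSV
#'
#' The canonical on-disk format is one row per observed cell:
#' `patient_id, day, feature, value`. Unobserved cells are simply absent,
#' so the mask round-trips exactly.
#'
#' @param panel a `dagoat_panel`.
#' @param path file path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns a `dagoat_panel`.
#' @export
write_panel_csv <- function(panel, path) {
  obs <- which(panel$mask == 1, arr.ind = TRUE)
  df <- data.frame(patient_id = panel$patient_ids[obs[, 1]],
                   day = obs[, 3],
                   feature = panel$feature_names[obs[, 2]],
                   value = panel$values[obs])
  df <- df[order(df$patient_id, df$feature, df$day), ]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @param patient_ids,feature_names,horizon panel geometry; defaults are
#'   inferred from the file.
#' @export
read_panel_csv <- function(path, patient_ids = NULL, feature_names = NULL,
                           horizon = 100L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  aggregate_daily(df, patient_ids = patient_ids,
                  feature_names = feature_names, horizon = horizon)
}

#' Read peri-transplantation and outcome tables from CSV
#'
#' One row per patient. The peri table holds `patient_id` plus arbitrary
#' categorical columns; the outcome table holds `patient_id, onset_day,
#' last_observed_day` with empty `onset_day` meaning no onset.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_peri_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"patient_id" %in% names(df)) stop("peri CSV lacks patient_id column")
  df
}

#' @rdname read_peri_csv
#' @export
read_outcomes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_outcomes(df)
}

#' Read a pipeline configuration file
#'
#' YAML with optional sections: `horizon`, `hold_days`, `model`
#' (`delta`, `gamma`, `smoothing`), and `plausibility` (feature ->
#' `[min, max]`).
#'
#' @param path YAML file path.
#' @return a named list merged over package defaults.
#' @export
read_dagoat_config <- function(path) {
  defaults <- list(horizon = 100L, hold_days = 3L,
                   model = list(delta = 14L, gamma = 0.1, smoothing = TRUE),
                   plausibility = list())
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(defaults, cfg)
  out$plausibility <- lapply(out$plausibility, as.numeric)
  out
}
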
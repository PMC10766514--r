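#' Load the smartphone activities / postural transitions dataset
#'
#' Reads the processed partition files of the UCI
#' "Smartphone-Based Recognition of Human Activities and Postural
#' Transitions" dataset: per partition, a whitespace-separated feature
#' matrix (`X_*.txt`, 561 columns), an activity label vector
#' (`y_*.txt`) and a subject id vector (`subject_id_*.txt`), all with
#' one row per 1.28-s window. Row order in the files (the temporal
#' order within subject) is preserved, as is the published
#' train / test split by subject.
#'
#' @param directory dataset root containing `Train/` and `Test/`
#'   subdirectories.
#' @param load_features read the 561-column feature matrices (set
#'   `FALSE` when only the label sequences are needed, e.g. for segment
#'   counting).
#' @param expected_features expected feature count per window (561 for
#'   the published dataset; override for reduced test fixtures).
#' @return list with elements `train` and `test`; each a list of
#'   per-subject series: `subject`, `labels` (integer activity codes),
#'   and `features` (windows x 561 matrix, or `NULL`).
#' @export
load_hapt <- function(directory, load_features = TRUE,
                      expected_features = 561L) {
  parts <- list(train = "Train", test = "Test")
  out <- lapply(names(parts), function(part) {
    sub <- file.path(directory, parts[[part]])
    suffix <- if (part == "train") "train" else "test"
    yf <- file.path(sub, paste0("y_", suffix, ".txt"))
    sf <- file.path(sub, paste0("subject_id_", suffix, ".txt"))
    if (!file.exists(yf) || !file.exists(sf))
      stop("missing HAPT file(s) under ", sub)
    y <- scan(yf, what = integer(), quiet = TRUE)
    subj <- scan(sf, what = integer(), quiet = TRUE)
    if (length(y) != length(subj))
      stop("row-count mismatch between labels and subjects in ", sub)
    X <- NULL
    if (load_features) {
      xf <- file.path(sub, paste0("X_", suffix, ".txt"))
      if (!file.exists(xf)) stop("missing HAPT feature file ", xf)
      X <- as.matrix(utils::read.table(xf))
      if (nrow(X) != length(y))
        stop("row-count mismatch between features and labels in ", sub)
      if (ncol(X) != expected_features)
        stop("expected ", expected_features,
             " features per window, found ", ncol(X))
    }
    lapply(unique(subj), function(s) {
      rows <- which(subj == s)
      list(subject = s, labels = y[rows],
           features = if (is.null(X)) NULL else X[rows, , drop = FALSE])
    })
  })
  names(out) <- names(parts)
  train_subj <- vapply(out$train, `[[`, integer(1), "subject")
  test_subj <- vapply(out$test, `[[`, integer(1), "subject")
  if (length(intersect(train_subj, test_subj)))
    stop("train/test partitions share subject(s): ",
         paste(intersect(train_subj, test_subj), collapse = ", "))
  out
}

#' Extract continuous-sitting segments with a stand-up lookahead label
#'
#' Every run of 7 consecutive sitting windows (8.96 s at a 1.28-s step)
#' yields one candidate segment per offset (stride 1). A segment is
#' labelled `+` if any of the following 4 windows (5.12 s) carries the
#' sit-to-stand transition code; segments whose lookahead crosses the
#' end of a subject's recording are labelled from the available
#' lookahead.
#'
#' @param series list of per-subject series from [load_hapt()] (one
#'   partition).
#' @param sitting_label,transition_label activity codes for sitting and
#'   the sit-to-stand transition (dataset codes 4 and 8).
#' @param seg_len segment length in windows (default 7).
#' @param lookahead label horizon in windows (default 4).
#' @return data frame with one row per segment: `subject`, `start`
#'   (window index of the first segment window), `label` (0/1) and,
#'   when features are loaded, an attached list column is avoided —
#'   feature blocks are returned separately by [hapt_to_cohort()].
#' @export
extract_segments <- function(series, sitting_label = 4L,
                             transition_label = 8L, seg_len = 7L,
                             lookahead = 4L) {
  rows <- list()
  for (s in series) {
    lab <- s$labels
    n <- length(lab)
    if (n < seg_len) next
    sitting <- lab == sitting_label
    # starts where seg_len consecutive sitting windows begin
    run_ok <- stats::filter(as.numeric(sitting), rep(1, seg_len),
                            sides = 1)[seq.int(seg_len, n)] == seg_len
    starts <- which(run_ok)  # start = index, window span [start, start+seg_len-1]
    for (st in starts) {
      after <- if (st + seg_len > n) integer(0) else
        seq.int(st + seg_len, min(st + seg_len + lookahead - 1L, n))
      plus <- length(after) > 0 && any(lab[after] == transition_label)
      rows[[length(rows) + 1L]] <- data.frame(subject = s$subject,
                                              start = st,
                                              label = as.integer(plus))
    }
  }
  if (!length(rows))
    return(data.frame(subject = integer(0), start = integer(0),
                      label = integer(0)))
  do.call(rbind, rows)
}

#' Turn extracted segments into a model-ready pseudo-cohort
#'
#' Each segment becomes a pseudo-patient with 7 "days" of 561 dynamic
#' features (fully observed), no peri-transplantation features (the
#' prior reduces to the class-prior log-odds) and, for `+` segments, a
#' nominal onset immediately after day 7. With `delta = 7` the scoring
#' window at day 7 spans the whole segment.
#'
#' @param series per-subject series with features loaded.
#' @param segments segment table from [extract_segments()].
#' @param seg_len segment length (default 7).
#' @return list with `cohort` (a `dagoat_cohort`) and `config` (the
#'   matching `dagoat_config` with delta = 7).
#' @export
hapt_to_cohort <- function(series, segments, seg_len = 7L) {
  if (!nrow(segments)) stop("no segments to convert")
  subj_map <- vapply(series, `[[`, integer(1), "subject")
  feats <- series[[1]]$features
  if (is.null(feats)) stop("series loaded without features; rerun load_hapt(load_features = TRUE)")
  p <- ncol(feats)
  n <- nrow(segments)
  values <- array(NA_real_, c(n, p, seg_len + 1L))
  for (i in seq_len(n)) {
    s <- series[[match(segments$subject[i], subj_map)]]
    block <- s$features[seq.int(segments$start[i],
                                segments$start[i] + seg_len - 1L), , drop = FALSE]
    values[i, , seq_len(seg_len)] <- t(block)
  }
  mask <- array(0, c(n, p, seg_len + 1L))
  mask[, , seq_len(seg_len)] <- 1
  values[mask == 0] <- NA_real_
  ids <- sprintf("seg%05d", seq_len(n))
  panel <- new_panel(values, mask, ids, sprintf("f%03d", seq_len(p)),
                     seg_len + 1L)
  outcomes <- data.frame(
    patient_id = ids,
    onset_day = ifelse(segments$label == 1L, seg_len + 1L, NA_integer_),
    last_observed_day = seg_len + 1L)
  peri <- data.frame(patient_id = ids)
  list(cohort = assemble_cohort(panel, peri, outcomes),
       config = dagoat_config(delta = seg_len, horizon = seg_len + 1L))
}
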
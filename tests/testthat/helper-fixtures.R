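# Small programmatic fixtures shared across test files.

# Hand-sized cohort: n patients, two dynamic features on a short
# horizon, one binary peri feature. Feature "marker" is shifted upward
# before onset for cases so the model has signal to find.
make_toy_cohort <- function(n = 40L, horizon = 30L, seed = 1L,
                            shift = 3) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n))
  event <- rep(c(TRUE, FALSE), length.out = n)
  onset_range <- seq.int(max(2L, horizon %/% 3L), horizon - 2L)
  onset <- ifelse(event, sample(onset_range, n, replace = TRUE), NA_integer_)
  rows <- list()
  for (i in seq_len(n)) {
    for (feat in c("marker", "noise")) {
      days <- sort(sample(seq_len(horizon), min(20L, max(5L, horizon * 2L %/% 3L))))
      val <- rnorm(length(days))
      if (feat == "marker" && event[i]) {
        pre <- days >= onset[i] - 10 & days <= onset[i]
        val[pre] <- val[pre] + shift
      }
      rows[[length(rows) + 1L]] <- data.frame(patient_id = ids[i], day = days,
                                              feature = feat, value = val)
    }
  }
  meas <- do.call(rbind, rows)
  panel <- aggregate_daily(meas, patient_ids = ids,
                           feature_names = c("marker", "noise"),
                           horizon = horizon)
  peri <- data.frame(patient_id = ids,
                     hla = sample(c("matched", "mismatched"), n, replace = TRUE))
  outcomes <- data.frame(patient_id = ids,
                         onset_day = as.integer(onset),
                         last_observed_day = horizon)
  assemble_cohort(panel, peri, outcomes)
}

# Synthetic miniature dataset in the smartphone-activities file layout
# (whitespace-separated X / y / subject files per partition), with known
# sitting runs and sit-to-stand transitions. Entirely synthetic; used to
# exercise the adapter's parsing and extraction mechanics.
write_synthetic_hapt <- function(dir, n_features = 5L) {
  sit <- 4L; s2s <- 8L; walk <- 1L; stand <- 5L
  seqs <- list(
    train = list(
      # subject 1: 10 sitting windows then stand-up: 4 segments, all '+'
      # (every start's 4-window lookahead reaches window 11)
      `1` = c(rep(sit, 10L), s2s, rep(stand, 3L)),
      # subject 2: 6 sitting windows only: too short, no segments
      `2` = c(rep(walk, 2L), rep(sit, 6L), rep(walk, 2L)),
      # subject 3: sitting run of 7 at the very end: truncated (empty)
      # lookahead, '-'
      `3` = c(rep(walk, 3L), rep(sit, 7L)),
      # subject 4: sitting run ends in walking, never stands up: all '-'
      `4` = c(walk, rep(sit, 9L), rep(walk, 4L))),
    test = list(
      # subject 9: 8 sitting windows then transition: 2 segments, both '+'
      `9` = c(rep(sit, 8L), s2s, stand)))
  for (part in names(seqs)) {
    sub <- file.path(dir, if (part == "train") "Train" else "Test")
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    y <- unlist(seqs[[part]], use.names = FALSE)
    subj <- rep(as.integer(names(seqs[[part]])),
                vapply(seqs[[part]], length, integer(1)))
    suffix <- part
    writeLines(as.character(y), file.path(sub, paste0("y_", suffix, ".txt")))
    writeLines(as.character(subj),
               file.path(sub, paste0("subject_id_", suffix, ".txt")))
    set.seed(7L)
    X <- matrix(round(rnorm(length(y) * n_features), 4), length(y))
    utils::write.table(X, file.path(sub, paste0("X_", suffix, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

# Expected segments for the synthetic layout above, derived by hand.
synthetic_hapt_expected <- function() {
  list(train = data.frame(subject = c(1L, 1L, 1L, 1L, 3L, 4L, 4L, 4L),
                          start = c(1L, 2L, 3L, 4L, 4L, 2L, 3L, 4L),
                          label = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)),
       test = data.frame(subject = c(9L, 9L),
                         start = c(1L, 2L),
                         label = c(1L, 1L)))
}
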
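#' Categorical Naive Bayes over peri-transplantation features
#'
#' Fits class priors and per-feature categorical conditionals with
#' additive (Laplace) smoothing. The model supplies the
#' peri-transplantation prior term rho(z): the Naive Bayes log-odds
#' log P(Y=1 | z) / P(Y=0 | z).
#'
#' @param peri data frame with `patient_id` plus categorical feature
#'   columns (zero feature columns is allowed: the prior then reduces to
#'   the class-prior log-odds).
#' @param labels 0/1 outcome vector matched to `peri` rows.
#' @param pseudocount additive smoothing count (default 1).
#' @return an object of class `dagoat_nb` with `class_log_prior` (named
#'   `c("0", "1")`), per-feature conditional tables and vocabularies.
#' @export
fit_nb <- function(peri, labels, pseudocount = 1) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), nrow(peri) == length(labels),
            pseudocount > 0)
  if (length(unique(labels)) < 2L)
    stop("cannot fit Naive Bayes: single-class labels")
  feats <- setdiff(names(peri), "patient_id")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  class_log_prior <- c("0" = log(n0 / (n0 + n1)), "1" = log(n1 / (n0 + n1)))
  tables <- list()
  for (f in feats) {
    z <- as.character(peri[[f]])
    vocab <- sort(unique(z))
    counts <- vapply(c(0L, 1L), function(cl)
      vapply(vocab, function(v) sum(z == v & labels == cl), numeric(1)),
      numeric(length(vocab)))
    counts <- matrix(counts, nrow = length(vocab),
                     dimnames = list(vocab, c("0", "1")))
    denom <- c(n0, n1) + pseudocount * length(vocab)
    probs <- sweep(counts + pseudocount, 2, denom, "/")
    tables[[f]] <- list(vocab = vocab, probs = probs,
                        n_class = c("0" = n0, "1" = n1),
                        pseudocount = pseudocount)
  }
  structure(list(class_log_prior = class_log_prior, tables = tables,
                 features = feats, pseudocount = pseudocount),
            class = "dagoat_nb")
}

#' Naive Bayes log-odds for new patients
#'
#' A category unseen in training contributes a zero-count smoothed
#' probability for both classes (pseudocount over the training
#' denominator), so scores stay finite.
#'
#' @param params a `dagoat_nb` fit.
#' @param peri data frame of peri features (one or more rows), or `NULL`
#'   / zero-feature frame when the fit has no features.
#' @return numeric vector of log-odds, one per row.
#' @export
nb_log_odds <- function(params, peri) {
  stopifnot(inherits(params, "dagoat_nb"))
  base <- params$class_log_prior["1"] - params$class_log_prior["0"]
  if (!length(params$features))
    return(rep(unname(base), max(1L, if (is.null(peri)) 1L else nrow(peri))))
  missing_f <- setdiff(params$features, names(peri))
  if (length(missing_f))
    stop("peri data lack feature(s): ", paste(missing_f, collapse = ", "))
  out <- rep(unname(base), nrow(peri))
  for (f in params$features) {
    tab <- params$tables[[f]]
    z <- as.character(peri[[f]])
    idx <- match(z, tab$vocab)
    p1 <- ifelse(is.na(idx), tab$pseudocount /
                   (tab$n_class["1"] + tab$pseudocount * length(tab$vocab)),
                 tab$probs[idx, "1"])
    p0 <- ifelse(is.na(idx), tab$pseudocount /
                   (tab$n_class["0"] + tab$pseudocount * length(tab$vocab)),
                 tab$probs[idx, "0"])
    out <- out + log(p1) - log(p0)
  }
  out
}

serialize_nb <- function(params) {
  list(class_log_prior = as.list(params$class_log_prior),
       features = params$features,
       pseudocount = params$pseudocount,
       tables = lapply(params$tables, function(tb)
         list(vocab = tb$vocab, probs = as.data.frame(tb$probs),
              n_class = as.list(tb$n_class), pseudocount = tb$pseudocount)))
}

deserialize_nb <- function(ser) {
  tables <- lapply(ser$tables, function(tb) {
    probs <- as.matrix(as.data.frame(tb$probs))
    rownames(probs) <- tb$vocab
    list(vocab = as.character(tb$vocab), probs = probs,
         n_class = c("0" = as.numeric(tb$n_class[["0"]]),
                     "1" = as.numeric(tb$n_class[["1"]])),
         pseudocount = as.numeric(tb$pseudocount))
  })
  structure(list(class_log_prior = c("0" = as.numeric(ser$class_log_prior[["0"]]),
                                     "1" = as.numeric(ser$class_log_prior[["1"]])),
                 tables = tables,
                 features = as.character(unlist(ser$features)),
                 pseudocount = as.numeric(ser$pseudocount)),
            class = "dagoat_nb")
}

# ---- benchmark models ------------------------------------------------------

#' Flatten a cohort's moving window into a fixed-length feature matrix
#'
#' One column per (dynamic feature, lag) pair over the `delta`-day
#' window ending at day t, with unobserved cells as `NA` (XGBoost
#' consumes these natively).
#'
#' @param cohort a `dagoat_cohort`.
#' @param t anchor day.
#' @param delta window length.
#' @return numeric matrix, patients x (features * window days).
#' @export
flatten_window <- function(cohort, t, delta) {
  days <- seq.int(max(1L, t - delta + 1L), t)
  np <- n_patients(cohort)
  p <- cohort$panel
  cols <- lapply(seq_along(p$feature_names), function(k) {
    v <- p$values[, k, days, drop = FALSE]
    dim(v) <- c(np, length(days))
    m <- p$mask[, k, days, drop = FALSE]
    dim(m) <- c(np, length(days))
    v[m != 1] <- NA_real_
    colnames(v) <- paste0(p$feature_names[k], "_d", days)
    v
  })
  do.call(cbind, cols)
}

#' Fit a benchmark scorer at one evaluation day
#'
#' Benchmarks share daGOAT's moving-window labels at day t.
#' `"nb"` and `"rf"` are peri-transplantation-features-only models
#' (Naive Bayes, Random Forest); `"xgboost"` receives the flattened
#' dynamic window with native missing-value handling.
#'
#' @param name one of `"nb"`, `"rf"`, `"xgboost"`.
#' @param cohort training `dagoat_cohort`.
#' @param t evaluation day.
#' @param config a `dagoat_config` (supplies `delta`).
#' @param seed integer seed for the stochastic learners.
#' @param hyperparameters named list overriding the recorded defaults
#'   (rf: `ntree` 500; xgboost: `nrounds` 50, `eta` 0.3, `max_depth` 6).
#' @return a function `scorer(cohort)` returning one numeric score per
#'   patient (higher = riskier), or `NULL` if the training labels are
#'   single-class.
#' @export
fit_benchmark <- function(name = c("nb", "rf", "xgboost"), cohort, t,
                          config = dagoat_config(), seed = 1L,
                          hyperparameters = list()) {
  name <- match.arg(name)
  lab <- window_labels(cohort, t, config$delta, config$horizon)
  keep <- lab$at_risk
  y <- lab$y[keep]
  if (length(unique(y)) < 2L) return(NULL)
  if (name == "nb") {
    fit <- fit_nb(cohort$peri[keep, , drop = FALSE], y)
    return(function(newdata) nb_log_odds(fit, newdata$peri))
  }
  if (name == "rf") {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("benchmark 'rf' requires the randomForest package")
    feats <- setdiff(names(cohort$peri), "patient_id")
    if (!length(feats)) stop("rf benchmark needs at least one peri feature")
    levs <- lapply(feats, function(f) sort(unique(as.character(cohort$peri[[f]]))))
    names(levs) <- feats
    make_x <- function(peri) {
      x <- peri[feats]
      for (f in feats)
        x[[f]] <- factor(as.character(x[[f]]), levels = levs[[f]])
      x
    }
    ntree <- hyperparameters$ntree %||% 500L
    set.seed(seed)
    fit <- randomForest::randomForest(make_x(cohort$peri[keep, , drop = FALSE]),
                                      factor(y, levels = c(0, 1)), ntree = ntree)
    return(function(newdata)
      stats::predict(fit, make_x(newdata$peri), type = "prob")[, "1"])
  }
  # xgboost over the flattened dynamic window
  if (!requireNamespace("xgboost", quietly = TRUE))
    stop("benchmark 'xgboost' requires the xgboost package")
  X <- flatten_window(cohort, t, config$delta)[keep, , drop = FALSE]
  params <- list(objective = "binary:logistic",
                 eta = hyperparameters$eta %||% 0.3,
                 max_depth = hyperparameters$max_depth %||% 6L,
                 nthread = 1L, seed = seed)
  nrounds <- hyperparameters$nrounds %||% 50L
  set.seed(seed)
  fit <- xgboost::xgb.train(params = params,
                            data = xgboost::xgb.DMatrix(X, label = y),
                            nrounds = nrounds, verbose = 0)
  function(newdata) {
    Xn <- flatten_window(newdata, t, config$delta)
    stats::predict(fit, xgboost::xgb.DMatrix(Xn))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
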
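#' Landmark plasma-biomarker comparator scores
#'
#' Linear scores over log-transformed plasma biomarker concentrations
#' measured at a fixed post-transplant landmark. The two-biomarker
#' score uses base-10 logarithms of ST2 and Reg3a; the three-biomarker
#' score uses base-2 logarithms of TNFR1, Reg3a and ST2. Assay units
#' are not fixed by the published coefficients: rank-based metrics
#' (AUROC, AUPRC) are invariant to any common per-analyte rescaling,
#' while absolute score values are not.
#'
#' @param st2,reg3a,tnfr1 strictly positive assay values (vectorized).
#' @return numeric score vector.
#' @export
magic_score <- function(st2, reg3a) {
  check_positive(st2 = st2, reg3a = reg3a)
  -11.263 + 1.844 * log10(st2) + 0.577 * log10(reg3a)
}

#' @rdname magic_score
#' @export
ann_arbor_score <- function(tnfr1, reg3a, st2) {
  check_positive(tnfr1 = tnfr1, reg3a = reg3a, st2 = st2)
  -9.169 + 0.598 * log2(tnfr1) - 0.028 * log2(reg3a) + 0.189 * log2(st2)
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args))
    if (any(!is.na(args[[nm]]) & args[[nm]] <= 0))
      stop("biomarker '", nm, "' must be strictly positive (log transform)")
  invisible(NULL)
}

#' Compute both biomarker scores for a patient table
#'
#' @param path_in CSV with columns `patient, st2, reg3a, tnfr1`.
#' @param path_out optional CSV destination for
#'   `patient, magic, annarbor`.
#' @return data frame with `patient`, `magic`, `annarbor`.
#' @export
biomarker_scores_csv <- function(path_in, path_out = NULL) {
  df <- utils::read.csv(path_in, stringsAsFactors = FALSE)
  need <- c("patient", "st2", "reg3a", "tnfr1")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("biomarker CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  out <- data.frame(patient = df$patient,
                    magic = magic_score(df$st2, df$reg3a),
                    annarbor = ann_arbor_score(df$tnfr1, df$reg3a, df$st2))
  if (!is.null(path_out)) utils::write.csv(out, path_out, row.names = FALSE)
  out
}
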
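# Independent brute-force oracles used to pin expected values.

# Mutual information of a binary split at cutoff c against binary labels,
# straight from the entropy definition H(X) + H(Y) - H(X, Y).
oracle_mi_at <- function(values, labels, cutoff) {
  x <- as.integer(values > cutoff)
  n <- length(x)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  px <- table(x) / n
  py <- table(labels) / n
  pxy <- table(x, labels) / n
  h(px) + h(py) - h(pxy)
}

# Exhaustive cutoff search; ties toward the smallest candidate.
oracle_best_cutoff <- function(values, labels) {
  v <- sort(unique(values))
  if (length(v) < 2L || length(unique(labels)) < 2L) return(NA_real_)
  cands <- (v[-1] + v[-length(v)]) / 2
  mi <- vapply(cands, function(cc) oracle_mi_at(values, labels, cc), numeric(1))
  cands[which.max(mi)]
}

# AUROC as the fraction of concordant (positive, negative) pairs, ties
# counting one half.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Average precision from the exhaustive precision-recall walk over
# distinct thresholds.
oracle_auprc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || all(labels == 1)) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (cc in thr) {
    sel <- scores >= cc
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n1
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Textbook continuity-corrected Pearson chi-square on a 2x2 table.
oracle_chisq_2x2 <- function(a, b, c, d, continuity = TRUE) {
  tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  adj <- if (continuity) pmin(0.5, abs(tab - E)) else 0
  stat <- sum((abs(tab - E) - adj)^2 / E)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
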
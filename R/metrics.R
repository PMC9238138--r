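#' Classification metrics: average precision (AUPR) and AUROC
#'
#' Average precision summarizes the precision-recall curve as the sum over
#' descending score thresholds (one per distinct score, so tied scores are
#' grouped) of precision at the threshold weighted by the recall increment.
#' AUROC is the Mann-Whitney statistic scaled to [0, 1], with tied scores
#' counted half. With all scores identical, AUPR equals the prevalence and
#' AUROC equals 0.5.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 labels with at least one of each class.
#' @return named numeric vector `c(aupr =, auroc =)`.
#' @export
compute_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("compute_metrics: metrics undefined for single-class labels")
  }
  if (length(scores) != length(labels)) {
    stop("compute_metrics: length mismatch")
  }
  # group tied scores: one PR point per distinct threshold
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1 - y)[grp_end]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  aupr <- sum(diff(c(0, recall)) * precision)
  # Mann-Whitney with ties half-credited, via midranks
  r <- rank(scores)
  auroc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  c(aupr = aupr, auroc = auroc)
}

#' Censored concordance index
#'
#' Fraction of admissible sample pairs whose predicted risk ordering agrees
#' with the observed survival ordering. A pair (i, j) is admissible when
#' sample i has an observed event and a strictly earlier time than j
#' (Harrell's convention; pairs censored before comparison are excluded).
#' The pair is concordant when the earlier-event sample has the higher risk
#' score; tied scores count half.
#'
#' @param scores risk scores (higher = shorter predicted survival).
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @return c-index in [0, 1].
#' @export
concordance_index <- function(scores, times, events) {
  if (any(times <= 0)) stop("concordance_index: times must be > 0")
  events <- as.integer(events)
  n <- length(scores)
  conc <- 0; total <- 0
  for (i in which(events == 1)) {
    later <- times > times[i]
    total <- total + sum(later)
    conc <- conc + sum(scores[i] > scores[later]) +
      0.5 * sum(scores[i] == scores[later])
  }
  if (total == 0) stop("concordance_index: no admissible pairs")
  conc / total
}
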
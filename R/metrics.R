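# Discrimination metrics.  AUROC in the Mann-Whitney form (probability a
# random positive outscores a random negative, ties counted half); AUPRC by
# step interpolation of the precision-recall curve.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)`, computed from midranks.
#'
#' @param labels 0/1 vector (both classes must be present)
#' @param scores numeric vector of the same length
#' @return AUROC in `[0, 1]`
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("auroc requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (step interpolation)
#'
#' Thresholds sweep the distinct score values from high to low; the area is
#' `sum over threshold steps of (recall_i - recall_{i-1}) * precision_i`.
#'
#' @param labels 0/1 vector with at least one positive
#' @param scores numeric vector of the same length
#' @return AUPRC in `(0, 1]`
#' @export
auprc <- function(labels, scores) {
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  if (P == 0) stop("auprc requires at least one positive")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(1 - lab)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)  # last index of each tie group
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Evaluation report for one example set
#' @param labels,scores as in [auroc()]
#' @param subgroup optional label for the report row
#' @return one-row data.frame: subgroup, n, n_pos, auroc, auprc
#' @export
eval_report <- function(labels, scores, subgroup = "all") {
  data.frame(subgroup = subgroup, n = length(labels),
             n_pos = sum(labels == 1),
             auroc = auroc(labels, scores),
             auprc = auprc(labels, scores),
             stringsAsFactors = FALSE)
}
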
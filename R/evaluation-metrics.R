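#' Confusion counts of a binary prediction
#'
#' The positive class is the mutated class (label 1).
#'
#' @param truth,predicted Equal-length 0-1 vectors.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length (", length(truth), " vs ",
         length(predicted), ")")
  t1 <- truth == 1L
  p1 <- predicted == 1L
  c(TP = sum(t1 & p1), FP = sum(!t1 & p1),
    TN = sum(!t1 & !p1), FN = sum(t1 & !p1))
}

#' ROC curve and rank-based AUC
#'
#' Sweeps the decision threshold over the unique predicted probabilities and
#' returns the (FPR, TPR) points, anchored at (0,0) and (1,1). The AUC is
#' the Mann-Whitney statistic: the probability that a random positive scores
#' above a random negative, with ties counting one half.
#'
#' @param probabilities Numeric scores.
#' @param truth 0-1 vector.
#' @return A list with `roc` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc` (`NA` with a warning if only one class is present).
#' @export
rocPoints <- function(probabilities, truth) {
  stopifnot(length(probabilities) == length(truth))
  nPos <- sum(truth == 1L)
  nNeg <- sum(truth == 0L)
  if (nPos == 0L || nNeg == 0L) {
    warning("AUC undefined: only one class present")
    return(list(roc = data.frame(fpr = c(0, 1), tpr = c(0, 1),
                                 threshold = c(Inf, -Inf)), auc = NA_real_))
  }
  th <- sort(unique(probabilities), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(probabilities >= t & truth == 1L) / nPos,
                numeric(1))
  fpr <- vapply(th, function(t) sum(probabilities >= t & truth == 0L) / nNeg,
                numeric(1))
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    threshold = c(Inf, th, -Inf))
  r <- rank(probabilities)
  auc <- (sum(r[truth == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  list(roc = roc, auc = auc)
}

#' Compute the full evaluation metric panel
#'
#' Derives the nine binary-classification metrics from the confusion counts:
#' accuracy, precision, recall, sensitivity (== recall), specificity, F1,
#' Matthews correlation coefficient, Cohen's kappa (observed agreement P_o
#' against chance agreement P_e from the marginal products), and - when
#' probabilities are supplied - the rank-based AUC with the ROC curve.
#' Zero denominators yield `NaN` and are listed in the report's `flags`
#' rather than raised.
#'
#' @param counts Named `TP`/`FP`/`TN`/`FN` vector from [confusionCounts()].
#' @param probabilities Optional scores for the ROC/AUC.
#' @param truth Optional 0-1 vector (required with `probabilities`).
#' @param protocol Optional protocol tag carried in the report.
#' @return A [MetricsReport-class].
#' @export
computeMetrics <- function(counts, probabilities = NULL, truth = NULL,
                           protocol = "") {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
  TP <- as.numeric(counts["TP"]); FP <- as.numeric(counts["FP"])
  TN <- as.numeric(counts["TN"]); FN <- as.numeric(counts["FN"])
  n <- TP + FP + TN + FN
  div <- function(num, den) if (den == 0) NaN else num / den
  precision <- div(TP, TP + FP)
  recall <- div(TP, TP + FN)
  specificity <- div(TN, TN + FP)
  accuracy <- div(TP + TN, n)
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0)
    NaN else 2 * precision * recall / (precision + recall)
  mccDen <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (mccDen == 0) NaN else (TP * TN - FP * FN) / mccDen
  pO <- accuracy
  pE <- div((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN), n ^ 2)
  kappa <- if (is.nan(pE) || pE == 1) NaN else (pO - pE) / (1 - pE)
  auc <- NA_real_
  roc <- data.frame(fpr = numeric(0), tpr = numeric(0),
                    threshold = numeric(0))
  if (!is.null(probabilities)) {
    if (is.null(truth))
      stop("truth labels are required to compute the ROC/AUC")
    rp <- suppressWarnings(rocPoints(probabilities, truth))
    auc <- rp$auc
    roc <- rp$roc
  }
  metrics <- c(accuracy = accuracy, precision = precision, recall = recall,
               sensitivity = recall, specificity = specificity, f1 = f1,
               mcc = mcc, cohens_kappa = kappa, auc = auc)
  flags <- names(metrics)[is.nan(metrics) |
                            (names(metrics) == "auc" & is.na(metrics) &
                               !is.null(probabilities))]
  methods::new("MetricsReport", protocol = protocol,
               counts = stats::setNames(as.integer(c(TP, FP, TN, FN)),
                                        c("TP", "FP", "TN", "FN")),
               metrics = metrics,
               agreement = c(P_o = pO, P_e = pE),
               roc = roc, flags = flags)
}
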
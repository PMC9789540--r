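#' Confusion counts with ACP as the positive class
#'
#' Tallies TP/FP/TN/FN from true and predicted storage codes. The storage
#' convention codes ACP as 0 and non-ACP as 1; this function is the single
#' place where that coding is inverted so that ACP is the positive class of
#' every downstream metric.
#'
#' @param truth,pred Integer vectors of storage codes (0 = ACP, 1 = non-ACP).
#' @return Object of class `confusion_counts`: list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred),
            all(truth %in% c(0L, 1L)), all(pred %in% c(0L, 1L)))
  pos <- truth == 0L   # ACP
  ppos <- pred == 0L
  structure(list(
    TP = sum(pos & ppos), FP = sum(!pos & ppos),
    TN = sum(!pos & !ppos), FN = sum(pos & !ppos)
  ), class = "confusion_counts")
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Threshold-based classification metrics
#'
#' Computes sensitivity (recall), specificity, precision, accuracy, MCC and
#' F1 from confusion counts:
#' `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`, `precision = TP/(TP+FP)`,
#' `ACC = (TP+TN)/(P+N)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))`,
#' `F1 = 2*recall*precision/(recall+precision)`.
#' Undefined 0/0 ratios are reported as 0 and flagged in the `degenerate`
#' field, which imbalanced designs (e.g. no predicted positives) can
#' produce.
#'
#' @param counts A [confusion_counts()] object or a list with TP/FP/TN/FN.
#' @return Object of class `metrics_report`: list with `SE`, `SP`,
#'   `precision`, `ACC`, `MCC`, `F1`, the counts, and `degenerate` (names of
#'   metrics whose ratio was 0/0).
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (any(c(TP, FP, TN, FN) < 0)) stop("negative counts", call. = FALSE)
  m <- list(
    SE = safe_div(TP, TP + FN),
    SP = safe_div(TN, TN + FP),
    precision = safe_div(TP, TP + FP),
    ACC = safe_div(TP + TN, TP + TN + FP + FN)
  )
  denom <- sqrt(prod(c(TP + FN, TP + FP, TN + FN, TN + FP)))
  m$MCC <- if (denom == 0) NA_real_ else (TP * TN - FP * FN) / denom
  m$F1 <- if (is.na(m$SE) || is.na(m$precision) || (m$SE + m$precision) == 0) {
    NA_real_
  } else {
    2 * m$SE * m$precision / (m$SE + m$precision)
  }
  degenerate <- names(m)[vapply(m, is.na, logical(1))]
  m[degenerate] <- 0
  structure(c(m, list(counts = counts, degenerate = degenerate)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  vals <- unlist(x[c("SE", "SP", "precision", "ACC", "MCC", "F1", "AUC")])
  vals <- vals[!is.na(vals)]
  cat(paste(sprintf("%s=%.3f", names(vals), vals), collapse = "  "), "\n")
  if (length(x$degenerate)) {
    cat("(degenerate 0/0 reported as 0:",
        paste(x$degenerate, collapse = ", "), ")\n")
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney rank statistic: the probability
#' that a randomly chosen positive (ACP) scores higher than a randomly
#' chosen negative, ties counting one half.
#'
#' @param scores Numeric vector of predicted ACP probabilities (or any
#'   monotone score; higher = more ACP-like).
#' @param labels Integer storage codes (0 = ACP, 1 = non-ACP).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 0L
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - P * (P + 1) / 2) / (P * N)
}

#' Evaluate predictions against true labels
#'
#' Thresholds ACP probabilities, tallies the confusion counts and returns the
#' full metric suite including AUC.
#'
#' @param truth Integer storage codes (0 = ACP, 1 = non-ACP).
#' @param prob_acp Predicted ACP probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return A `metrics_report` with an additional `AUC` element.
#' @export
evaluate_predictions <- function(truth, prob_acp, threshold = 0.5) {
  pred <- ifelse(prob_acp >= threshold, 0L, 1L)
  rep <- compute_metrics(confusion_counts(truth, pred))
  rep$AUC <- if (length(unique(truth)) == 2L) compute_auc(prob_acp, truth)
  else NA_real_
  rep
}

metrics_row <- function(rep) {
  data.frame(SE = rep$SE, SP = rep$SP, precision = rep$precision,
             ACC = rep$ACC, MCC = rep$MCC, F1 = rep$F1,
             AUC = if (is.null(rep$AUC)) NA_real_ else rep$AUC)
}
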
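# Evaluation metrics: confusion counts at a cutoff and the scalar summaries
# SEN, SPE, ACC, MCC, plus rank-based ROC-AUC.

#' Confusion counts at a decision cutoff
#'
#' A score is called positive iff `score >= cutoff` (ties positive). The four
#' counts partition the sample.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores, same length.
#' @param cutoff Decision threshold.
#' @return Object of class `confusion_counts`: list with integers `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(labels, scores, cutoff) {
  if (length(labels) == 0L) stop("empty input")
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  call <- scores >= cutoff
  pos <- labels == 1
  structure(list(TP = sum(call & pos), FP = sum(call & !pos),
                 TN = sum(!call & !pos), FN = sum(!call & pos)),
            class = "confusion_counts")
}

#' Build confusion counts directly
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return `confusion_counts` object.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP + FP + TN + FN > 0)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Scalar metrics from confusion counts
#'
#' Sensitivity `TP / (TP + FN)`, specificity `TN / (FP + TN)`, accuracy
#' `(TP + TN) / (TP + TN + FP + FN)`. A zero denominator yields `NA_real_`
#' (explicitly undefined) rather than NaN.
#'
#' @param counts A `confusion_counts` object.
#' @return Single numeric value.
#' @export
sensitivity <- function(counts) safe_ratio(counts$TP, counts$TP + counts$FN)

#' @rdname sensitivity
#' @export
specificity <- function(counts) safe_ratio(counts$TN, counts$FP + counts$TN)

#' @rdname sensitivity
#' @export
accuracy <- function(counts) {
  safe_ratio(counts$TP + counts$TN,
             counts$TP + counts$TN + counts$FP + counts$FN)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(FP+TN)(TN+FN))`, computed in
#' double precision with the denominator assembled as a product of square
#' roots, so counts up to ~1e5 do not overflow. When any denominator factor is
#' zero (single-class predictions or labels) the value is 0 with attribute
#' `undefined = TRUE`.
#'
#' @param counts A `confusion_counts` object.
#' @return Numeric in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  TP <- as.numeric(counts$TP); FP <- as.numeric(counts$FP)
  TN <- as.numeric(counts$TN); FN <- as.numeric(counts$FN)
  fac <- c(TP + FP, TP + FN, FP + TN, TN + FN)
  if (any(fac == 0))
    return(structure(0, undefined = TRUE))
  (TP * TN - FP * FN) / prod(sqrt(fac))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, with ties counting one half. Equivalent to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param labels Binary 0/1 vector with both classes present.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' (FPR, TPR) pairs over all distinct score thresholds, for plotting or
#' export.
#'
#' @inheritParams roc_auc
#' @return `data.frame` with columns `cutoff`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, scores) {
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- labels == 1
  do.call(rbind, lapply(cuts, function(ct) {
    call <- scores >= ct
    data.frame(cutoff = ct, fpr = sum(call & !pos) / sum(!pos),
               tpr = sum(call & pos) / sum(pos))
  }))
}

#' Full metrics report
#'
#' Confusion counts at the cutoff plus ACC/SEN/SPE/MCC and AUC in one object.
#'
#' @inheritParams roc_auc
#' @param cutoff Decision threshold.
#' @return Object of class `metrics_report`.
#' @export
metrics_report <- function(labels, scores, cutoff) {
  cc <- confusion(labels, scores, cutoff)
  structure(list(counts = cc, cutoff = cutoff,
                 ACC = accuracy(cc), SEN = sensitivity(cc),
                 SPE = specificity(cc), MCC = as.numeric(mcc(cc)),
                 AUC = roc_auc(labels, scores)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("cutoff %.3g | ACC %.3f SEN %.3f SPE %.3f MCC %.3f AUC %.3f\n",
              x$cutoff, x$ACC, x$SEN, x$SPE, x$MCC, x$AUC))
  print(x$counts)
  invisible(x)
}

#' Write a metrics report to CSV or JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path; format chosen by `.json` vs `.csv` extension.
#' @export
write_metrics_report <- function(report, path) {
  row <- data.frame(cutoff = report$cutoff, ACC = report$ACC, SEN = report$SEN,
                    SPE = report$SPE, MCC = report$MCC, AUC = report$AUC,
                    TP = report$counts$TP, FP = report$counts$FP,
                    TN = report$counts$TN, FN = report$counts$FN)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(row), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(row, path, row.names = FALSE)
  }
  invisible(path)
}
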
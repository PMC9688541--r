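#' Confusion counts for binary P300 detection
#'
#' Class 1 (P300) is "positive". TP: targets retrieved by the classifier;
#' TN: non-targets correctly not retrieved; FP: non-targets incorrectly
#' retrieved; FN: targets missed.
#'
#' @param labels,predictions Equal-length vectors with values in `{0, 1}`.
#' @return Object of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`
#'   and `n`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop_param("labels and predictions must have equal length")
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stop_param("labels and predictions must be binary 0/1")
  structure(list(TP = sum(labels == 1 & predictions == 1),
                 TN = sum(labels == 0 & predictions == 0),
                 FP = sum(labels == 0 & predictions == 1),
                 FN = sum(labels == 1 & predictions == 0),
                 n = length(labels)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  FN %d  TN %d (n = %d)\n",
              x$TP, x$FP, x$FN, x$TN, x$n))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' F-beta score from confusion counts
#'
#' `Fbeta = (1 + beta^2) TP / ((1 + beta^2) TP + beta^2 FN + FP)`;
#' `beta = 1` recovers the F1 score, `beta = 0.5` weights precision more,
#' `beta = 2` weights recall more.
#'
#' @param counts A [confusion()] result.
#' @param beta Positive weighting parameter.
#' @return The score, or `NA` when undefined (zero denominator).
#' @export
f_beta <- function(counts, beta = 1) {
  stopifnot(inherits(counts, "confusion_counts"), beta > 0)
  b2 <- beta^2
  safe_ratio((1 + b2) * counts$TP,
             (1 + b2) * counts$TP + b2 * counts$FN + counts$FP)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over the unique score thresholds (classify positive
#' at `prob >= t`): `sum_i (R_i - R_{i-1}) P_i` with points ordered by
#' decreasing threshold. No linear interpolation between points, avoiding
#' the optimism of interpolated PR curves. Invariant to strictly monotone
#' transforms of the scores; 1 for a perfect ranker.
#'
#' @param labels Binary labels.
#' @param probabilities Classifier scores for class 1.
#' @return AUPRC in \[0, 1\], `NA` if no positive labels.
#' @export
auprc <- function(labels, probabilities) {
  if (length(labels) != length(probabilities))
    stop_param("labels and probabilities must have equal length")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) return(NA_real_)
  ord <- order(probabilities, decreasing = TRUE)
  lab <- labels[ord]
  p <- probabilities[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  # keep the last index of each tied score block
  last <- c(p[-1] != p[-length(p)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' The metric suite over a confusion table
#'
#' Accuracy, precision, sensitivity (= recall), specificity
#' `TN / (TN + FP)`, F1, F0.5, F2, NPV `TN / (TN + FN)` and, when scores
#' are supplied, AUPRC. Ratios with zero denominators are returned as `NA`
#' and listed in the `undefined` element rather than silently set to 0.
#'
#' @param counts A [confusion()] result.
#' @param probabilities Optional class-1 scores (needed only for AUPRC).
#' @param labels Labels matching `probabilities`; must reproduce `counts`
#'   at threshold 0.5 when both are given.
#' @return Object of class `p300_metrics`.
#' @export
compute_metrics <- function(counts, probabilities = NULL, labels = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (!is.null(probabilities) && !is.null(labels)) {
    chk <- confusion(labels, as.integer(probabilities >= 0.5))
    if (!identical(unclass(chk)[1:4], unclass(counts)[1:4]))
      stop_param("counts are inconsistent with labels/probabilities at threshold 0.5")
  }
  m <- list(
    accuracy = safe_ratio(counts$TP + counts$TN, counts$n),
    precision = safe_ratio(counts$TP, counts$TP + counts$FP),
    sensitivity = safe_ratio(counts$TP, counts$TP + counts$FN),
    specificity = safe_ratio(counts$TN, counts$TN + counts$FP),
    npv = safe_ratio(counts$TN, counts$TN + counts$FN),
    f1 = f_beta(counts, 1),
    f0.5 = f_beta(counts, 0.5),
    f2 = f_beta(counts, 2),
    auprc = if (is.null(probabilities)) NA_real_
            else auprc(labels, probabilities))
  m$recall <- m$sensitivity
  und <- names(m)[vapply(m, is.na, logical(1))]
  structure(c(m, list(counts = counts, undefined = und)),
            class = "p300_metrics")
}

#' @export
print.p300_metrics <- function(x, digits = 4, ...) {
  nm <- c("accuracy", "precision", "sensitivity", "specificity", "npv",
          "f1", "f0.5", "f2", "auprc")
  for (k in nm)
    cat(sprintf("  %-12s %s\n", k,
                ifelse(is.na(x[[k]]), "undefined",
                       formatC(x[[k]], digits = digits, format = "f"))))
  if (length(x$undefined))
    cat("  undefined ratios:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' One-row data frame in the per-patient table layout
#'
#' Columns: Accuracy, F1, Precision, Sensitivity, Specificity, NPV, AUPRC,
#' F0.5, F2 -- the column layout of the per-patient evaluation tables.
#'
#' @param x A `p300_metrics`.
#' @param ... Unused.
#' @export
as.data.frame.p300_metrics <- function(x, ...) {
  data.frame(Accuracy = x$accuracy, F1 = x$f1, Precision = x$precision,
             Sensitivity = x$sensitivity, Specificity = x$specificity,
             NPV = x$npv, AUPRC = x$auprc, F0.5 = x$`f0.5`, F2 = x$f2,
             check.names = FALSE)
}

#' Metric suite for a cross-validation report
#'
#' Pooled out-of-fold metrics plus the per-fold metric rows.
#'
#' @param cv A [cross_validate()] result.
#' @return List with `pooled` (a `p300_metrics`) and `per_fold` (data frame
#'   of per-fold metric rows).
#' @export
evaluate_cv <- function(cv) {
  stopifnot(inherits(cv, "p300_cv"))
  pooled <- compute_metrics(confusion(cv$labels, cv$pred), cv$prob,
                            cv$labels)
  per_fold <- do.call(rbind, lapply(cv$folds, function(f) {
    m <- compute_metrics(confusion(cv$labels[f$test], f$pred), f$prob,
                         cv$labels[f$test])
    cbind(data.frame(fold = f$fold), as.data.frame(m))
  }))
  list(pooled = pooled, per_fold = per_fold)
}

#' Serialise a metric report to JSON
#'
#' @param metrics A `p300_metrics`.
#' @param path Output file.
#' @export
write_metrics_json <- function(metrics, path) {
  out <- metrics[c("accuracy", "precision", "sensitivity", "specificity",
                   "npv", "f1", "f0.5", "f2", "auprc")]
  out$counts <- unclass(metrics$counts)
  out$undefined <- metrics$undefined
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
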
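# Confusion-matrix performance metrics and one-vs-all ROC/AUC.

#' Confusion matrix of true vs predicted labels
#'
#' Rows are true classes (in `class_order`), columns predicted classes; any
#' prediction outside `class_order` (e.g. an expert reader's "inconclusive /
#' other" call) is collected into an extra `"other"` column, a prediction
#' category that can never be correct but still counts in the totals.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param class_order Class order for rows/columns; defaults to the canonical
#'   order of the classes present in `true_labels`.
#' @param other_label Column name for out-of-set predictions.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels, class_order = NULL,
                      other_label = "other") {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length", call. = FALSE)
  if (length(true_labels) == 0) stop("no labels given", call. = FALSE)
  if (is.null(class_order)) class_order <- order_classes(true_labels)
  if (!all(true_labels %in% class_order))
    stop("true labels outside `class_order`: ",
         paste(setdiff(true_labels, class_order), collapse = ", "),
         call. = FALSE)
  pred <- ifelse(predicted_labels %in% class_order, predicted_labels,
                 other_label)
  cols <- c(class_order,
            if (any(pred == other_label & !(other_label %in% class_order)))
              other_label)
  cm <- table(factor(true_labels, class_order), factor(pred, cols))
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
  structure(cm, class = c("confusion_matrix", "matrix"), class_order = class_order)
}

#' Per-class performance metrics from a confusion matrix
#'
#' One-vs-all reduction per class: TP is the diagonal entry, FN the rest of
#' the class row, FP the rest of the class column, TN everything else. Then
#' specificity = TN/(TN+FP), precision = TP/(TP+FP), sensitivity =
#' TP/(TP+FN), F1 = 2*Precision*Sensitivity/(Precision+Sensitivity), with the
#' convention that a zero denominator yields 0 (warned). Overall accuracy is
#' trace/total; "other" predictions are never on the diagonal and so always
#' count as errors.
#'
#' @param cm A [confusion()] matrix.
#' @return List with `per_class` (data frame: class, specificity, precision,
#'   sensitivity, f1) and `overall_accuracy`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  classes <- attr(cm, "class_order")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den, what, cl) {
    if (den == 0) {
      warning(sprintf("%s undefined for class %s (0/0); reported as 0", what, cl),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  rows <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- total - tp - fn - fp
    sp <- safe_div(tn, tn + fp, "specificity", cl)
    pr <- safe_div(tp, tp + fp, "precision", cl)
    se <- safe_div(tp, tp + fn, "sensitivity", cl)
    f1 <- if (pr + se == 0) 0 else 2 * pr * se / (pr + se)
    data.frame(class = cl, specificity = sp, precision = pr,
               sensitivity = se, f1 = f1, stringsAsFactors = FALSE)
  })
  list(per_class = do.call(rbind, rows),
       overall_accuracy = sum(diag(cm[, classes, drop = FALSE][classes, ,
                                                               drop = FALSE])) / total)
}

#' Overall accuracy as a proportion
#'
#' @param correct Number of correctly classified cases.
#' @param total Total number of cases (> 0).
#' @return `correct / total`.
#' @export
overall_accuracy <- function(correct, total) {
  if (!is_count(correct) || !is_count(total) || total == 0 || correct > total)
    stop("need 0 <= correct <= total with total > 0", call. = FALSE)
  correct / total
}

#' Integer percent, rounding half away from zero
#'
#' The rounding used when reporting accuracies as whole percentages
#' (e.g. 161/206 prints as 78).
#'
#' @param proportion Proportion(s) in `[0, 1]`.
#' @return Integer percent value(s).
#' @export
percent <- function(proportion) {
  sign(proportion) * floor(abs(proportion) * 100 + 0.5)
}

#' Harmonic-mean F1 from precision and sensitivity
#'
#' @param precision,sensitivity Values in `[0, 1]`.
#' @return `2 * P * S / (P + S)`, or 0 when `P + S == 0`.
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(precision + sensitivity == 0, 0,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' One-vs-all ROC AUC by the rank (Mann-Whitney) formulation
#'
#' AUC equals the probability that a randomly drawn subject of the positive
#' class scores higher than a randomly drawn subject of any other class; tied
#' scores contribute 1/2 (midranks).
#'
#' @param class_scores Numeric score per subject (higher = more
#'   positive-class-like).
#' @param true_labels Label vector aligned with `class_scores`.
#' @param positive_class The class treated as positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc_one_vs_all <- function(class_scores, true_labels, positive_class) {
  if (length(class_scores) != length(true_labels))
    stop("scores and labels must align", call. = FALSE)
  pos <- true_labels == positive_class
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop(sprintf("class %s absent from truth (or no negatives); AUC undefined",
                 positive_class), call. = FALSE)
  r <- rank(class_scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Render a metrics report as a compact table
#'
#' One row per approach mirroring the conventional per-class layout (F1,
#' specificity, precision, sensitivity per class, plus overall accuracy in
#' percent).
#'
#' @param report Output of [per_class_metrics()] / [evaluate_ensemble()].
#' @param digits Rounding for F1 (default 2).
#' @return A one-row data frame.
#' @export
metrics_table_row <- function(report, digits = 2) {
  pc <- report$per_class
  out <- list()
  for (i in seq_len(nrow(pc))) {
    cl <- pc$class[i]
    out[[paste0(cl, "_F1")]] <- round(pc$f1[i], digits)
    out[[paste0(cl, "_Sp")]] <- percent(pc$specificity[i])
    out[[paste0(cl, "_Pr")]] <- percent(pc$precision[i])
    out[[paste0(cl, "_Se")]] <- percent(pc$sensitivity[i])
  }
  out$overall_acc <- percent(report$overall_accuracy)
  as.data.frame(out)
}
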
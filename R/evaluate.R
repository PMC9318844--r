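# Confusion-matrix metrics with stressed (experimental) plots as the
# positive class, and the per-species / average-per-class aggregation used
# to report classifier performance.

#' Confusion matrix
#'
#' @param tp,fn,fp,tn non-negative counts. TP: stressed plots identified as
#'   stressed; FN: stressed plots missed; FP: control plots flagged; TN:
#'   control plots identified as control.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (sum(v) < 1) stop("confusion matrix must contain at least one sample")
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix TP %d FN %d FP %d TN %d>\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Build a confusion matrix from labels and predictions
#'
#' @param labels,predictions equal-length vectors of class values.
#' @param positive the positive (stressed) class value.
#' @return a [confusion_matrix()].
#' @export
confusion_from_predictions <- function(labels, predictions,
                                       positive = "experimental") {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  labels <- as.character(labels); predictions <- as.character(predictions)
  known <- unique(c(labels, predictions))
  if (!positive %in% known && length(labels))
    warning("positive class absent from data")
  confusion_matrix(tp = sum(labels == positive & predictions == positive),
                   fn = sum(labels == positive & predictions != positive),
                   fp = sum(labels != positive & predictions == positive),
                   tn = sum(labels != positive & predictions != positive))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)`, reported as percentages. Display values are rounded half-up
#' to 2 decimals; full precision is kept in the `*_exact` fields. A zero
#' denominator raises an error rather than silently reporting 0.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `accuracy`, `recall`, `specificity` (rounded percent)
#'   and `accuracy_exact`, `recall_exact`, `specificity_exact`.
#' @export
cm_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  if (tp + fn == 0) stop("recall undefined: no positive samples (TP + FN = 0)")
  if (tn + fp == 0) stop("specificity undefined: no negative samples (TN + FP = 0)")
  acc <- 100 * (tp + tn) / (tp + tn + fp + fn)
  rec <- 100 * tp / (tp + fn)
  spe <- 100 * tn / (tn + fp)
  list(accuracy = round_half_up(acc), recall = round_half_up(rec),
       specificity = round_half_up(spe),
       accuracy_exact = acc, recall_exact = rec, specificity_exact = spe)
}

#' Average-per-class metric aggregation
#'
#' Unweighted arithmetic mean of each metric across classes (species),
#' rounded half-up to 2 decimals for display.
#'
#' @param per_class a data frame or list of metric sets with `accuracy`,
#'   `recall`, `specificity` components (percent).
#' @return list with averaged `accuracy`, `recall`, `specificity`.
#' @export
aggregate_metrics <- function(per_class) {
  if (is.data.frame(per_class)) per_class <- split(per_class, seq_len(nrow(per_class)))
  if (!length(per_class)) stop("empty metric list")
  get <- function(field) vapply(per_class, function(m) {
    v <- m[[field]]
    if (is.null(v) || is.na(v)) stop("undefined metric entry in aggregation")
    as.numeric(v)
  }, numeric(1))
  list(accuracy = round_half_up(mean(get("accuracy"))),
       recall = round_half_up(mean(get("recall"))),
       specificity = round_half_up(mean(get("specificity"))))
}

#' Per-species evaluation of a classifier
#'
#' Partitions a test set by species, computes one confusion matrix and
#' metric set per species, and the average-per-class aggregation.
#'
#' @param model a trained `glnb` model.
#' @param test_set a `thermal_dataset`.
#' @return list with `per_species` (data frame) and `average` (list).
#' @export
evaluate_by_species <- function(model, test_set) {
  pr <- predict_glnb(model, test_set)
  pred_cond <- CONDITION_LEVELS[pr$class]
  out <- lapply(split(seq_along(test_set$images), test_set$species), function(ii) {
    cm <- confusion_from_predictions(as.character(test_set$labels[ii]),
                                     pred_cond[ii])
    m <- cm_metrics(cm)
    data.frame(n = length(ii), tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
               accuracy = m$accuracy, recall = m$recall,
               specificity = m$specificity)
  })
  per <- do.call(rbind, out)
  per <- cbind(species = rownames(per), per)
  rownames(per) <- NULL
  list(per_species = per, average = aggregate_metrics(per))
}

#' Format a metrics report table
#'
#' @param per_species data frame from [evaluate_by_species()].
#' @param average aggregated metrics list.
#' @return character vector of report lines.
#' @export
format_metrics_report <- function(per_species, average) {
  lines <- sprintf("%-18s %10s %10s %12s", "Vegetation type", "Accuracy",
                   "Recall", "Specificity")
  for (i in seq_len(nrow(per_species)))
    lines <- c(lines, sprintf("%-18s %9.2f%% %9.2f%% %11.2f%%",
                              per_species$species[i], per_species$accuracy[i],
                              per_species$recall[i], per_species$specificity[i]))
  c(lines, sprintf("%-18s %9.2f%% %9.2f%% %11.2f%%", "Average per-class",
                   average$accuracy, average$recall, average$specificity))
}
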
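#' Confusion counts for binary window predictions
#'
#' Preictal (1) is the positive class.
#'
#' @param y_true,y_pred 0/1 integer vectors of equal, nonzero length.
#' @return Object of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("confusion_counts: empty input")
  if (length(y_true) != length(y_pred)) {
    stop("confusion_counts: length mismatch")
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop("confusion_counts: labels must be 0 or 1")
  }
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, `SN = TP / (TP + FN)`.
#' Specificity has two selectable definitions: the standard
#' `TN / (TN + FP)` (default), and an "as-printed" variant `TN / (TP + TN)`
#' that some reports use; both are offered so either convention can be
#' reproduced. A zero denominator yields `NA` (undefined, never silently 0).
#'
#' @param counts a [confusion_counts()] object.
#' @param sp_definition `"standard"` or `"as-printed"`.
#' @return List with `acc`, `sn`, `sp` (rates in `[0, 1]` or `NA`).
#' @export
classification_metrics <- function(counts, sp_definition = c("standard", "as-printed")) {
  sp_definition <- match.arg(sp_definition)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, list(
    acc = safe_div(TP + TN, TP + TN + FP + FN),
    sn = safe_div(TP, TP + FN),
    sp = if (sp_definition == "standard") safe_div(TN, TN + FP)
         else safe_div(TN, TP + TN)))
}

#' False alarm rate over interictal windows
#'
#' Fraction of interictal time windows on which a preictal alarm was raised:
#' `FAR = N_alarm / N_wo`. An alarm is a single positive window prediction.
#'
#' @param pred_interictal 0/1 predictions restricted to interictal windows.
#' @return List with `far` (`NA` when there are no interictal windows),
#'   `n_alarm`, `n_wo`.
#' @export
false_alarm_rate <- function(pred_interictal) {
  n_wo <- length(pred_interictal)
  n_alarm <- sum(as.integer(pred_interictal) == 1L)
  list(far = if (n_wo > 0L) n_alarm / n_wo else NA_real_,
       n_alarm = n_alarm, n_wo = n_wo)
}

#' Per-fold evaluation report
#'
#' @param y_true,y_pred 0/1 labels and predictions on the held-out episode.
#' @param patient_id,held_out_episode identifiers carried into the report.
#' @param sp_definition see [classification_metrics()].
#' @return Object of class `fold_report` with confusion counts, `acc`,
#'   `sn`, `sp`, `far`, `n_alarm`, `n_wo`.
#' @export
fold_report <- function(y_true, y_pred, patient_id = "patient",
                        held_out_episode = NA_integer_,
                        sp_definition = "standard") {
  counts <- confusion_counts(y_true, y_pred)
  m <- classification_metrics(counts, sp_definition)
  far <- false_alarm_rate(y_pred[y_true == 0L])
  structure(c(list(patient_id = patient_id,
                   held_out_episode = held_out_episode, counts = counts),
              m, far),
            class = "fold_report")
}

#' @export
print.fold_report <- function(x, ...) {
  cat(sprintf("<fold_report> %s / episode %s: ACC %.4f SN %s SP %s FAR %s (n=%d)\n",
              x$patient_id, x$held_out_episode, x$acc,
              format(x$sn, digits = 4), format(x$sp, digits = 4),
              format(x$far, digits = 4),
              with(x$counts, TP + TN + FP + FN)))
  invisible(x)
}

#' Aggregate fold reports
#'
#' Mean and standard deviation of each metric across folds, plus a
#' pooled-confusion alternative in which the counts of every fold are summed
#' before computing the metrics.
#'
#' @param reports nonempty list of [fold_report()] objects.
#' @param sp_definition see [classification_metrics()].
#' @return List with `per_fold` (data frame), `mean`, `sd` and `pooled`.
#' @export
aggregate_folds <- function(reports, sp_definition = "standard") {
  if (!length(reports)) stop("aggregate_folds: no fold reports")
  per_fold <- do.call(rbind, lapply(reports, function(r) {
    data.frame(held_out_episode = r$held_out_episode, acc = r$acc, sn = r$sn,
               sp = r$sp, far = r$far, n = with(r$counts, TP + TN + FP + FN))
  }))
  metr <- c("acc", "sn", "sp", "far")
  mu <- vapply(metr, function(m) mean(per_fold[[m]], na.rm = TRUE), numeric(1))
  sdv <- vapply(metr, function(m) {
    v <- per_fold[[m]][!is.na(per_fold[[m]])]
    if (length(v) > 1L) stats::sd(v) else 0
  }, numeric(1))
  pooled_counts <- structure(list(
    TP = sum(vapply(reports, function(r) r$counts$TP, numeric(1))),
    TN = sum(vapply(reports, function(r) r$counts$TN, numeric(1))),
    FP = sum(vapply(reports, function(r) r$counts$FP, numeric(1))),
    FN = sum(vapply(reports, function(r) r$counts$FN, numeric(1)))),
    class = "confusion_counts")
  pooled <- classification_metrics(pooled_counts, sp_definition)
  pooled$far <- with(pooled_counts,
                     if (TN + FP > 0) FP / (TN + FP) else NA_real_)
  list(per_fold = per_fold, mean = as.list(mu), sd = as.list(sdv),
       pooled = pooled, pooled_counts = pooled_counts)
}
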
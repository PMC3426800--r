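#' Evaluate phenotype predictions against gold labels
#'
#' @description
#' Standard binary-classification scoring: a 2x2 confusion matrix and the
#' four derived metrics
#' precision = tp / (tp + fp), recall = tp / (tp + fn),
#' F1 = 2pr / (p + r), accuracy = (tp + tn) / total.
#' A metric with a zero denominator is reported as 0 with a warning, so
#' threshold sweeps never crash.
#'
#' @name evaluation
NULL

#' Confusion matrix of predictions against gold labels
#'
#' @param predictions Tibble with columns `patient_id` and `label` (logical
#'   or 0/1), e.g. from [classify_patients()].
#' @param gold Gold labels tibble (see [gold_labels()]).
#' @return A `confusion_matrix` object (one-row tibble with `tp`, `fp`,
#'   `tn`, `fn`).
#' @export
confusion <- function(predictions, gold) {
  predictions <- as_tibble(predictions)
  gold <- gold_labels(gold)
  missing_gold <- setdiff(predictions$patient_id, gold$patient_id)
  if (length(missing_gold) > 0) {
    abort(sprintf(
      "No gold label for patient(s): %s", paste(head(missing_gold, 10), collapse = ", ")
    ))
  }
  pred <- as.logical(predictions$label)
  truth <- gold$label[match(predictions$patient_id, gold$patient_id)]
  confusion_matrix(
    tp = sum(pred & truth), fp = sum(pred & !truth),
    tn = sum(!pred & !truth), fn = sum(!pred & truth)
  )
}

#' @rdname confusion
#' @param tp,fp,tn,fn Nonnegative counts.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  for (x in list(tp, fp, tn, fn)) assert_count(x, "count")
  structure(
    tibble(tp = as.integer(tp), fp = as.integer(fp),
           tn = as.integer(tn), fn = as.integer(fn)),
    class = c("confusion_matrix", class(tibble()))
  )
}

#' Precision, recall, F1 and accuracy from a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return One-row tibble: `precision`, `recall`, `f1`, `accuracy`, each in
#'   \[0, 1\].
#' @export
eval_metrics <- function(cm) {
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total == 0) abort("Empty confusion matrix.")
  precision <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision")
  recall <- safe_ratio(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- f_measure(precision, recall)
  tibble(
    precision = precision,
    recall = recall,
    f1 = f1,
    accuracy = (cm$tp + cm$tn) / total
  )
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warn(sprintf("%s undefined (zero denominator); reporting 0.", what))
    return(0)
  }
  num / den
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Values in \[0, 1\].
#' @return The F1 score; 0 when `precision + recall == 0`.
#' @export
f_measure <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' One-call evaluation of predictions against gold labels
#'
#' @inheritParams confusion
#' @return A `phenotype_eval` object bundling the confusion matrix and the
#'   metrics; supports [tidy()], [glance()] and [autoplot()].
#' @export
evaluate_predictions <- function(predictions, gold) {
  cm <- confusion(predictions, gold)
  structure(
    list(
      confusion = cm,
      metrics = eval_metrics(cm),
      method = if ("method" %in% names(predictions)) unique(predictions$method) else NA_character_
    ),
    class = "phenotype_eval"
  )
}

#' @export
print.phenotype_eval <- function(x, ...) {
  cm <- x$confusion
  m <- x$metrics
  cat(sprintf("<phenotype_eval>%s\n",
              if (!is.na(x$method[1])) paste0(" method: ", paste(x$method, collapse = "+")) else ""))
  cat(sprintf("  tp %d  fp %d  tn %d  fn %d\n", cm$tp, cm$fp, cm$tn, cm$fn))
  cat(sprintf(
    "  precision %.1f%%  recall %.1f%%  F1 %.1f%%  accuracy %.1f%%\n",
    percent_1dp(m$precision), percent_1dp(m$recall),
    percent_1dp(m$f1), percent_1dp(m$accuracy)
  ))
  invisible(x)
}

#' @method tidy phenotype_eval
#' @export
tidy.phenotype_eval <- function(x, ...) {
  m <- x$metrics
  tibble(
    metric = c("precision", "recall", "f1", "accuracy"),
    value = c(m$precision, m$recall, m$f1, m$accuracy),
    percent = percent_1dp(c(m$precision, m$recall, m$f1, m$accuracy))
  )
}

#' @method glance phenotype_eval
#' @export
glance.phenotype_eval <- function(x, ...) {
  dplyr::bind_cols(as_tibble(x$confusion), x$metrics)
}

#' Metrics across a grid of decision thresholds
#'
#' Re-labels graph predictions at each threshold and scores them, which is
#' useful for choosing the operating point (no area-under-curve summary is
#' computed).
#'
#' @param predictions Graph predictions with `seed_activation`.
#' @param gold Gold labels.
#' @param thresholds Numeric vector of thresholds.
#' @return Tibble with one row per threshold plus the metric columns.
#' @export
threshold_sweep <- function(predictions, gold, thresholds) {
  purrr::map_dfr(thresholds, function(th) {
    preds <- mutate(as_tibble(predictions), label = .data$seed_activation > th)
    dplyr::bind_cols(tibble(threshold = th), glance(evaluate_predictions(preds, gold)))
  })
}
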
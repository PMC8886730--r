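# Confusion matrix, the three reported classification metrics
# (sensitivity, positive predictive value, accuracy), report generation
# and multi-model comparison tables.

#' Binary confusion matrix
#'
#' @param y_true,y_pred Equal-length vectors with values in `{0, 1}`.
#' @param positive_label The class counted as positive (default 1).
#' @return Object of class `confusion_matrix` with counts `tp`, `fp`,
#'   `tn`, `fn` partitioning the sample.
#' @export
#' @examples
#' cm <- confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' sensitivity(cm)
confusion_matrix <- function(y_true, y_pred, positive_label = 1L) {
  if (!length(y_true)) stop("confusion_matrix: empty label vectors", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("confusion_matrix: y_true and y_pred lengths differ", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("confusion_matrix: labels must be binary 0/1", call. = FALSE)
  }
  pos <- y_true == positive_label
  pred_pos <- y_pred == positive_label
  structure(list(tp = sum(pos & pred_pos), fp = sum(!pos & pred_pos),
                 tn = sum(!pos & !pred_pos), fn = sum(pos & !pred_pos),
                 positive_label = positive_label,
                 n = length(y_true)),
            class = "confusion_matrix")
}

#' Construct a confusion matrix from counts
#'
#' Useful for re-deriving metrics from a published 2x2 table.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @param positive_label Positive class label.
#' @return A `confusion_matrix`.
#' @export
cm_from_counts <- function(tp, fp, tn, fn, positive_label = 1L) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("cm_from_counts: negative count", call. = FALSE)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 positive_label = positive_label, n = tp + fp + tn + fn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(true = c("negative", "positive"),
                              predicted = c("negative", "positive")))
  print(m)
  invisible(x)
}

# Round half-up at d decimals (presentation rounding; R's round() is
# round-half-even).
round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d

metric_round <- function(x, decimals) {
  if (is.null(decimals)) x else round_half_up(x, decimals)
}

#' Sensitivity (recall of the positive class), in percent
#'
#' `100 * tp / (tp + fn)`. Computed at full precision; `decimals` applies
#' half-up presentation rounding.
#'
#' @param cm A `confusion_matrix`.
#' @param decimals Optional decimal places (half-up); `NULL` = full
#'   precision.
#' @return Percent in \[0, 100\].
#' @export
sensitivity <- function(cm, decimals = NULL) {
  if (cm$tp + cm$fn == 0) {
    stop("sensitivity: undefined, no positive samples (tp + fn = 0)", call. = FALSE)
  }
  metric_round(100 * cm$tp / (cm$tp + cm$fn), decimals)
}

#' Positive predictive value (precision), in percent
#'
#' `100 * tp / (tp + fp)`.
#'
#' @inheritParams sensitivity
#' @return Percent in \[0, 100\].
#' @export
ppv <- function(cm, decimals = NULL) {
  if (cm$tp + cm$fp == 0) {
    stop("ppv: undefined, no positive calls (tp + fp = 0)", call. = FALSE)
  }
  metric_round(100 * cm$tp / (cm$tp + cm$fp), decimals)
}

#' Classification accuracy, in percent
#'
#' `100 * (tp + tn) / n`.
#'
#' @inheritParams sensitivity
#' @return Percent in \[0, 100\].
#' @export
accuracy <- function(cm, decimals = NULL) {
  if (cm$n == 0) stop("accuracy: empty confusion matrix", call. = FALSE)
  metric_round(100 * (cm$tp + cm$tn) / cm$n, decimals)
}

#' Specificity and negative predictive value, in percent
#'
#' @inheritParams sensitivity
#' @return Percent in \[0, 100\].
#' @export
specificity <- function(cm, decimals = NULL) {
  if (cm$tn + cm$fp == 0) {
    stop("specificity: undefined (tn + fp = 0)", call. = FALSE)
  }
  metric_round(100 * cm$tn / (cm$tn + cm$fp), decimals)
}

#' @rdname specificity
#' @export
npv <- function(cm, decimals = NULL) {
  if (cm$tn + cm$fn == 0) stop("npv: undefined (tn + fn = 0)", call. = FALSE)
  metric_round(100 * cm$tn / (cm$tn + cm$fn), decimals)
}

#' Evaluate a model on a manifest split
#'
#' Loads every image of the split, runs the model (in its current
#' ablation mode, loading masks when the mode needs them), takes the
#' argmax-probability decision and computes the three reported metrics.
#'
#' @param model A `medusa_model`.
#' @param manifest Manifest data frame (see [read_manifest()]) or a path
#'   to one.
#' @param dir Directory the manifest paths are relative to; defaults to
#'   the manifest's `dir` attribute or the CSV's directory.
#' @param split Which split to evaluate (`NULL` = all rows).
#' @param dataset_id,model_id Identifiers recorded in the report.
#' @return A `metrics_report`: sensitivity/ppv/accuracy (full precision,
#'   percent), the confusion matrix, `n`, ids and the ablation mode.
#' @export
evaluate <- function(model, manifest, dir = NULL, split = "test",
                     dataset_id = "dataset", model_id = "model") {
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(dir)) dir <- attr(manifest, "dir")
  if (is.null(dir)) stop("evaluate: cannot resolve the manifest's directory", call. = FALSE)
  rows <- if (is.null(split)) manifest else manifest[manifest$split == split, ]
  if (!nrow(rows)) stop("evaluate: split '", split, "' is empty", call. = FALSE)
  need_masks <- model$ablation_mode %in% c("seg_input_only", "seg_input_additive")
  samples <- load_manifest_samples(rows, dir, model$config$image_size,
                                   with_masks = need_masks)
  pred <- predict(model, lapply(samples, `[[`, "image"),
                  masks = if (need_masks) lapply(samples, `[[`, "lung_mask"))
  cm <- confusion_matrix(rows$label, pred)
  structure(list(sensitivity = metric_or_na(sensitivity, cm),
                 ppv = metric_or_na(ppv, cm),
                 accuracy = accuracy(cm), cm = cm, n = cm$n,
                 dataset_id = dataset_id, model_id = model_id,
                 ablation_mode = model$ablation_mode),
            class = "metrics_report")
}

# Degenerate splits (no positives, or no positive calls) leave a metric
# undefined; reports carry NA there while the metric functions stay strict.
metric_or_na <- function(fn, cm) {
  tryCatch(fn(cm), error = function(e) NA_real_)
}

#' Build a metrics report from labels and predictions
#'
#' @param y_true,y_pred Binary label vectors.
#' @param dataset_id,model_id Identifiers recorded in the report.
#' @param ablation_mode Mode tag for the report.
#' @return A `metrics_report`.
#' @export
metrics_report <- function(y_true, y_pred, dataset_id = "dataset",
                           model_id = "model", ablation_mode = "full") {
  cm <- confusion_matrix(y_true, y_pred)
  structure(list(sensitivity = metric_or_na(sensitivity, cm),
                 ppv = metric_or_na(ppv, cm),
                 accuracy = accuracy(cm), cm = cm, n = cm$n,
                 dataset_id = dataset_id, model_id = model_id,
                 ablation_mode = ablation_mode),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, decimals = 2, ...) {
  cat(sprintf("metrics_report [%s / %s, mode %s, n = %d]\n",
              x$model_id, x$dataset_id, x$ablation_mode, x$n))
  fmt <- function(v) if (is.na(v)) "NA" else
    sprintf("%.*f%%", decimals, round_half_up(v, decimals))
  cat("  sensitivity", fmt(x$sensitivity), " ppv", fmt(x$ppv),
      " accuracy", fmt(x$accuracy), "\n")
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report A `metrics_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(
    model_id = report$model_id, dataset_id = report$dataset_id,
    ablation_mode = report$ablation_mode, n = report$n,
    sensitivity = report$sensitivity, ppv = report$ppv,
    accuracy = report$accuracy,
    confusion_matrix = report$cm[c("tp", "fp", "tn", "fn")]),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Compare models in a table
#'
#' One row per report with the three metrics and, for each model, its
#' accuracy margin over the best competing model (antisymmetric for a
#' pair of reports; `NA` for a single one).
#'
#' @param reports List of `metrics_report` objects with unique
#'   `model_id`s.
#' @return Data frame with columns `model_id`, `sensitivity`, `ppv`,
#'   `accuracy`, `accuracy_margin`.
#' @export
compare_models <- function(reports) {
  if (!length(reports)) stop("compare_models: need at least one report", call. = FALSE)
  ids <- vapply(reports, `[[`, character(1), "model_id")
  if (anyDuplicated(ids)) {
    stop("compare_models: duplicate model id '", ids[anyDuplicated(ids)], "'",
         call. = FALSE)
  }
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  margin <- vapply(seq_along(acc), function(i) {
    if (length(acc) < 2) NA_real_ else acc[i] - max(acc[-i])
  }, numeric(1))
  data.frame(model_id = ids,
             sensitivity = vapply(reports, `[[`, numeric(1), "sensitivity"),
             ppv = vapply(reports, `[[`, numeric(1), "ppv"),
             accuracy = acc,
             accuracy_margin = margin,
             stringsAsFactors = FALSE)
}
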
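#' Confusion matrix from label vectors
#'
#' `M[i, j]` counts items of true class `i` predicted as class `j` (0-based
#' labels, rows/columns ordered by class index).
#'
#' @param true_labels,predicted_labels equal-length 0-based integer vectors.
#' @param n_classes class count `K`.
#' @param class_names optional class names (default `class_00 ...`).
#' @return a `K x K` integer matrix of class `confusion_matrix` with
#'   dimnames from `class_names`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes,
                             class_names = NULL) {
  stopifnot(length(true_labels) == length(predicted_labels))
  bad <- which(true_labels < 0 | true_labels >= n_classes |
                 predicted_labels < 0 | predicted_labels >= n_classes)
  if (length(bad) > 0)
    stop("label out of range [0, ", n_classes, ") at index ", bad[1])
  class_names <- class_names %||% sprintf("class_%02d", seq_len(n_classes) - 1)
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = class_names, predicted = class_names))
  for (i in seq_along(true_labels))
    m[true_labels[i] + 1L, predicted_labels[i] + 1L] <-
      m[true_labels[i] + 1L, predicted_labels[i] + 1L] + 1L
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Overall accuracy of a confusion matrix
#'
#' Multiclass reading: `trace(M) / sum(M)`.
#'
#' @param m a [confusion_matrix()] (any square count matrix works).
#' @export
overall_accuracy <- function(m) {
  if (sum(m) == 0) stop("empty confusion matrix")
  sum(diag(m)) / sum(m)
}

#' Per-class recall, precision and F1
#'
#' `Recall_i = M_ii / sum_j M_ij`, `Precision_i = M_ii / sum_j M_ji`,
#' `F1_i = 2 R P / (R + P)`. Degenerate denominators (no true items, no
#' predictions, or `R = P = 0`) yield 0 with the corresponding defined-flag
#' set to `FALSE`.
#'
#' @param m a [confusion_matrix()].
#' @return data.frame with columns `class`, `recall`, `precision`, `f1`,
#'   `support`, `recall_defined`, `precision_defined`, `f1_defined`.
#' @export
per_class_metrics <- function(m) {
  if (sum(m) == 0) stop("empty confusion matrix")
  tp <- diag(m)
  support <- rowSums(m)
  predn <- colSums(m)
  rdef <- support > 0
  pdef <- predn > 0
  recall <- ifelse(rdef, tp / support, 0)
  precision <- ifelse(pdef, tp / predn, 0)
  fdef <- rdef & pdef & (recall + precision > 0)
  f1 <- ifelse(fdef, 2 * recall * precision / (recall + precision), 0)
  data.frame(class = rownames(m) %||% sprintf("class_%02d", seq_along(tp) - 1),
             recall = recall, precision = precision, f1 = f1,
             support = as.integer(support), recall_defined = rdef,
             precision_defined = pdef, f1_defined = fdef,
             row.names = NULL)
}

# Half-up rounding to `digits` decimals (R's round() rounds half to even;
# published tables use half-up).
round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

#' F1 score from recall and precision
#'
#' Harmonic mean `2RP/(R+P)`; 0 when both are 0.
#'
#' @param recall,precision values in `[0, 1]` (vectorized).
#' @export
f1_score <- function(recall, precision) {
  ifelse(recall + precision == 0, 0,
         2 * recall * precision / (recall + precision))
}

#' Macro-averaged F1
#'
#' Unweighted mean of per-class F1 values. With `rounding = "table"` each F1
#' is first rounded half-up to 2 decimals, which reproduces averages printed
#' in report tables; `"none"` keeps full precision. Classes whose F1 is
#' degenerate count as 0 unless `drop_undefined = TRUE`.
#'
#' @param metrics a data.frame from [per_class_metrics()], or a numeric
#'   vector of F1 values.
#' @param rounding `"none"` or `"table"`.
#' @param drop_undefined exclude degenerate classes from the average.
#' @export
macro_average_f1 <- function(metrics, rounding = c("none", "table"),
                             drop_undefined = FALSE) {
  rounding <- match.arg(rounding)
  if (is.data.frame(metrics)) {
    f1 <- metrics$f1
    if (drop_undefined) f1 <- f1[metrics$f1_defined]
  } else f1 <- as.numeric(metrics)
  if (length(f1) == 0) stop("no F1 values to average")
  if (rounding == "table") f1 <- round_half_up(f1, 2)
  mean(f1)
}

#' Grouped metric report
#'
#' Splits the classes into named groups (e.g. diseased vs healthy leaves)
#' and emits one per-class metric table per group plus group macro-averaged
#' F1 values and the overall accuracy.
#'
#' @param m a [confusion_matrix()].
#' @param class_names class names (defaults to the matrix dimnames).
#' @param split_map named list of 0-based class-index vectors forming a
#'   partition of `0:(K-1)`.
#' @return list with `tables` (named list of per-group data.frames),
#'   `group_macro_f1`, `overall_accuracy`, `macro_f1` (all classes).
#' @export
metrics_report <- function(m, class_names = rownames(m), split_map) {
  K <- nrow(m)
  idx <- sort(unlist(split_map))
  if (!identical(as.integer(idx), seq_len(K) - 1L))
    stop("split_map must partition 0:(K-1)")
  pm <- per_class_metrics(m)
  pm$class <- class_names
  tables <- lapply(split_map, function(ix) pm[ix + 1L, , drop = FALSE])
  list(tables = tables,
       group_macro_f1 = vapply(tables, macro_average_f1, 1.0),
       overall_accuracy = overall_accuracy(m),
       macro_f1 = macro_average_f1(pm))
}

#' Write a metrics report as CSV + JSON
#'
#' One CSV per group (columns class, recall, precision, f1, support) plus a
#' JSON summary with the overall accuracy and macro averages.
#'
#' @param report a [metrics_report()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables))
    write.csv(report$tables[[nm]][, c("class", "recall", "precision", "f1",
                                      "support")],
              file.path(dir, paste0("metrics_", nm, ".csv")),
              row.names = FALSE)
  jsonlite::write_json(list(overall_accuracy = report$overall_accuracy,
                            macro_f1 = report$macro_f1,
                            group_macro_f1 = as.list(report$group_macro_f1)),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Evaluate a prediction CSV
#'
#' Reads a CSV with columns `item_id`, `true_label`, `predicted_label`
#' (0-based) and returns the confusion matrix and per-class metrics.
#'
#' @param pred_file CSV path.
#' @param n_classes class count.
#' @param class_names optional class names.
#' @export
evaluate_predictions <- function(pred_file, n_classes, class_names = NULL) {
  df <- read.csv(pred_file)
  stopifnot(all(c("true_label", "predicted_label") %in% names(df)))
  m <- confusion_matrix(df$true_label, df$predicted_label, n_classes,
                        class_names)
  list(confusion = m, metrics = per_class_metrics(m),
       accuracy = overall_accuracy(m))
}
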
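# Confusion-matrix construction and the per-class / macro-averaged metric
# suite. Conventions: rows are the true class, columns the predicted class;
# per-class "accuracy" is the class recall (the convention of the study's
# result tables, where each class row's accuracy equals its sensitivity);
# the one-vs-rest accuracy (TP+TN)/total is reported separately as
# `ovr_accuracy`. Displayed values are percentages rounded half-up to two
# decimals; raw values are always retained.

#' Confusion matrix from label vectors
#'
#' @param truth,predicted Equal-length vectors of 0-based class labels.
#' @param K Number of classes; inferred from the labels when `NULL`.
#' @return A `confusion_matrix`: `K x K` integer matrix, `counts[i, j]` =
#'   number of samples with true class `i-1` predicted as `j-1`.
#' @export
#' @examples
#' confusion(c(0, 0, 1, 1), c(0, 1, 1, 1)) # [[1,1],[0,2]]
confusion <- function(truth, predicted, K = NULL) {
  if (length(truth) != length(predicted)) {
    stop("label vectors must have equal length.", call. = FALSE)
  }
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (is.null(K)) K <- max(truth, predicted) + 1L
  if (any(truth < 0 | truth >= K) || any(predicted < 0 | predicted >= K)) {
    stop("labels out of range [0, K).", call. = FALSE)
  }
  cm <- matrix(0L, K, K,
               dimnames = list(true = 0:(K - 1L), predicted = 0:(K - 1L)))
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, predicted[i] + 1L] <- cm[truth[i] + 1L, predicted[i] + 1L] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Per-class metrics from a confusion matrix
#'
#' One-vs-rest counts for class `c`: TP (true `c` predicted `c`), FP, FN,
#' TN. Sensitivity = TP/(TP+FN), precision = TP/(TP+FP), specificity =
#' TN/(TN+FP), F-score = harmonic mean of precision and sensitivity; the
#' per-class `accuracy` column follows the table convention and equals the
#' sensitivity, while `ovr_accuracy` is (TP+TN)/total. All as raw
#' percentages. Ratios with zero denominators are reported as 0 and
#' flagged in the `undefined` column.
#'
#' @param cm A [confusion()] matrix.
#' @param class 0-based class index.
#' @return One-row tibble.
#' @export
class_metrics <- function(cm, class) {
  K <- nrow(cm)
  c1 <- class + 1L
  stopifnot(c1 >= 1, c1 <= K)
  tp <- cm[c1, c1]
  fn <- sum(cm[c1, ]) - tp
  fp <- sum(cm[, c1]) - tp
  tn <- sum(cm) - tp - fn - fp
  rate <- function(num, den) if (den == 0) c(0, TRUE) else c(100 * num / den, FALSE)
  sens <- rate(tp, tp + fn)
  prec <- rate(tp, tp + fp)
  spec <- rate(tn, tn + fp)
  f <- if (prec[1] == 0 && sens[1] == 0) c(0, TRUE) else
    c(f_score_from(prec[1], sens[1]), FALSE)
  tibble::tibble(class = as.integer(class),
                 accuracy = sens[1],
                 ovr_accuracy = 100 * (tp + tn) / sum(cm),
                 precision = prec[1],
                 sensitivity = sens[1],
                 specificity = spec[1],
                 f_score = f[1],
                 undefined = any(c(sens[2], prec[2], spec[2], f[2]) == 1))
}

#' F-score from precision and sensitivity percentages
#'
#' Harmonic mean `2 P S / (P + S)`, on the percent scale. The degenerate
#' `P = S = 0` case is defined as 0 (with attribute `undefined = TRUE`).
#'
#' @param precision,sensitivity Percentages in `[0, 100]`.
#' @return F-score percentage.
#' @export
#' @examples
#' round_half_up(f_score_from(100, 93.97), 2) # 96.89
f_score_from <- function(precision, sensitivity) {
  stopifnot(precision >= 0, precision <= 100,
            sensitivity >= 0, sensitivity <= 100)
  if (precision == 0 && sensitivity == 0) {
    return(structure(0, undefined = TRUE))
  }
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Macro (unweighted) average of per-class metric rows
#'
#' @param per_class Tibble of [class_metrics()] rows.
#' @return One-row tibble of column means over classes (metric columns
#'   only).
#' @export
macro_average <- function(per_class) {
  stopifnot(nrow(per_class) >= 1)
  cols <- c("accuracy", "ovr_accuracy", "precision", "sensitivity",
            "specificity", "f_score")
  cols <- intersect(cols, names(per_class))
  tibble::as_tibble(as.list(colMeans(per_class[, cols])))
}

#' Full evaluation of a predicted label set
#'
#' Builds the confusion matrix, per-class metrics, macro averages, overall
#' accuracy (trace/total), and a display table rounded half-up to two
#' decimals. Raw values are retained alongside.
#'
#' @param truth,predicted Equal-length 0-based label vectors (non-empty).
#' @param K Number of classes (inferred when `NULL`).
#' @param class_names Optional display names per class.
#' @return A `metrics_report` list: `confusion`, `per_class`, `macro`,
#'   `overall_accuracy`, `display`.
#' @export
evaluate_split <- function(truth, predicted, K = NULL, class_names = NULL) {
  if (length(truth) == 0) stop("empty label vectors.", call. = FALSE)
  cm <- confusion(truth, predicted, K)
  K <- nrow(cm)
  per_class <- do.call(rbind, lapply(0:(K - 1L), function(c) class_metrics(cm, c)))
  macro <- macro_average(per_class)
  overall <- 100 * sum(diag(cm)) / sum(cm)
  if (is.null(class_names)) class_names <- sprintf("class_%d", 0:(K - 1L))
  disp_cols <- c("accuracy", "precision", "sensitivity", "specificity", "f_score")
  display <- tibble::tibble(class = c(class_names, "Average"))
  for (col in disp_cols) {
    display[[col]] <- round_half_up(c(per_class[[col]], macro[[col]]), 2)
  }
  structure(list(confusion = cm, per_class = per_class, macro = macro,
                 overall_accuracy = overall, display = display,
                 class_names = class_names),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> overall accuracy",
      format(round_half_up(x$overall_accuracy, 2), nsmall = 2), "%\n")
  print(as.data.frame(x$display), row.names = FALSE)
  invisible(x)
}

#' Tidy a metrics report into a long tibble
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Long tibble with `class`, `metric`, `value` (raw percentages;
#'   class `"macro"` rows hold the averages).
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  pc <- x$per_class
  cols <- c("accuracy", "ovr_accuracy", "precision", "sensitivity",
            "specificity", "f_score")
  long <- do.call(rbind, lapply(cols, function(col) {
    tibble::tibble(class = c(as.character(pc$class), "macro"),
                   metric = col,
                   value = c(pc[[col]], x$macro[[col]]))
  }))
  long
}

#' One-row summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return One-row tibble with overall accuracy and macro metrics.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(n = sum(x$confusion),
                 overall_accuracy = x$overall_accuracy,
                 macro_precision = x$macro$precision,
                 macro_sensitivity = x$macro$sensitivity,
                 macro_specificity = x$macro$specificity,
                 macro_f_score = x$macro$f_score)
}

#' Heatmap of a report's confusion matrix
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot tile plot of the confusion counts.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::tibble(
    true = factor(rep(object$class_names, times = ncol(cm)),
                  levels = rev(object$class_names)),
    predicted = factor(rep(object$class_names, each = nrow(cm)),
                       levels = object$class_names),
    count = as.vector(cm)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

#' Write a metrics report to CSV and YAML
#'
#' The CSV mirrors the result-table layout (one row per class plus the
#' average row, displayed 2-decimal values); the YAML carries the raw
#' unrounded values and the confusion counts for lossless round-tripping.
#'
#' @param report A `metrics_report`.
#' @param dir Output directory.
#' @param phase Tag recorded in the files (e.g. `"training"`/`"testing"`).
#' @return Paths of the written files, invisibly.
#' @export
write_metrics_report <- function(report, dir, phase = "evaluation") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0("metrics_", phase, ".csv"))
  disp <- report$display
  disp <- tibble::add_column(disp, phase = phase, .before = 1)
  utils::write.csv(disp, csv, row.names = FALSE)
  yml <- file.path(dir, paste0("metrics_", phase, ".yaml"))
  yaml::write_yaml(list(phase = phase,
                        overall_accuracy = report$overall_accuracy,
                        per_class = lapply(seq_len(nrow(report$per_class)),
                                           function(i) as.list(report$per_class[i, ])),
                        macro = as.list(report$macro),
                        confusion = apply(unclass(report$confusion), 1, as.list)),
                   yml, precision = 15)
  invisible(c(csv = csv, yaml = yml))
}

#' Read back a metrics report written by [write_metrics_report()]
#'
#' @param yaml_path Path to the YAML file.
#' @return A list with the raw values (`overall_accuracy`, `per_class`
#'   tibble, `macro` tibble).
#' @export
read_metrics_report <- function(yaml_path) {
  y <- yaml::read_yaml(yaml_path)
  list(phase = y$phase,
       overall_accuracy = y$overall_accuracy,
       per_class = do.call(rbind, lapply(y$per_class, tibble::as_tibble)),
       macro = tibble::as_tibble(y$macro))
}
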
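#' The MIS "1+1" signature panel
#'
#' The boolean co-expression rule defining a metastasis-initiating cell:
#' at least one Group A gene AND at least one Group B gene with
#' `count >= count_threshold` in the same cell. Defaults are the 7-gene
#' MIS panel split as Group A = C19orf33, S100A14, RHOD and Group B =
#' CST6, CD44, TM4SF1, TACSTD2 with threshold 1.
#'
#' @param group_a,group_b Disjoint, non-empty gene identifier vectors.
#' @param count_threshold Positive integer count threshold (default 1).
#' @return An object of class `signature_panel`.
#' @export
signature_panel <- function(group_a = c("C19orf33", "S100A14", "RHOD"),
                            group_b = c("CST6", "CD44", "TM4SF1", "TACSTD2"),
                            count_threshold = 1L) {
  if (!length(group_a) || !length(group_b)) {
    stop_config("group_a/group_b", "must be non-empty")
  }
  if (length(intersect(group_a, group_b))) {
    stop_config("group_a/group_b", "must be disjoint")
  }
  if (count_threshold < 1) stop_config("count_threshold", "must be >= 1")
  structure(list(group_a = group_a, group_b = group_b,
                 count_threshold = as.integer(count_threshold)),
            class = "signature_panel")
}

#' @export
print.signature_panel <- function(x, ...) {
  cat("<signature_panel> 1+1 rule, count >=", x$count_threshold, "\n",
      "A:", paste(x$group_a, collapse = ", "), "\n",
      "B:", paste(x$group_b, collapse = ", "), "\n")
  invisible(x)
}

#' Classify cells with the 1+1 co-expression rule
#'
#' A cell is called a MIC iff some Group A gene and some Group B gene each
#' reach the panel's count threshold. Raw counts only: normalized matrices
#' are rejected because the `count >= 1` threshold has no meaning on a
#' log scale.
#'
#' @param matrix A [count_matrix()].
#' @param panel A [signature_panel()]; all panel genes must be present.
#' @return A tibble with one row per cell: `cell_id`, metadata columns,
#'   and logical `mic_call`.
#' @export
classify_cells <- function(matrix, panel = signature_panel()) {
  if (inherits(matrix, "normalized_matrix")) {
    abort(paste("classify_cells requires raw counts: the count >= threshold",
                "rule is undefined on normalized values"),
          class = "mictrack_input_error")
  }
  stopifnot(inherits(matrix, "count_matrix"))
  missing <- setdiff(c(panel$group_a, panel$group_b), matrix$gene_ids)
  if (length(missing)) {
    abort(paste0("panel genes missing from matrix: ",
                 paste(missing, collapse = ", ")),
          class = "mictrack_input_error")
  }
  thr <- panel$count_threshold
  a_hit <- Matrix::rowSums(matrix$counts[, panel$group_a, drop = FALSE] >= thr) > 0
  b_hit <- Matrix::rowSums(matrix$counts[, panel$group_b, drop = FALSE] >= thr) > 0
  dplyr::mutate(matrix$cell_meta, mic_call = unname(a_hit & b_hit))
}

new_confusion_metrics <- function(tp, fp, fn, tn, ppv, npv, sensitivity,
                                  specificity, accuracy, n, analytic = FALSE) {
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, ppv = ppv, npv = npv,
                 sensitivity = sensitivity, specificity = specificity,
                 accuracy = accuracy, n = n, analytic = analytic),
            class = "confusion_metrics")
}

#' Confusion-matrix evaluation of a binary classifier
#'
#' Tabulates TP/FP/FN/TN of predictions against ground truth and derives
#' PPV, NPV, sensitivity, specificity and accuracy. A rate whose
#' denominator is zero is `NA`, never an error. Raw counts are always
#' reported alongside the rates so every derived value is auditable.
#'
#' @param predicted,truth Logical vectors of equal positive length.
#' @param subset Optional logical mask restricting evaluation to a cell
#'   subset (e.g. parental cells only).
#' @return An object of class `confusion_metrics`; see [tidy()] for the
#'   one-row tibble form.
#' @export
evaluate_classifier <- function(predicted, truth, subset = NULL) {
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  if (length(predicted) != length(truth)) {
    abort("predicted and truth must have equal length",
          class = "mictrack_input_error")
  }
  if (!is.null(subset)) {
    predicted <- predicted[subset]
    truth <- truth[subset]
  }
  if (!length(predicted)) {
    abort("no cells to evaluate", class = "mictrack_input_error")
  }
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  tn <- sum(!predicted & !truth)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  new_confusion_metrics(
    tp = tp, fp = fp, fn = fn, tn = tn,
    ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn),
    sensitivity = rate(tp, tp + fn), specificity = rate(tn, tn + fp),
    accuracy = (tp + tn) / (tp + fp + fn + tn), n = tp + fp + fn + tn)
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics>%s\n", if (x$analytic) " (analytic)" else ""))
  if (!x$analytic) {
    cat(sprintf("  tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
                x$tp, x$fp, x$fn, x$tn, x$n))
  }
  cat(sprintf("  ppv=%.4f npv=%.4f sens=%.4f spec=%.4f acc=%.4f\n",
              x$ppv, x$npv, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' @rdname evaluate_classifier
#' @param x A `confusion_metrics` object.
#' @param ... Unused.
#' @export
tidy.confusion_metrics <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
                 ppv = x$ppv, npv = x$npv, sensitivity = x$sensitivity,
                 specificity = x$specificity, accuracy = x$accuracy)
}

#' Subpopulation fraction trajectory across timepoints
#'
#' Fraction of positively labelled cells per timepoint, with counts
#' reported alongside. Timepoints with no cells yield an `NA` fraction,
#' distinct from an observed zero.
#'
#' @param labels Logical label per cell.
#' @param timepoints Categorical timepoint per cell (same length).
#' @return A tibble: `timepoint`, `n_cells`, `n_positive`, `fraction`.
#' @export
subpopulation_trajectory <- function(labels, timepoints) {
  if (length(labels) != length(timepoints)) {
    abort("labels and timepoints must have equal length",
          class = "mictrack_input_error")
  }
  tp <- if (is.factor(timepoints)) timepoints else factor(timepoints,
        levels = unique(timepoints))
  tab <- tibble::tibble(timepoint = tp, label = as.logical(labels)) |>
    dplyr::group_by(.data$timepoint, .drop = FALSE) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_positive = sum(.data$label), .groups = "drop")
  dplyr::mutate(tab, fraction = ifelse(.data$n_cells > 0,
                                       .data$n_positive / .data$n_cells,
                                       NA_real_))
}
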
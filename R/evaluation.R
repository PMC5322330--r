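#' Create an empty confusion matrix
#'
#' Rows are the true class, columns the prediction, in schema order.
#'
#' @param class_levels Character vector of class labels.
#' @return A k x k integer matrix of class `confusion_matrix`.
#' @export
new_confusion_matrix <- function(class_levels) {
  k <- length(class_levels)
  if (k < 1L) stop("need at least one class level")
  structure(matrix(0L, k, k, dimnames = list(truth = class_levels,
                                             predicted = class_levels)),
            class = c("confusion_matrix", "matrix"))
}

#' Record one prequential test
#'
#' Increments exactly one cell (truth row, prediction column).
#'
#' @param cm A [new_confusion_matrix()].
#' @param truth,predicted Class labels (or 1-based indices).
#' @return The updated matrix.
#' @export
prequential_update <- function(cm, truth, predicted) {
  ti <- cm_index(cm, truth)
  pi <- cm_index(cm, predicted)
  cm[ti, pi] <- cm[ti, pi] + 1L
  cm
}

cm_index <- function(cm, label) {
  if (is.numeric(label)) {
    i <- as.integer(label)
    if (i < 1L || i > nrow(cm)) stop("class index ", i, " out of range")
    return(i)
  }
  i <- match(as.character(label), rownames(cm))
  if (is.na(i)) stop("unknown class label '", label, "'")
  i
}

#' Prequential accuracy of a confusion matrix
#'
#' Trace over total. With zero recorded tests the accuracy is defined as 0
#' (and carries attribute `no_tests = TRUE`): a learner that has answered
#' nothing has demonstrated nothing.
#'
#' @param cm A confusion matrix.
#' @return Accuracy in `[0, 1]`.
#' @export
cm_accuracy <- function(cm) {
  n <- sum(cm)
  if (n == 0) return(structure(0, no_tests = TRUE))
  sum(diag(cm)) / n
}

#' Cohen's kappa of a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace / n` and chance agreement
#' `p_e = sum_c row_c * col_c / n^2`. When `p_e = 1` (all mass in a single
#' cell, so chance agreement is saturated) kappa is defined as 1 if the
#' agreement is perfect and 0 otherwise — the value reported for degenerate
#' one-class predictors.
#'
#' @param cm A confusion matrix with at least one recorded test.
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' cm <- matrix(c(45, 25, 15, 15), 2, 2)  # truth in rows
#' cohen_kappa(cm)  # ~0.1304
cohen_kappa <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("kappa is undefined for an empty confusion matrix")
  po <- sum(diag(as.matrix(cm))) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1 - 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Qualitative band of a kappa value
#'
#' Maps `kappa * 100` to the conventional agreement bands: up to 20
#' "Slight" (negative values included), (20, 40] "Fair", (40, 60]
#' "Moderate", (60, 80] "Substantial", (80, 100] "Almost perfect". The
#' intervals are half-open on their stated upper bounds.
#'
#' @param kappa Value in `[-1, 1]`.
#' @return The band label.
#' @export
kappa_band <- function(kappa) {
  if (!is.numeric(kappa) || is.na(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must lie in [-1, 1]")
  }
  pct <- kappa * 100
  if (pct <= 20) "Slight"
  else if (pct <= 40) "Fair"
  else if (pct <= 60) "Moderate"
  else if (pct <= 80) "Substantial"
  else "Almost perfect"
}

#' Assemble the final prequential report
#'
#' Combines the per-window trace with finals computed from the cumulative
#' confusion matrix and the final model.
#'
#' @param trace Per-window `data.frame` (from [run_stream()]).
#' @param cm The cumulative confusion matrix.
#' @param model The final [hoeffding_tree()].
#' @param config Config list echoed verbatim.
#' @param counts Named list of run accounting counts.
#' @param timing Named list of wall-clock components (non-deterministic;
#'   kept apart from the deterministic results).
#' @return An object of class `prequential_report`.
#' @export
summarize_run <- function(trace, cm, model, config = list(), counts = list(),
                          timing = list()) {
  if (!nrow(trace)) stop("cannot summarize an empty trace")
  acc <- cm_accuracy(cm)
  kap <- if (sum(cm) > 0) cohen_kappa(cm) else NA_real_
  finals <- list(
    accuracy = as.numeric(acc),
    kappa = kap,
    kappa_band = if (is.na(kap)) NA_character_ else kappa_band(kap),
    tree_size = tree_size(model),
    n_windows = nrow(trace),
    n_tested = sum(cm))
  finals <- c(finals, counts)
  structure(list(config = config, windows = trace, finals = finals,
                 confusion = unclass(cm), timing = timing),
            class = "prequential_report")
}

#' @export
print.prequential_report <- function(x, ...) {
  f <- x$finals
  cat("prequential_report:", f$n_windows, "windows,", f$n_tested, "tests\n")
  cat(sprintf("  accuracy %.4f | kappa %.4f (%s) | tree size %d\n",
              f$accuracy, f$kappa, f$kappa_band, f$tree_size))
  if (!is.null(f$n_outliers_total)) {
    cat(sprintf("  outliers %d (removed to DB %d, retained kept %d, retained noise %d)\n",
                f$n_outliers_total, f$n_removed_db, f$n_retained_kept,
                f$n_retained_noise))
  }
  if (length(x$timing)) {
    cat(sprintf("  t_ODR = %.3fs (ODR-A %.3fs + ODR-R %.3fs), total %.3fs\n",
                x$timing$t_odr_a + x$timing$t_odr_r, x$timing$t_odr_a,
                x$timing$t_odr_r, x$timing$t_total))
  }
  invisible(x)
}

#' Deterministic JSON form of a report
#'
#' Serializes everything except the wall-clock `timing` section; identical
#' config + seed yields a byte-identical string. [write_report()] writes the
#' full report (including timing) to a file.
#'
#' @param report A `prequential_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  core <- report[setdiff(names(report), c("timing", "model"))]
  as.character(jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA, na = "null"))
}

#' @rdname report_json
#' @param path Output file path.
#' @export
write_report <- function(report, path) {
  out <- report[intersect(c("config", "windows", "finals", "confusion",
                            "outliers", "timing"), names(report))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
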
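#' Empirical quantile of a window (inverse empirical CDF)
#'
#' Linear interpolation of order statistics: with sorted values
#' `x_(1..n)` and position `h = p * (n - 1)`, returns
#' `x_(floor(h)+1) + (h - floor(h)) * (x_(floor(h)+2) - x_(floor(h)+1))`
#' (the common "type 7" convention, computed via [stats::quantile()]).
#' Missing values are dropped first.
#'
#' @param values Numeric vector.
#' @param p Probability (or vector of probabilities) in `[0, 1]`.
#' @return Quantile value(s); `p = 0` gives the minimum, `p = 1` the maximum.
#' @export
#' @examples
#' empirical_quantile(c(2, 4, 6, 8, 10, 12, 14, 16), 0.25)  # 5.5
empirical_quantile <- function(values, p) {
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("'p' must be a probability in [0, 1]")
  }
  x <- values[!is.na(values)]
  if (!length(x)) stop("no non-missing values to take a quantile of")
  stats::quantile(x, probs = p, type = 7, names = FALSE)
}

#' Per-attribute quartile fences for one window
#'
#' Computes Q1, Q3, the interquartile range `IQR = Q3 - Q1`, and the fences
#' `[Q1 - beta * IQR, Q3 + beta * IQR]` (the Tukey form). The alternative
#' `fence_dialect = "paper"` uses `Q1 + beta * IQR` as the lower fence, which
#' deliberately violates the `lower_fence <= Q1` ordering; it exists for
#' auditing only and is never the default.
#'
#' @param values Numeric vector (one attribute's values over a window).
#' @param beta Tolerance factor, `beta >= 0`.
#' @param attribute Optional attribute name carried along in the result.
#' @param fence_dialect `"standard"` (Tukey) or `"paper"`.
#' @return An object of class `quartile_summary` with fields `attribute`,
#'   `q1`, `q3`, `iqr`, `beta`, `lower_fence`, `upper_fence`, `n_used`, and
#'   `usable` (`FALSE` when every value is missing).
#' @export
quartile_summary <- function(values, beta, attribute = NA_character_,
                             fence_dialect = c("standard", "paper")) {
  fence_dialect <- match.arg(fence_dialect)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("beta must be a single non-negative number")
  }
  if (!is.numeric(values)) stop("quartile fences apply to numeric attributes only")
  x <- values[!is.na(values)]
  if (!length(x)) {
    return(structure(list(attribute = attribute, q1 = NA_real_, q3 = NA_real_,
                          iqr = NA_real_, beta = beta, lower_fence = NA_real_,
                          upper_fence = NA_real_, n_used = 0L, usable = FALSE),
                     class = "quartile_summary"))
  }
  q <- empirical_quantile(x, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  lower <- if (fence_dialect == "standard") q[1] - beta * iqr else q[1] + beta * iqr
  structure(list(attribute = attribute, q1 = q[1], q3 = q[2], iqr = iqr,
                 beta = beta, lower_fence = lower, upper_fence = q[2] + beta * iqr,
                 n_used = length(x), usable = TRUE),
            class = "quartile_summary")
}

#' @export
print.quartile_summary <- function(x, ...) {
  cat(sprintf("quartile_summary%s: Q1=%.4g Q3=%.4g IQR=%.4g fences=[%.4g, %.4g] (beta=%g, n=%d)\n",
              if (is.na(x$attribute)) "" else paste0(" [", x$attribute, "]"),
              x$q1, x$q3, x$iqr, x$lower_fence, x$upper_fence, x$beta, x$n_used))
  invisible(x)
}

#' Split a window into clean instances and fence-violating outliers
#'
#' For every numeric attribute of the window, quartile fences are computed
#' and values strictly outside them are violations (boundary values are
#' clean). Under `rule = "any"` one violated attribute flags the instance;
#' under `rule = "fraction"` the fraction of violated numeric attributes must
#' exceed `tau`. Missing values never violate a fence. The class column, if
#' present, is ignored: labels must not leak into outlier detection.
#'
#' @param window A `data.frame` or numeric matrix of window rows (instances),
#'   or an [odr_stream()] together with `start`/`length`.
#' @param beta Fence tolerance factor (>= 0).
#' @param rule `"any"` or `"fraction"`.
#' @param tau Fraction threshold for `rule = "fraction"`.
#' @param fence_dialect See [quartile_summary()].
#' @param start,length When `window` is an [odr_stream()], the 0-based window
#'   start and window length.
#' @return An object of class `outlier_scan`: list with `is_outlier`
#'   (logical per row), `clean_idx`, `outlier_idx` (1-based row indices),
#'   `violating` (list of attribute-name vectors, one per outlier), and
#'   `summaries` (a `data.frame` of per-attribute fences).
#' @export
detect_outliers <- function(window, beta, rule = c("any", "fraction"), tau = 0.5,
                            fence_dialect = c("standard", "paper"),
                            start = NULL, length = NULL) {
  rule <- match.arg(rule)
  fence_dialect <- match.arg(fence_dialect)
  if (inherits(window, "odr_stream")) {
    if (is.null(start) || is.null(length)) {
      stop("give 'start' and 'length' to scan a window of a stream")
    }
    cls <- window$schema$class_attribute$name
    window <- window$data[seq.int(start + 1L, length.out = length),
                          setdiff(names(window$data), cls), drop = FALSE]
  }
  if (is.matrix(window)) window <- as.data.frame(window)
  n <- nrow(window)
  if (n < 4L) stop("a window needs at least 4 instances for quartiles")
  num_cols <- names(window)[vapply(window, is.numeric, TRUE)]
  if (!length(num_cols)) {
    stop("window has no numeric attributes; fence-based detection is inapplicable")
  }
  viol <- matrix(FALSE, n, length(num_cols), dimnames = list(NULL, num_cols))
  summaries <- vector("list", length(num_cols))
  usable <- logical(length(num_cols))
  for (j in seq_along(num_cols)) {
    v <- window[[num_cols[j]]]
    s <- quartile_summary(v, beta, attribute = num_cols[j], fence_dialect = fence_dialect)
    summaries[[j]] <- data.frame(attribute = s$attribute, q1 = s$q1, q3 = s$q3,
                                 iqr = s$iqr, beta = s$beta,
                                 lower_fence = s$lower_fence,
                                 upper_fence = s$upper_fence, n_used = s$n_used)
    usable[j] <- s$usable
    if (s$usable) viol[, j] <- !is.na(v) & (v < s$lower_fence | v > s$upper_fence)
  }
  flag <- if (rule == "any") {
    rowSums(viol) > 0L
  } else {
    if (!any(usable)) rep(FALSE, n) else
      rowMeans(viol[, usable, drop = FALSE]) > tau
  }
  out_idx <- which(flag)
  structure(list(
    is_outlier = flag,
    clean_idx = which(!flag),
    outlier_idx = out_idx,
    violating = lapply(out_idx, function(i) num_cols[viol[i, ]]),
    summaries = do.call(rbind, summaries)
  ), class = "outlier_scan")
}

#' Disposition of a detected outlier set
#'
#' The size of the outlier set `O` of a window decides its fate: fewer than
#' `lof_min` outliers are treated as noise and removed to the misclassified
#' database (excluded from training); `lof_min` or more form a candidate rare
#' group that is retained and queued for the re-learning check. The boundary
#' `|O| == lof_min` resolves to retained (ties favor keeping data).
#'
#' @param n_outliers Size of the detected outlier set.
#' @param lof_min Minimum group size (>= 1).
#' @return `"removed_to_db"`, `"retained_group"`, or `"none"` for an empty set.
#' @export
assign_disposition <- function(n_outliers, lof_min) {
  if (!is.numeric(lof_min) || length(lof_min) != 1L || lof_min < 1) {
    stop("lof_min must be a single count >= 1")
  }
  if (n_outliers == 0L) return("none")
  if (n_outliers < lof_min) "removed_to_db" else "retained_group"
}

#' Create a misclassified database
#'
#' Append-only store of removed outliers (positives for the ODR-R rule
#' model) plus a bounded reservoir sample of clean instances (negatives).
#' The reservoir uses standard reservoir sampling, so it is deterministic
#' under a fixed RNG seed.
#'
#' @param reservoir_cap Maximum number of clean instances retained as
#'   negatives.
#' @return An environment of class `misclassified_db` with fields `pos`
#'   (list of instance matrices), `n_pos`, `res` (reservoir matrix),
#'   `n_filled`, `n_seen`, and `log` (outlier record rows).
#' @export
new_misclassified_db <- function(reservoir_cap = 5000L) {
  db <- new.env(parent = emptyenv())
  db$pos <- list()
  db$pos_y <- list()
  db$n_pos <- 0L
  db$res <- NULL
  db$n_filled <- 0L
  db$n_seen <- 0L
  db$cap <- as.integer(reservoir_cap)
  db$log <- list()
  class(db) <- "misclassified_db"
  db
}

db_add_positives <- function(db, X, y) {
  if (!nrow(X)) return(invisible(db))
  db$pos[[length(db$pos) + 1L]] <- X
  db$pos_y[[length(db$pos_y) + 1L]] <- y
  db$n_pos <- db$n_pos + nrow(X)
  invisible(db)
}

db_positives <- function(db) {
  if (!db$n_pos) return(NULL)
  do.call(rbind, db$pos)
}

# Reservoir sampling of clean rows (negatives for ODR-R training).
db_add_negatives <- function(db, X) {
  if (!nrow(X)) return(invisible(db))
  if (is.null(db$res)) db$res <- matrix(NA_real_, db$cap, ncol(X))
  for (i in seq_len(nrow(X))) {
    db$n_seen <- db$n_seen + 1L
    if (db$n_filled < db$cap) {
      db$n_filled <- db$n_filled + 1L
      db$res[db$n_filled, ] <- X[i, ]
    } else {
      j <- sample.int(db$n_seen, 1L)
      if (j <= db$cap) db$res[j, ] <- X[i, ]
    }
  }
  invisible(db)
}

db_negatives <- function(db) {
  if (!db$n_filled) return(NULL)
  db$res[seq_len(db$n_filled), , drop = FALSE]
}

db_log_records <- function(db, window_start, stream_idx, violating, disposition) {
  db$log[[length(db$log) + 1L]] <- data.frame(
    window_start = window_start,
    stream_index = stream_idx,
    violating_attributes = vapply(violating, paste, "", collapse = ";"),
    disposition = disposition,
    stringsAsFactors = FALSE)
  invisible(db)
}

#' Outlier log of a misclassified database as a data.frame
#'
#' One row per outlier record: `window_start`, 0-based `stream_index`,
#' semicolon-joined `violating_attributes`, and the final `disposition`.
#'
#' @param db A [new_misclassified_db()] environment.
#' @return A `data.frame` (zero rows when nothing was logged).
#' @export
outlier_log <- function(db) {
  if (!length(db$log)) {
    return(data.frame(window_start = integer(0), stream_index = integer(0),
                      violating_attributes = character(0), disposition = character(0)))
  }
  do.call(rbind, db$log)
}

#' @export
print.misclassified_db <- function(x, ...) {
  cat("misclassified_db:", x$n_pos, "outlier records,",
      x$n_filled, "reservoir negatives (cap", x$cap, ")\n")
  invisible(x)
}
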
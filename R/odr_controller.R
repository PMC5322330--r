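#' Configuration of an ODR stream run
#'
#' All values are echoed verbatim into the run report. Defaults:
#' window length `omega = 1000` with non-overlapping step `m = omega`;
#' fence factor `beta = 3`; minimum rare-group size `lof_min = 10`;
#' accuracy threshold `acc_min = 0.75` (the controller runs active IQR
#' detection, ODR-A, while the running accuracy is below it, and the learned
#' rule model, ODR-R, once above); split confidence `delta = 1e-7` and grace
#' period 200 for the learner. The implied error ceiling is
#' `err_max = 1 - acc_min`.
#'
#' @param beta Fence tolerance factor (>= 0).
#' @param omega Window length (>= 4).
#' @param m Window step (default `omega`: partition semantics).
#' @param lof_min Minimum outlier-group size retained as a candidate rare
#'   group; smaller sets are removed to the misclassified database.
#' @param acc_min Running-accuracy threshold selecting ODR-A vs ODR-R.
#' @param delta,grace,n_thresholds,tie_mode,tie_tau,leaf_mode Learner
#'   parameters, see [hoeffding_tree()].
#' @param fence_dialect,rule,rule_tau Detector parameters, see
#'   [detect_outliers()].
#' @param group_policy What to do with a retained outlier group.
#'   `"relearn_first"` (default) runs the re-learning check immediately: a
#'   copy of the learner is trained on the group and adopted only if it does
#'   not worsen the error on the window's clean slice — noise never enters
#'   the live model. `"train_immediately"` trains the group into the live
#'   learner at once (the group "still belongs to the original dataset")
#'   and runs the re-learning check on the pending group only when the
#'   running error breaches `err_max`; required for an off-concept rare
#'   class to be learned at all, since such a group cannot improve the
#'   error on clean-only evaluation data.
#' @param odr Master switch; `FALSE` trains on every instance (the plain
#'   learner baseline).
#' @param use_odr_r Allow the learned rule model; `FALSE` keeps the
#'   controller in ODR-A permanently.
#' @param n_min_rules Minimum positives (and negatives) before the rule
#'   model is trained.
#' @param reservoir_cap Clean-instance reservoir size for rule-model
#'   negatives.
#' @param rule_delta,rule_grace Split confidence and grace period of the
#'   (small-sample) rule model.
#' @param seed Integer seed for every source of randomness in the run.
#' @return A validated list of class `odr_run_config`.
#' @export
run_config <- function(beta = 3, omega = 1000L, m = omega, lof_min = 10L,
                       acc_min = 0.75, delta = 1e-7, grace = 200L,
                       n_thresholds = 10L, tie_mode = c("adaptive", "fixed"),
                       tie_tau = 0.05, leaf_mode = c("majority", "nb_adaptive"),
                       fence_dialect = c("standard", "paper"),
                       rule = c("any", "fraction"), rule_tau = 0.5,
                       group_policy = c("relearn_first", "train_immediately"),
                       odr = TRUE, use_odr_r = TRUE, n_min_rules = 20L,
                       reservoir_cap = 5000L, rule_delta = 1e-3,
                       rule_grace = 20L, seed = 1L) {
  cfg <- list(beta = beta, omega = as.integer(omega), m = as.integer(m),
              lof_min = as.integer(lof_min), acc_min = acc_min, delta = delta,
              grace = as.integer(grace), n_thresholds = as.integer(n_thresholds),
              tie_mode = match.arg(tie_mode), tie_tau = tie_tau,
              leaf_mode = match.arg(leaf_mode),
              fence_dialect = match.arg(fence_dialect),
              rule = match.arg(rule), rule_tau = rule_tau,
              group_policy = match.arg(group_policy),
              odr = isTRUE(odr), use_odr_r = isTRUE(use_odr_r),
              n_min_rules = as.integer(n_min_rules),
              reservoir_cap = as.integer(reservoir_cap),
              rule_delta = rule_delta, rule_grace = as.integer(rule_grace),
              seed = as.integer(seed))
  if (!is.numeric(cfg$beta) || is.na(cfg$beta) || cfg$beta < 0) {
    stop("beta must be a non-negative number")
  }
  if (cfg$omega < 4L) stop("omega must be at least 4")
  if (cfg$m < 1L || cfg$m > cfg$omega) stop("m must satisfy 1 <= m <= omega")
  if (cfg$lof_min < 1L) stop("lof_min must be >= 1")
  if (cfg$acc_min < 0 || cfg$acc_min > 1) stop("acc_min must lie in [0, 1]")
  cfg$err_max <- 1 - cfg$acc_min
  structure(cfg, class = "odr_run_config")
}

#' Create the controller state for a run
#'
#' Holds the cumulative confusion matrix and running accuracy, the
#' misclassified database, the (optional) ODR-R rule model, the live
#' learner, timing accumulators and run accounting. The running accuracy
#' bootstraps at 0, so the first windows always execute ODR-A.
#'
#' @param schema The stream's [stream_schema()].
#' @param config An [run_config()].
#' @return An environment of class `odr_state`.
#' @export
new_controller_state <- function(schema, config) {
  st <- new.env(parent = emptyenv())
  st$cm <- new_confusion_matrix(schema_class_levels(schema))
  st$correct <- 0L
  st$total <- 0L
  st$db <- new_misclassified_db(config$reservoir_cap)
  st$odr_r <- NULL
  st$rule_trained_at <- 0L
  st$pending <- NULL
  st$model <- hoeffding_tree(schema, delta = config$delta, grace = config$grace,
                             n_thresholds = config$n_thresholds,
                             tie_mode = config$tie_mode, tie_tau = config$tie_tau,
                             leaf_mode = config$leaf_mode)
  st$t_odr_a <- 0
  st$t_odr_r <- 0
  st$n_trained_clean <- 0L
  st$n_removed_db <- 0L
  st$n_retained_kept <- 0L
  st$n_retained_noise <- 0L
  st$n_outliers_total <- 0L
  class(st) <- "odr_state"
  st
}

acc_current <- function(st) if (st$total) st$correct / st$total else 0

# One window of the ODR loop over the compiled stream. Returns the trace row.
process_window_impl <- function(st, comp, start0, len, config) {
  rows <- seq.int(start0 + 1L, length.out = len)
  Xw <- comp$X[rows, , drop = FALSE]
  yw <- comp$y[rows]
  num_cols <- which(comp$kinds == "numeric")

  acc0 <- acc_current(st)
  mode <- if (!config$odr) {
    "none"
  } else if (config$use_odr_r && acc0 >= config$acc_min) {
    if (is.null(st$odr_r)) "ODR_A" else "ODR_R"   # documented fallback
  } else {
    "ODR_A"
  }

  out_local <- integer(0)
  violating <- list()
  if (mode == "ODR_R") {
    t0 <- proc.time()[["elapsed"]]
    flags <- logical(len)
    for (i in seq_len(len)) {
      flags[i] <- ht_predict_idx(st$odr_r, Xw[i, ]) == 2L
    }
    st$t_odr_r <- st$t_odr_r + (proc.time()[["elapsed"]] - t0)
    if (sum(flags) > len / 2) {
      # degenerate rule model (flags the bulk of a window): drop it and fall
      # back to fence detection; it will be retrained from the database
      st$odr_r <- NULL
      mode <- "ODR_A"
    } else {
      out_local <- which(flags)
      violating <- rep(list("<rule>"), length(out_local))
    }
  }
  if (mode == "ODR_A") {
    t0 <- proc.time()[["elapsed"]]
    scan <- detect_outliers(as.data.frame(Xw[, num_cols, drop = FALSE]),
                            beta = config$beta, rule = config$rule,
                            tau = config$rule_tau,
                            fence_dialect = config$fence_dialect)
    st$t_odr_a <- st$t_odr_a + (proc.time()[["elapsed"]] - t0)
    out_local <- scan$outlier_idx
    violating <- scan$violating
  }

  n_out <- length(out_local)
  st$n_outliers_total <- st$n_outliers_total + n_out
  disp <- assign_disposition(n_out, config$lof_min)
  clean_local <- setdiff(seq_len(len), out_local)
  if (!length(clean_local)) {
    warning("window at ", start0, ": no clean instances; nothing trained")
  }

  # prequential test-then-train over clean instances, in stream order
  w_correct <- 0L
  for (i in clean_local) {
    pred <- ht_step(st$model, Xw[i, ], yw[i])
    st$cm[yw[i], pred] <- st$cm[yw[i], pred] + 1L
    if (pred == yw[i]) w_correct <- w_correct + 1L
  }
  st$correct <- st$correct + w_correct
  st$total <- st$total + length(clean_local)
  st$n_trained_clean <- st$n_trained_clean + length(clean_local)
  if (length(clean_local) && config$odr) {
    db_add_negatives(st$db, Xw[clean_local, , drop = FALSE])
  }

  add_pos <- function(X, y, src_mode) {
    if (src_mode == "ODR_R") {
      ok <- db_fence_valid(st$db, X, comp$kinds, config$beta, config$fence_dialect)
      X <- X[ok, , drop = FALSE]
      y <- y[ok]
    }
    db_add_positives(st$db, X, y)
  }

  if (disp == "removed_to_db") {
    add_pos(Xw[out_local, , drop = FALSE], yw[out_local], mode)
    db_log_records(st$db, start0, start0 + out_local - 1L, violating, "removed_to_db")
    st$n_removed_db <- st$n_removed_db + n_out
  } else if (disp == "retained_group") {
    Xg <- Xw[out_local, , drop = FALSE]
    yg <- yw[out_local]
    meta <- list(start = start0, idx = start0 + out_local - 1L,
                 violating = violating, mode = mode)
    if (config$group_policy == "relearn_first" && length(clean_local) >= 1L) {
      # check-before-commit: noise never reaches the live model
      res <- relearn_core(st$model, Xg, yg,
                          Xw[clean_local, , drop = FALSE], yw[clean_local])
      if (res$disposition == "relearned_kept") {
        st$model <- res$model
        st$n_retained_kept <- st$n_retained_kept + n_out
      } else {
        add_pos(Xg, yg, mode)
        st$n_retained_noise <- st$n_retained_noise + n_out
      }
      db_log_records(st$db, meta$start, meta$idx, meta$violating, res$disposition)
    } else {
      # the group still belongs to the dataset: train it now, adjudicate it
      # later if the running error breaches err_max
      for (i in seq_len(n_out)) ht_train(st$model, Xg[i, ], yg[i])
      st$n_retained_kept <- st$n_retained_kept + n_out
      st$pending <- list(X = Xg, y = yg, meta = meta)
    }
  }

  # error-breach re-learning check on a pending (already trained) group
  if (!is.null(st$pending) && st$total > 0L &&
      (1 - acc_current(st)) > config$err_max) {
    ev <- if (length(clean_local)) {
      list(X = Xw[clean_local, , drop = FALSE], y = yw[clean_local])
    } else NULL
    if (!is.null(ev)) {
      res <- relearn_core(st$model, st$pending$X, st$pending$y, ev$X, ev$y)
      if (res$disposition == "relearned_kept") {
        st$model <- res$model
      } else {
        add_pos(st$pending$X, st$pending$y, st$pending$meta$mode)
        st$n_retained_kept <- st$n_retained_kept - nrow(st$pending$X)
        st$n_retained_noise <- st$n_retained_noise + nrow(st$pending$X)
      }
      m <- st$pending$meta
      db_log_records(st$db, m$start, m$idx, m$violating, res$disposition)
      st$pending <- NULL
    }
  }

  # refresh the rule model with whatever the DB now holds
  if (config$odr && config$use_odr_r && st$db$n_pos > st$rule_trained_at) {
    rm <- train_odr_rules_impl(st$db, config, comp$kinds, comp$levels)
    if (!is.null(rm)) {
      st$odr_r <- rm
      st$rule_trained_at <- st$db$n_pos
    }
  }

  acc_cum <- acc_current(st)
  data.frame(start = start0, mode = mode, n_outliers = n_out,
             n_clean = length(clean_local), disposition = disp,
             accuracy_window = if (length(clean_local)) w_correct / length(clean_local) else NA_real_,
             accuracy = acc_cum,
             kappa = if (st$total) cohen_kappa(st$cm) else NA_real_,
             tree_size = tree_size(st$model),
             stringsAsFactors = FALSE)
}

#' Process one window through the ODR loop
#'
#' Selects the mode from the running accuracy (`acc_cur < acc_min` or no
#' trained rule model: ODR-A fence detection, otherwise ODR-R rule
#' filtering), splits the window into clean instances and outliers, applies
#' the size disposition, prequentially tests-then-trains the learner on the
#' clean instances, runs the re-learning check on a retained group, and
#' refreshes the rule model from the misclassified database. The live
#' learner is `state$model` and may be replaced when a re-learned group is
#' adopted.
#'
#' @param state A [new_controller_state()].
#' @param stream The [odr_stream()] the window indexes into.
#' @param start 0-based window start.
#' @param length Window length.
#' @param config An [run_config()].
#' @return The per-window trace row (`data.frame`), invisibly; `state` is
#'   updated in place.
#' @export
process_window <- function(state, stream, start, length, config = run_config()) {
  stopifnot(inherits(state, "odr_state"), inherits(stream, "odr_stream"))
  comp <- compile_stream(stream)
  invisible(process_window_impl(state, comp, as.integer(start),
                                as.integer(length), config))
}

# Keep the misclassified DB pure when positives come from the rule model
# rather than from fences: accept a row as a positive only if some numeric
# attribute lies outside fences computed from the cumulative clean
# reservoir. Fence-detected (ODR-A) positives skip this check.
db_fence_valid <- function(db, X, kinds, beta, fence_dialect) {
  N <- db_negatives(db)
  if (is.null(N) || nrow(N) < 4L) return(rep(TRUE, nrow(X)))
  keep <- rep(FALSE, nrow(X))
  for (j in which(kinds == "numeric")) {
    s <- quartile_summary(N[, j], beta, fence_dialect = fence_dialect)
    if (s$usable) {
      keep <- keep | (!is.na(X[, j]) & (X[, j] < s$lower_fence | X[, j] > s$upper_fence))
    }
  }
  keep
}

relearn_core <- function(model, Xg, yg, Xe, ye, err_cur = NULL) {
  if (is.null(err_cur)) err_cur <- eval_error(model, Xe, ye)
  copy <- clone_model(model)
  for (i in seq_len(nrow(Xg))) ht_train(copy, Xg[i, ], yg[i])
  err_re <- eval_error(copy, Xe, ye)
  if (err_re >= err_cur) {
    list(disposition = "relearned_noise", model = model,
         err_re = err_re, err_cur = err_cur)
  } else {
    list(disposition = "relearned_kept", model = copy,
         err_re = err_re, err_cur = err_cur)
  }
}

eval_error <- function(model, X, y) {
  wrong <- 0L
  for (i in seq_len(nrow(X))) {
    if (ht_predict_idx(model, X[i, ]) != y[i]) wrong <- wrong + 1L
  }
  wrong / nrow(X)
}

#' Re-learning check for a retained outlier group
#'
#' Decides whether a retained group is noise or a worthwhile rare case: a
#' deep copy of the learner is trained on the group and evaluated on a
#' recent clean slice. If the re-learned error is no better
#' (`err_re >= err_cur`, inclusive) the group is noise and the copy is
#' discarded; otherwise the group is kept and the copy becomes the live
#' learner.
#'
#' @param learner A [hoeffding_tree()].
#' @param group A `data.frame` of group instances including the class
#'   column.
#' @param recent_clean A `data.frame` of recent clean instances (held out
#'   from the copy's training) including the class column.
#' @param err_cur Optional current error on `recent_clean`; computed from
#'   `learner` when omitted.
#' @return List with `disposition` (`"relearned_noise"` or
#'   `"relearned_kept"`), `model` (the surviving learner), `err_re`,
#'   `err_cur`.
#' @export
relearn_outliers <- function(learner, group, recent_clean, err_cur = NULL) {
  stopifnot(inherits(learner, "hoeffding_tree"),
            nrow(group) > 0, nrow(recent_clean) > 0)
  g <- frame_to_coded(learner, group)
  e <- frame_to_coded(learner, recent_clean)
  relearn_core(learner, g$X, g$y, e$X, e$y, err_cur = err_cur)
}

frame_to_coded <- function(model, df) {
  cls <- model$schema$class_attribute$name
  n <- nrow(df)
  X <- matrix(NA_real_, n, model$p)
  y <- integer(n)
  for (i in seq_len(n)) {
    X[i, ] <- code_instance(model, df[i, setdiff(names(df), cls), drop = FALSE])
    y[i] <- code_label(model, df[[cls]][i])
  }
  list(X = X, y = y)
}

train_odr_rules_impl <- function(db, config, kinds, levels) {
  if (db$n_pos < config$n_min_rules || db$n_filled < config$n_min_rules) {
    return(NULL)
  }
  P <- db_positives(db)
  N <- db_negatives(db)
  n_use <- min(nrow(P), nrow(N))
  Pu <- if (nrow(P) > n_use) P[sample.int(nrow(P), n_use), , drop = FALSE] else P
  Nu <- if (nrow(N) > n_use) N[sample.int(nrow(N), n_use), , drop = FALSE] else N
  X2 <- rbind(Pu, Nu)
  y2 <- c(rep(2L, nrow(Pu)), rep(1L, nrow(Nu)))
  # the DB is small relative to a stream, so the incremental tree is given
  # several epochs over it; fixed conservative tie-breaking keeps a
  # small-sample model from splitting on noise
  rm <- new_ht(kinds, levels, c("normal", "outlier"),
               delta = config$rule_delta, grace = config$rule_grace,
               n_thresholds = config$n_thresholds, tie_mode = "fixed",
               tie_tau = 0.05, leaf_mode = "majority")
  epochs <- max(1L, ceiling(12000 / nrow(X2)))
  np <- nrow(Pu)   # == nrow(Nu): both were balanced to n_use
  for (e in seq_len(epochs)) {
    # class-balanced interleave with one shared permutation: positives and
    # negatives alternate pairwise, so the leaf statistics never carry a
    # transient class imbalance that would masquerade as gain on
    # uninformative attributes (in particular, identically distributed
    # classes yield exactly zero gain and no splits)
    op <- sample.int(np)
    ord <- as.vector(rbind(op, np + op))
    for (i in ord) ht_train(rm, X2[i, ], y2[i])
  }
  rm
}

#' Train the ODR-R rule model from the misclassified database
#'
#' A binary incremental tree over the predictive attributes, positives =
#' database records (label `"outlier"`), negatives = the clean-instance
#' reservoir (label `"normal"`), class-balanced and trained in seeded
#' shuffled order. Returns `NULL` when the database holds fewer than
#' `n_min_rules` positives or negatives (the controller then stays in
#' ODR-A).
#'
#' @param db A [new_misclassified_db()].
#' @param schema The stream's [stream_schema()].
#' @param config An [run_config()].
#' @return A binary [hoeffding_tree()] with class levels
#'   `c("normal", "outlier")`, or `NULL`.
#' @export
train_odr_rules <- function(db, schema, config = run_config()) {
  train_odr_rules_impl(db, config, schema_attr_kinds(schema),
                       schema_attr_levels(schema))
}

#' Filter a window with the ODR-R rule model
#'
#' @param model A binary rule model from [train_odr_rules()].
#' @param window A `data.frame` of window instances (predictive attributes;
#'   a class column, if present, is ignored).
#' @return List with `clean_idx`, `outlier_idx` (1-based rows) and
#'   `violating` (the literal `"<rule>"` marker per outlier).
#' @export
apply_odr_rules <- function(model, window) {
  stopifnot(inherits(model, "hoeffding_tree"))
  keep <- setdiff(names(window), "class")
  flags <- logical(nrow(window))
  for (i in seq_len(nrow(window))) {
    x <- code_instance(model, window[i, keep, drop = FALSE])
    flags[i] <- ht_predict_idx(model, x) == 2L
  }
  if (all(flags)) warning("rule model flagged every instance in the window")
  list(clean_idx = which(!flags), outlier_idx = which(flags),
       violating = rep(list("<rule>"), sum(flags)))
}

#' Run the full ODR loop over a stream
#'
#' Slices the stream into sliding windows, processes each through
#' [process_window()] semantics, and returns a prequential report with the
#' per-window trace, finals (accuracy, kappa and band, tree size, run
#' accounting), the cumulative confusion matrix, the outlier log, and
#' wall-clock timing. Fully deterministic given `config$seed`, except for
#' the `timing` section.
#'
#' @param stream An [odr_stream()].
#' @param config An [run_config()].
#' @return A `prequential_report` (see [summarize_run()]), with an
#'   `outliers` element holding the outlier log.
#' @export
run_stream <- function(stream, config = run_config()) {
  stopifnot(inherits(stream, "odr_stream"), inherits(config, "odr_run_config"))
  t_start <- proc.time()[["elapsed"]]
  set.seed(config$seed)
  comp <- compile_stream(stream)
  wins <- sliding_windows(nrow(comp$X), config$omega, config$m)
  if (!nrow(wins)) stop("stream too short: no windows to process")
  st <- new_controller_state(stream$schema, config)
  trace <- vector("list", nrow(wins))
  for (w in seq_len(nrow(wins))) {
    trace[[w]] <- tryCatch(
      process_window_impl(st, comp, wins$start[w], wins$length[w], config),
      error = function(e) {
        stop("window ", w, " (start ", wins$start[w], "): ",
             conditionMessage(e), call. = FALSE)
      })
  }
  trace <- do.call(rbind, trace)
  if (!is.null(st$pending)) {   # trained group never adjudicated: stays retained
    m <- st$pending$meta
    db_log_records(st$db, m$start, m$idx, m$violating, "retained_group")
    st$pending <- NULL
  }
  counts <- list(n_instances = nrow(comp$X),
                 n_trained_clean = st$n_trained_clean,
                 n_outliers_total = st$n_outliers_total,
                 n_removed_db = st$n_removed_db,
                 n_retained_kept = st$n_retained_kept,
                 n_retained_noise = st$n_retained_noise)
  timing <- list(t_odr_a = st$t_odr_a, t_odr_r = st$t_odr_r,
                 t_total = proc.time()[["elapsed"]] - t_start)
  report <- summarize_run(trace, st$cm, st$model, config = unclass(config),
                          counts = counts, timing = timing)
  report$outliers <- outlier_log(st$db)
  report$model <- st$model
  report
}
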
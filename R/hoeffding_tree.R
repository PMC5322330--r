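#' Hoeffding bound
#'
#' `epsilon = sqrt(R^2 * ln(1/delta) / (2 n))`: with confidence `1 - delta`,
#' the empirical mean of `n` independent observations with range `R` is
#' within `epsilon` of the true mean. Used to certify that the best split
#' candidate at a leaf truly beats the runner-up from partial data.
#'
#' @param value_range Range `R >= 0` of the averaged quantity (1 for
#'   normalized information gain).
#' @param delta Split confidence, in `(0, 1]`.
#' @param n Number of observations (>= 1).
#' @return The bound `epsilon`.
#' @export
#' @examples
#' hoeffding_bound(1, 0.05, 1000)
hoeffding_bound <- function(value_range, delta, n) {
  if (!is.numeric(value_range) || any(value_range < 0)) stop("value_range must be >= 0")
  if (!is.numeric(delta) || any(delta <= 0) || any(delta > 1)) {
    stop("delta must lie in (0, 1]")
  }
  if (!is.numeric(n) || any(n < 1)) stop("n must be a count >= 1")
  sqrt(value_range^2 * log(1 / delta) / (2 * n))
}

# Entropy in bits of a count vector; 0 for an empty distribution.
entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n <= 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Row-wise entropy of a branches x classes count matrix.
row_entropy <- function(M) {
  n <- rowSums(M)
  P <- M / ifelse(n > 0, n, 1)
  H <- -rowSums(ifelse(P > 0, P * log2(P), 0))
  H[n <= 0] <- 0
  H
}

#' Information gain of a candidate split
#'
#' `gain = H(parent) - sum_b (n_b / n) H(branch_b)` with entropy in bits,
#' where the parent distribution is the column sum of the branch table.
#' Clipped to be non-negative.
#'
#' @param branch_counts Branches x classes matrix of non-negative counts
#'   (rows = split branches).
#' @return The gain in bits (>= 0); 0 for an empty table.
#' @export
#' @examples
#' information_gain(rbind(c(50, 0), c(0, 50)))  # 1 bit
information_gain <- function(branch_counts) {
  M <- as.matrix(branch_counts)
  if (any(M < 0)) stop("branch counts must be non-negative")
  n <- sum(M)
  if (n == 0) return(0)
  g <- entropy_bits(colSums(M)) - sum(rowSums(M) / n * row_entropy(M))
  max(g, 0)
}

#' Candidate thresholds for a numeric split
#'
#' `k` equally spaced thresholds strictly between the observed minimum and
#' maximum of the attribute; empty when the range is degenerate.
#'
#' @param min_value,max_value Observed attribute range.
#' @param k Number of thresholds.
#' @return Numeric vector of length `k` (possibly empty).
#' @export
#' @examples
#' candidate_thresholds(0, 10, 9)  # 1..9
candidate_thresholds <- function(min_value, max_value, k = 10L) {
  if (!is.finite(min_value) || !is.finite(max_value) || max_value <= min_value) {
    return(numeric(0))
  }
  min_value + seq_len(k) * (max_value - min_value) / (k + 1)
}

#' Create an incremental Hoeffding tree
#'
#' A decision tree grown one instance at a time. Each leaf accumulates
#' sufficient statistics (class counts, per-class Gaussian summaries for
#' numeric attributes, value-class counts for nominal ones); every `grace`
#' instances a split attempt compares the best and second-best candidate
#' gains against the Hoeffding bound. Near-ties are resolved adaptively:
#' when the current bound falls below the running mean of all bounds seen at
#' split attempts, the best candidate is split anyway (the learner has
#' waited "long enough" relative to its own history); `tie_mode = "fixed"`
#' uses the classical constant threshold instead.
#'
#' Gains are measured in bits and normalized by `log2(n_classes)` so that
#' the bound's unit-range assumption (`R = 1`) holds.
#'
#' @param schema A [stream_schema()].
#' @param delta Split confidence (default `1e-7`).
#' @param grace Instances a leaf accumulates between split attempts
#'   (default 200).
#' @param n_thresholds Candidate thresholds per numeric attribute
#'   (default 10).
#' @param tie_mode `"adaptive"` (running mean of bounds) or `"fixed"`.
#' @param tie_tau Tie threshold for `tie_mode = "fixed"`.
#' @param leaf_mode `"majority"` or `"nb_adaptive"` (per-leaf choice of
#'   majority vote vs naive Bayes, whichever has been more accurate at that
#'   leaf so far).
#' @return An environment of class `hoeffding_tree`.
#' @export
hoeffding_tree <- function(schema, delta = 1e-7, grace = 200L, n_thresholds = 10L,
                           tie_mode = c("adaptive", "fixed"), tie_tau = 0.05,
                           leaf_mode = c("majority", "nb_adaptive")) {
  stopifnot(inherits(schema, "stream_schema"))
  kinds <- schema_attr_kinds(schema)
  levels <- schema_attr_levels(schema)
  new_ht(kinds, levels, schema_class_levels(schema),
         delta = delta, grace = grace, n_thresholds = n_thresholds,
         tie_mode = match.arg(tie_mode), tie_tau = tie_tau,
         leaf_mode = match.arg(leaf_mode), schema = schema)
}

# Internal constructor over compiled schema parts (also used for the binary
# ODR-R rule model, which has no user-facing schema object).
new_ht <- function(kinds, levels, class_levels, delta, grace, n_thresholds,
                   tie_mode, tie_tau, leaf_mode, schema = NULL) {
  if (!is.numeric(delta) || delta <= 0 || delta > 1) stop("delta must lie in (0, 1]")
  if (grace < 1) stop("grace must be >= 1")
  model <- new.env(parent = emptyenv())
  model$schema <- schema
  model$kinds <- kinds
  model$levels <- levels
  model$class_levels <- class_levels
  model$k <- length(class_levels)
  model$p <- length(kinds)
  model$num_idx <- which(kinds == "numeric")
  model$nom_idx <- which(kinds == "nominal")
  model$delta <- delta
  model$grace <- as.integer(grace)
  model$n_thresholds <- as.integer(n_thresholds)
  model$tie_mode <- tie_mode
  model$tie_tau <- tie_tau
  model$leaf_mode <- leaf_mode
  model$gain_norm <- max(log2(model$k), 1e-12)
  model$bound_sum <- 0
  model$bound_n <- 0L
  model$n_splits <- 0L
  model$n_nodes <- 1L
  model$n_leaves <- 1L
  model$n_seen <- 0L
  model$root <- new_leaf(model)
  class(model) <- "hoeffding_tree"
  model
}

new_leaf <- function(model, init_dist = NULL) {
  leaf <- new.env(parent = emptyenv())
  leaf$is_leaf <- TRUE
  p <- model$p; k <- model$k
  leaf$cc <- numeric(k)
  leaf$n_total <- 0L
  leaf$n_since <- 0L
  leaf$ns <- matrix(0, p, k)
  leaf$s1 <- matrix(0, p, k)
  leaf$s2 <- matrix(0, p, k)
  leaf$mn <- rep(Inf, p)
  leaf$mx <- rep(-Inf, p)
  leaf$nom <- if (length(model$nom_idx)) {
    stats::setNames(lapply(model$nom_idx, function(j) {
      matrix(0, length(model$levels[[j]]), k)
    }), model$nom_idx)
  } else NULL
  leaf$init_dist <- init_dist
  leaf$mc_ok <- 0L
  leaf$nb_ok <- 0L
  leaf
}

# Route an instance (coded numeric vector) to its leaf; when learning, child
# traffic counts are updated so missing split values can follow the majority
# branch deterministically.
route_to_leaf <- function(model, x, learn = FALSE) {
  node <- model$root
  while (!node$is_leaf) {
    v <- x[node$attr]
    ci <- if (is.na(v)) {
      which.max(node$child_n)
    } else if (node$split_type == "numeric") {
      if (v <= node$threshold) 1L else 2L
    } else {
      iv <- as.integer(v)
      if (iv >= 1L && iv <= length(node$children)) iv else which.max(node$child_n)
    }
    if (learn) node$child_n[ci] <- node$child_n[ci] + 1L
    node <- node$children[[ci]]
  }
  node
}

update_leaf <- function(model, leaf, x, y) {
  leaf$cc[y] <- leaf$cc[y] + 1
  leaf$n_total <- leaf$n_total + 1L
  leaf$n_since <- leaf$n_since + 1L
  ni <- model$num_idx
  if (length(ni)) {
    xi <- x[ni]
    ok <- !is.na(xi)
    if (any(ok)) {
      idx <- ni[ok]; xv <- xi[ok]
      leaf$ns[idx, y] <- leaf$ns[idx, y] + 1
      leaf$s1[idx, y] <- leaf$s1[idx, y] + xv
      leaf$s2[idx, y] <- leaf$s2[idx, y] + xv * xv
      leaf$mn[idx] <- pmin(leaf$mn[idx], xv)
      leaf$mx[idx] <- pmax(leaf$mx[idx], xv)
    }
  }
  for (j in model$nom_idx) {
    v <- x[j]
    if (!is.na(v)) {
      key <- as.character(j)
      leaf$nom[[key]][as.integer(v), y] <- leaf$nom[[key]][as.integer(v), y] + 1
    }
  }
  invisible(leaf)
}

# Best split candidate per attribute: numeric candidates derive branch class
# distributions from the per-class Gaussian summaries (mass on each side of
# the threshold); nominal candidates are multiway on the observed value
# table. Gains are normalized to [0, 1] by log2(k).
leaf_candidates <- function(model, leaf) {
  res <- list()
  norm <- model$gain_norm
  k <- model$k
  for (j in model$num_idx) {
    nj <- leaf$ns[j, ]
    tot <- sum(nj)
    if (tot < 2 || !is.finite(leaf$mn[j]) || leaf$mx[j] <= leaf$mn[j]) next
    thr <- candidate_thresholds(leaf$mn[j], leaf$mx[j], model$n_thresholds)
    if (!length(thr)) next
    mu <- ifelse(nj > 0, leaf$s1[j, ] / nj, 0)
    va <- ifelse(nj > 0, pmax(leaf$s2[j, ] / nj - mu^2, 0), 0)
    sdv <- sqrt(va)
    L <- vapply(seq_len(k), function(c) {
      if (nj[c] == 0) rep(0, length(thr))
      else if (sdv[c] > 0) nj[c] * stats::pnorm(thr, mu[c], sdv[c])
      else nj[c] * as.numeric(mu[c] <= thr)
    }, numeric(length(thr)))
    L <- matrix(L, nrow = length(thr), ncol = k)
    R <- matrix(nj, nrow = length(thr), ncol = k, byrow = TRUE) - L
    hp <- entropy_bits(nj)
    gains <- hp - (rowSums(L) / tot) * row_entropy(L) - (rowSums(R) / tot) * row_entropy(R)
    gains <- pmax(gains, 0) / norm
    gains[gains < 1e-12] <- 0    # rounding dust must not feed the tie rule
    b <- which.max(gains)
    res[[length(res) + 1L]] <- list(attr = j, type = "numeric", threshold = thr[b],
                                    gain = gains[b],
                                    branch_dist = rbind(L[b, ], R[b, ]))
  }
  for (j in model$nom_idx) {
    M <- leaf$nom[[as.character(j)]]
    if (sum(rowSums(M) > 0) < 2) next
    res[[length(res) + 1L]] <- list(attr = j, type = "nominal", threshold = NA_real_,
                                    gain = information_gain(M) / norm,
                                    branch_dist = M)
  }
  res
}

#' Attempt to split a leaf
#'
#' Computes candidate gains, the Hoeffding bound
#' `epsilon = hoeffding_bound(1, delta, n_total)`, and splits on the best
#' candidate when `G1 - G2 > epsilon`, or — the adaptive tie rule — when the
#' difference is within the bound but `epsilon` has dropped below the running
#' mean of all bounds computed at split attempts (model-wide). The running
#' mean is updated with the current `epsilon` on every attempt regardless of
#' the outcome, and the leaf's attempt counter is reset. Ties among equal
#' best gains break toward the lowest attribute index; a tie split requires a
#' strictly positive best gain. Called automatically by [learn_one()]; exposed
#' for inspection and testing.
#'
#' @param model A [hoeffding_tree()].
#' @param leaf A leaf node of `model` (default: the root, for fresh trees).
#' @return `TRUE` if a split was realized, else `FALSE`, invisibly.
#' @export
attempt_split <- function(model, leaf = model$root) {
  leaf$n_since <- 0L
  if (sum(leaf$cc > 0) < 2) return(invisible(FALSE))
  cands <- leaf_candidates(model, leaf)
  if (!length(cands)) return(invisible(FALSE))
  gains <- vapply(cands, `[[`, 0, "gain")
  ord <- order(-gains, vapply(cands, `[[`, 0L, "attr"))
  g1 <- gains[ord[1]]
  g2 <- if (length(gains) >= 2) gains[ord[2]] else 0   # the "no-split" null
  eps <- hoeffding_bound(1, model$delta, leaf$n_total)
  model$bound_sum <- model$bound_sum + eps
  model$bound_n <- model$bound_n + 1L
  bound_mean <- model$bound_sum / model$bound_n
  tie_ok <- if (model$tie_mode == "adaptive") eps < bound_mean else eps < model$tie_tau
  do_split <- (g1 - g2 > eps) || (g1 > 0 && g1 - g2 <= eps && tie_ok)
  if (!do_split) return(invisible(FALSE))
  realize_split(model, leaf, cands[[ord[1]]])
  invisible(TRUE)
}

realize_split <- function(model, leaf, cand) {
  nb <- nrow(cand$branch_dist)
  children <- lapply(seq_len(nb), function(b) {
    d <- cand$branch_dist[b, ]
    new_leaf(model, init_dist = if (sum(d) > 0) d else NULL)
  })
  leaf$is_leaf <- FALSE
  leaf$attr <- cand$attr
  leaf$split_type <- cand$type
  leaf$threshold <- cand$threshold
  leaf$children <- children
  leaf$child_n <- numeric(nb)
  # free leaf statistics
  leaf$cc <- leaf$ns <- leaf$s1 <- leaf$s2 <- leaf$mn <- leaf$mx <- leaf$nom <- NULL
  model$n_splits <- model$n_splits + 1L
  model$n_nodes <- model$n_nodes + nb
  model$n_leaves <- model$n_leaves + nb - 1L
  invisible(leaf)
}

# Class scores at a leaf: observed counts, else the branch distribution the
# split handed down, else uniform.
leaf_scores <- function(model, leaf) {
  cc <- leaf$cc
  if (sum(cc) == 0) {
    if (!is.null(leaf$init_dist) && sum(leaf$init_dist) > 0) cc <- leaf$init_dist
    else return(rep(1 / model$k, model$k))
  }
  cc / sum(cc)
}

# Naive-Bayes class scores at a leaf (log-space; Gaussian numeric
# likelihoods, Laplace-smoothed nominal counts).
leaf_nb_scores <- function(model, leaf, x) {
  k <- model$k
  n <- sum(leaf$cc)
  if (n == 0) return(leaf_scores(model, leaf))
  ls <- log((leaf$cc + 1) / (n + k))
  for (j in model$num_idx) {
    v <- x[j]
    if (is.na(v)) next
    nj <- leaf$ns[j, ]
    mu <- ifelse(nj > 0, leaf$s1[j, ] / nj, 0)
    va <- ifelse(nj > 0, pmax(leaf$s2[j, ] / nj - mu^2, 0), 0)
    sdv <- sqrt(va) + 1e-6
    ll <- ifelse(nj > 0, stats::dnorm(v, mu, sdv, log = TRUE), 0)
    ls <- ls + ll
  }
  for (j in model$nom_idx) {
    v <- x[j]
    if (is.na(v)) next
    M <- leaf$nom[[as.character(j)]]
    ls <- ls + log((M[as.integer(v), ] + 1) / (colSums(M) + nrow(M)))
  }
  s <- exp(ls - max(ls))
  s / sum(s)
}

leaf_predict_idx <- function(model, leaf, x) {
  if (model$leaf_mode == "nb_adaptive" && leaf$n_total > 0L) {
    mc <- which.max(leaf_scores(model, leaf))
    nb <- which.max(leaf_nb_scores(model, leaf, x))
    if (leaf$nb_ok > leaf$mc_ok) nb else mc
  } else {
    which.max(leaf_scores(model, leaf))
  }
}

# Prequential step: route once, predict from the leaf's pre-update state,
# then train on the instance (and attempt a split when the grace period is
# up). Returns the predicted class index.
ht_step <- function(model, x, y) {
  leaf <- route_to_leaf(model, x, learn = TRUE)
  pred <- leaf_predict_idx(model, leaf, x)
  if (model$leaf_mode == "nb_adaptive" && leaf$n_total > 0L) {
    if (which.max(leaf_scores(model, leaf)) == y) leaf$mc_ok <- leaf$mc_ok + 1L
    if (which.max(leaf_nb_scores(model, leaf, x)) == y) leaf$nb_ok <- leaf$nb_ok + 1L
  }
  update_leaf(model, leaf, x, y)
  model$n_seen <- model$n_seen + 1L
  if (leaf$n_since >= model$grace) attempt_split(model, leaf)
  pred
}

ht_train <- function(model, x, y) {
  leaf <- route_to_leaf(model, x, learn = TRUE)
  update_leaf(model, leaf, x, y)
  model$n_seen <- model$n_seen + 1L
  if (leaf$n_since >= model$grace) attempt_split(model, leaf)
  invisible(model)
}

ht_predict_idx <- function(model, x) {
  leaf <- route_to_leaf(model, x, learn = FALSE)
  leaf_predict_idx(model, leaf, x)
}

# Coerce a user-facing instance (data.frame row, named list/vector) to the
# coded numeric vector the internal functions consume.
code_instance <- function(model, instance) {
  if (is.data.frame(instance)) instance <- as.list(instance[1, , drop = FALSE])
  nm <- if (!is.null(model$schema)) schema_attr_names(model$schema) else names(instance)
  x <- numeric(model$p)
  for (j in seq_len(model$p)) {
    v <- if (!is.null(names(instance))) instance[[nm[j]]] else instance[[j]]
    x[j] <- if (is.null(v) || is.na(v)) {
      NA_real_
    } else if (model$kinds[j] == "numeric") {
      as.numeric(v)
    } else {
      iv <- match(as.character(v), model$levels[[j]])
      if (is.na(iv)) stop("value '", v, "' outside declared domain of attribute ", nm[j])
      as.numeric(iv)
    }
  }
  x
}

code_label <- function(model, label) {
  iy <- match(as.character(label), model$class_levels)
  if (is.na(iy)) stop("label '", label, "' not among the schema's class levels")
  iy
}

#' Train the tree on one labeled instance
#'
#' The instance is routed root-to-leaf by the split tests (a missing split
#' attribute follows the majority branch), the leaf's sufficient statistics
#' are updated, and a split is attempted once the leaf has accumulated
#' `grace` instances since the last attempt.
#'
#' @param model A [hoeffding_tree()].
#' @param instance A one-row `data.frame` or named list/vector of attribute
#'   values conforming to the schema.
#' @param label The class label.
#' @return The model, invisibly (updated in place).
#' @export
learn_one <- function(model, instance, label) {
  stopifnot(inherits(model, "hoeffding_tree"))
  ht_train(model, code_instance(model, instance), code_label(model, label))
}

#' Predict the class of one instance
#'
#' @param model A [hoeffding_tree()].
#' @param instance As in [learn_one()].
#' @return A list with `label` (ties break toward the first class in schema
#'   order; an untrained model returns the first class) and `scores` (named
#'   class proportions).
#' @export
predict_one <- function(model, instance) {
  stopifnot(inherits(model, "hoeffding_tree"))
  x <- code_instance(model, instance)
  leaf <- route_to_leaf(model, x, learn = FALSE)
  s <- if (model$leaf_mode == "nb_adaptive" && leaf$n_total > 0L &&
           leaf$nb_ok > leaf$mc_ok) {
    leaf_nb_scores(model, leaf, x)
  } else {
    leaf_scores(model, leaf)
  }
  names(s) <- model$class_levels
  list(label = model$class_levels[which.max(s)], scores = s)
}

#' @export
#' @method predict hoeffding_tree
predict.hoeffding_tree <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    out[i] <- model_levels_pred(object, code_instance(object, newdata[i, , drop = FALSE]))
  }
  factor(out, levels = object$class_levels)
}

model_levels_pred <- function(model, x) model$class_levels[ht_predict_idx(model, x)]

#' Number of nodes in the tree
#'
#' Internal nodes plus leaves, by full traversal (also cross-checked against
#' the model's incremental node counter).
#'
#' @param model A [hoeffding_tree()].
#' @return Integer node count.
#' @export
tree_size <- function(model) {
  count_nodes <- function(node) {
    if (node$is_leaf) return(1L)
    1L + sum(vapply(node$children, count_nodes, 0L))
  }
  count_nodes(model$root)
}

# Deep copy of the model (environments are reference semantics).
clone_model <- function(model) {
  clone_env <- function(e) {
    out <- new.env(parent = emptyenv())
    for (nm in ls(e, all.names = TRUE)) {
      v <- get(nm, envir = e, inherits = FALSE)
      assign(nm, v, envir = out)
    }
    if (!out$is_leaf) out$children <- lapply(out$children, clone_env)
    out
  }
  out <- new.env(parent = emptyenv())
  for (nm in ls(model, all.names = TRUE)) {
    assign(nm, get(nm, envir = model, inherits = FALSE), envir = out)
  }
  out$root <- clone_env(model$root)
  class(out) <- class(model)
  out
}

#' Serialize a tree to a plain list (JSON-ready)
#'
#' Nodes carry their split test or leaf class counts; suitable for
#' [jsonlite::toJSON()] and for structural comparison in tests.
#'
#' @param model A [hoeffding_tree()].
#' @return A nested list.
#' @export
tree_to_list <- function(model) {
  node_to_list <- function(node) {
    if (node$is_leaf) {
      list(type = "leaf", n = node$n_total,
           class_counts = as.numeric(node$cc))
    } else {
      list(type = "split",
           attribute = node$attr,
           test = if (node$split_type == "numeric") {
             list(kind = "numeric", threshold = node$threshold)
           } else {
             list(kind = "nominal")
           },
           children = lapply(node$children, node_to_list))
    }
  }
  list(n_nodes = tree_size(model), delta = model$delta, grace = model$grace,
       bound_history_mean = if (model$bound_n) model$bound_sum / model$bound_n else NA,
       root = node_to_list(model$root))
}

#' @export
print.hoeffding_tree <- function(x, ...) {
  cat("hoeffding_tree:", tree_size(x), "nodes (", x$n_leaves, "leaves ),",
      x$n_seen, "instances seen; delta =", format(x$delta),
      ", grace =", x$grace, ", tie =", x$tie_mode, "\n")
  invisible(x)
}

#' Cost balance of a run (monitoring score)
#'
#' Weighted sum of min-max-normalized `(1 - accuracy)`, tree size and
#' elapsed time: a single scalar in `[0, 1]` (lower is better) balancing the
#' three objectives an incremental learner trades off. Purely a reporting
#' utility — it never alters learning. Size and time are normalized against
#' caller-supplied reference ranges (e.g. the min/max across a parameter
#' sweep); values outside the range are clipped.
#'
#' @param accuracy Fraction in `[0, 1]`.
#' @param size Tree node count.
#' @param elapsed Seconds.
#' @param weights Three non-negative weights summing to 1.
#' @param size_range,time_range Length-2 normalization ranges.
#' @return The score in `[0, 1]`.
#' @export
cost_balance <- function(accuracy, size, elapsed, weights = rep(1, 3) / 3,
                         size_range = c(0, 1), time_range = c(0, 1)) {
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be three non-negative numbers summing to 1")
  }
  norm01 <- function(v, r) {
    if (r[2] <= r[1]) return(0)
    min(max((v - r[1]) / (r[2] - r[1]), 0), 1)
  }
  comp <- c(min(max(1 - accuracy, 0), 1),
            norm01(size, size_range),
            norm01(elapsed, time_range))
  sum(weights * comp)
}
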
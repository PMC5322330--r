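#' Configuration for the synthetic stream generator
#'
#' Defaults are the package's reference study conditions: a depth-3 random
#' concept over 5 uniform numeric attributes and 2 classes, 20,000
#' instances, 5% point noise placed 10 clean-IQR beyond the clean quartiles
#' with flipped labels, and no rare group. Uniform(0, 1) base attributes
#' make the clean quartiles analytically known (Q1 = 0.25, Q3 = 0.75,
#' IQR = 0.5), so `outlier_magnitude` calibrates corruption exactly.
#'
#' @param n_attributes Number of numeric predictive attributes.
#' @param n_classes Number of concept classes (>= 2).
#' @param concept_depth Depth of the random concept tree (>= 1).
#' @param n_instances Stream length (>= 1).
#' @param noise_rate Fraction of instances corrupted as point outliers.
#' @param outlier_magnitude Multiple of the clean IQR by which a corrupted
#'   value is placed beyond Q3 (or below Q1; sign random).
#' @param label_flip_on_noise Flip the label of corrupted instances to a
#'   random other class?
#' @param rare_group_rate Fraction of instances drawn from a tight
#'   off-range cluster with its own dedicated class (`"rare"`).
#' @param seed Integer seed fixing the whole stream.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_attributes = 5L, n_classes = 2L, concept_depth = 3L,
                         n_instances = 20000L, noise_rate = 0.05,
                         outlier_magnitude = 10, label_flip_on_noise = TRUE,
                         rare_group_rate = 0, seed = 1L) {
  cfg <- list(n_attributes = as.integer(n_attributes),
              n_classes = as.integer(n_classes),
              concept_depth = as.integer(concept_depth),
              n_instances = as.integer(n_instances),
              noise_rate = noise_rate,
              outlier_magnitude = outlier_magnitude,
              label_flip_on_noise = isTRUE(label_flip_on_noise),
              rare_group_rate = rare_group_rate,
              seed = as.integer(seed))
  if (cfg$n_attributes < 1L) stop("need at least one attribute")
  if (cfg$n_classes < 2L) stop("need at least two classes")
  if (cfg$concept_depth < 1L) stop("concept depth must be >= 1")
  if (cfg$n_instances < 1L) stop("n_instances must be >= 1")
  if (cfg$noise_rate < 0 || cfg$noise_rate > 1 ||
      cfg$rare_group_rate < 0 || cfg$rare_group_rate > 1 ||
      cfg$noise_rate + cfg$rare_group_rate > 0.5) {
    stop("rates must lie in [0, 1] with noise_rate + rare_group_rate <= 0.5")
  }
  if (cfg$outlier_magnitude <= 0) stop("outlier_magnitude must be positive")
  structure(cfg, class = "synth_config")
}

#' Generate a random decision-tree concept
#'
#' A full binary tree of the given depth over uniform(0, 1) numeric
#' attributes: each internal node tests a random attribute against a random
#' threshold in (0.3, 0.7); leaf classes are assigned so that every class
#' appears when the tree has at least `n_classes` leaves. Deterministic
#' given the seed.
#'
#' @param n_attributes,n_classes,depth As in [synth_config()].
#' @param seed Integer seed.
#' @return An object of class `stream_concept`.
#' @export
make_concept <- function(n_attributes, n_classes, depth, seed) {
  if (depth < 1) stop("concept depth must be >= 1")
  if (n_classes < 2) stop("need at least two classes")
  set.seed(as.integer(seed))
  grow <- function(d) {
    if (d == 0L) return(list(leaf = TRUE, class = NA_integer_))
    list(leaf = FALSE,
         attr = sample.int(n_attributes, 1L),
         threshold = stats::runif(1, 0.3, 0.7),
         left = grow(d - 1L),
         right = grow(d - 1L))
  }
  root <- grow(as.integer(depth))
  n_leaves <- 2L^as.integer(depth)
  classes <- sample(rep_len(seq_len(n_classes), n_leaves))
  i <- 0L
  assign_classes <- function(node) {
    if (node$leaf) {
      i <<- i + 1L
      node$class <- classes[i]
      return(node)
    }
    node$left <- assign_classes(node$left)
    node$right <- assign_classes(node$right)
    node
  }
  structure(list(root = assign_classes(root), n_attributes = n_attributes,
                 n_classes = n_classes, depth = as.integer(depth)),
            class = "stream_concept")
}

#' Class labels of instances under a concept
#'
#' @param concept A [make_concept()] object.
#' @param X Numeric matrix (instances x attributes).
#' @return Integer class vector.
#' @export
concept_labels <- function(concept, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  lab <- function(node, i) {
    while (!node$leaf) {
      node <- if (X[i, node$attr] <= node$threshold) node$left else node$right
    }
    node$class
  }
  vapply(seq_len(nrow(X)), function(i) lab(concept$root, i), 0L)
}

#' Generate a labeled synthetic stream with ground-truth outlier flags
#'
#' Base instances have uniform(0, 1) attributes labeled by a random concept.
#' Point noise replaces one random attribute of a corrupted instance with
#' `Q3 + magnitude * IQR` above (or `Q1 - magnitude * IQR` below, sign
#' random) the clean quartiles, optionally flipping the label. Rare-group
#' instances are drawn from a tight cluster centered beyond the fences on
#' every attribute and carry a dedicated class `"rare"`. Instance order is
#' randomized by the seed.
#'
#' @param config A [synth_config()].
#' @return An [odr_stream()] whose `truth` holds `truth_outlier` and
#'   `truth_group` flags.
#' @export
generate_stream <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  concept <- make_concept(config$n_attributes, config$n_classes,
                          config$concept_depth, config$seed)
  set.seed(config$seed + 1L)
  n <- config$n_instances
  p <- config$n_attributes
  k <- config$n_classes
  n_rare <- round(config$rare_group_rate * n)
  n_base <- n - n_rare
  X <- matrix(stats::runif(n_base * p), n_base, p)
  y <- concept_labels(concept, X)
  outlier <- logical(n_base)
  group <- logical(n_base)

  n_noise <- round(config$noise_rate * n)
  if (n_noise > 0) {
    idx <- sample.int(n_base, n_noise)
    attr_j <- sample.int(p, n_noise, replace = TRUE)
    up <- stats::runif(n_noise) < 0.5
    # clean uniform quartiles: Q1 = 0.25, Q3 = 0.75, IQR = 0.5
    val <- ifelse(up, 0.75 + config$outlier_magnitude * 0.5,
                  0.25 - config$outlier_magnitude * 0.5)
    X[cbind(idx, attr_j)] <- val
    outlier[idx] <- TRUE
    if (config$label_flip_on_noise) {
      y[idx] <- vapply(y[idx], function(cl) {
        sample(setdiff(seq_len(k), cl), 1L)
      }, 0L)
    }
  }

  class_levels <- paste0("c", seq_len(k))
  if (n_rare > 0) {
    center <- 0.75 + config$outlier_magnitude * 0.5
    Xr <- matrix(stats::rnorm(n_rare * p, center, 0.02), n_rare, p)
    X <- rbind(X, Xr)
    y <- c(y, rep(k + 1L, n_rare))
    outlier <- c(outlier, rep(TRUE, n_rare))
    group <- c(group, rep(TRUE, n_rare))
    class_levels <- c(class_levels, "rare")
  }

  ord <- sample.int(n)
  X <- X[ord, , drop = FALSE]
  y <- y[ord]
  outlier <- outlier[ord]
  group <- group[ord]

  attr_names <- paste0("a", seq_len(p))
  df <- as.data.frame(X)
  names(df) <- attr_names
  df$class <- factor(class_levels[y], levels = class_levels)
  schema <- stream_schema(lapply(attr_names, attribute_spec, kind = "numeric"),
                          attribute_spec("class", "nominal", class_levels))
  odr_stream(df, schema,
             truth = data.frame(truth_outlier = outlier, truth_group = group))
}

#' Precision and recall of detected outliers against ground truth
#'
#' @param detected_idx 1-based stream indices flagged as outliers.
#' @param stream An [odr_stream()] carrying truth flags.
#' @return List with `precision`, `recall`, `n_detected`, `n_truth`, and
#'   `zero_detection` (when nothing was detected, precision is reported as 1
#'   with this flag set).
#' @export
truth_confusion <- function(detected_idx, stream) {
  if (is.null(stream$truth)) stop("stream carries no ground-truth outlier flags")
  truth_idx <- which(stream$truth$truth_outlier)
  tp <- length(intersect(detected_idx, truth_idx))
  n_det <- length(unique(detected_idx))
  n_truth <- length(truth_idx)
  list(precision = if (n_det == 0) 1 else tp / n_det,
       recall = if (n_truth == 0) 1 else tp / n_truth,
       n_detected = n_det,
       n_truth = n_truth,
       zero_detection = n_det == 0)
}
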
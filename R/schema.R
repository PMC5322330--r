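#' Declare a stream attribute
#'
#' An attribute is either `numeric` or `nominal`; nominal attributes carry an
#' ordered, unique set of category labels.
#'
#' @param name Attribute name (single non-empty string).
#' @param kind `"numeric"` or `"nominal"`.
#' @param categories Character vector of category labels; required (non-empty,
#'   unique) for nominal attributes, must be absent for numeric ones.
#' @return An object of class `attribute_spec`.
#' @export
#' @examples
#' attribute_spec("age", "numeric")
#' attribute_spec("state", "nominal", c("open", "closed"))
attribute_spec <- function(name, kind = c("numeric", "nominal"), categories = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("attribute name must be a single non-empty string")
  }
  if (kind == "nominal") {
    if (is.null(categories) || length(categories) == 0L) {
      stop("nominal attribute '", name, "' needs a non-empty set of categories")
    }
    categories <- as.character(categories)
    if (anyDuplicated(categories)) {
      stop("categories of '", name, "' must be unique")
    }
  } else if (!is.null(categories)) {
    stop("numeric attribute '", name, "' must not declare categories")
  }
  structure(list(name = name, kind = kind, categories = categories),
            class = "attribute_spec")
}

#' Stream schema: ordered attributes plus a nominal class attribute
#'
#' @param attributes List of [attribute_spec()] objects (the predictive
#'   attributes, in stream column order).
#' @param class_attribute An [attribute_spec()] of kind `"nominal"`; must not
#'   share a name with any predictive attribute.
#' @return An object of class `stream_schema`.
#' @export
stream_schema <- function(attributes, class_attribute) {
  if (inherits(attributes, "attribute_spec")) attributes <- list(attributes)
  if (!length(attributes) || !all(vapply(attributes, inherits, TRUE, "attribute_spec"))) {
    stop("'attributes' must be a non-empty list of attribute_spec objects")
  }
  if (!inherits(class_attribute, "attribute_spec") || class_attribute$kind != "nominal") {
    stop("'class_attribute' must be a nominal attribute_spec")
  }
  nm <- vapply(attributes, `[[`, "", "name")
  if (anyDuplicated(c(nm, class_attribute$name))) {
    stop("attribute names must be unique and distinct from the class attribute")
  }
  structure(list(attributes = attributes, class_attribute = class_attribute),
            class = "stream_schema")
}

#' Schema accessors
#'
#' Predictive attribute names, kinds (`"numeric"`/`"nominal"`), nominal
#' category sets, and the class levels of a [stream_schema()].
#'
#' @param schema A [stream_schema()].
#' @return A character vector (`schema_attr_names`, `schema_attr_kinds`,
#'   `schema_class_levels`) or a list of category vectors
#'   (`schema_attr_levels`, `NULL` entries for numeric attributes).
#' @export
schema_attr_names <- function(schema) unname(vapply(schema$attributes, `[[`, "", "name"))

#' @rdname schema_attr_names
#' @export
schema_attr_kinds <- function(schema) unname(vapply(schema$attributes, `[[`, "", "kind"))

#' @rdname schema_attr_names
#' @export
schema_attr_levels <- function(schema) unname(lapply(schema$attributes, `[[`, "categories"))

#' @rdname schema_attr_names
#' @export
schema_class_levels <- function(schema) schema$class_attribute$categories

schema_n_attrs <- function(schema) length(schema$attributes)

#' @export
print.stream_schema <- function(x, ...) {
  kinds <- schema_attr_kinds(x)
  cat("stream_schema:", length(kinds), "predictive attributes (",
      sum(kinds == "numeric"), "numeric,", sum(kinds == "nominal"), "nominal ),",
      "class", sQuote(x$class_attribute$name), "with",
      length(schema_class_levels(x)), "levels\n")
  invisible(x)
}

#' Bundle a schema with instance data as a stream
#'
#' The in-memory representation of a finite labeled stream: a `data.frame`
#' whose columns follow the schema (predictive attributes in order, class
#' column last), plus optional per-instance ground-truth outlier flags from
#' the synthetic generator.
#'
#' @param data A `data.frame` with one column per schema attribute plus the
#'   class column. Nominal columns are coerced to factors with the declared
#'   categories; values outside the declared domain are an error.
#' @param schema A [stream_schema()]; if `NULL`, inferred from `data`
#'   (numeric columns numeric, everything else nominal with observed
#'   categories, class column = last unless named by `class_column`).
#' @param class_column Class column name or index used during inference.
#' @param truth Optional `data.frame` with logical columns `truth_outlier`
#'   and `truth_group` (synthetic streams only).
#' @return An object of class `odr_stream`.
#' @export
odr_stream <- function(data, schema = NULL, class_column = NULL, truth = NULL) {
  if (!is.data.frame(data)) stop("'data' must be a data.frame")
  if (is.null(schema)) schema <- infer_schema(data, class_column)
  nm <- schema_attr_names(schema)
  cls <- schema$class_attribute$name
  missing_cols <- setdiff(c(nm, cls), names(data))
  if (length(missing_cols)) {
    stop("data lacks schema columns: ", paste(missing_cols, collapse = ", "))
  }
  data <- data[c(nm, cls)]
  kinds <- schema_attr_kinds(schema)
  levs <- schema_attr_levels(schema)
  for (j in seq_along(nm)) {
    if (kinds[j] == "numeric") {
      data[[j]] <- as.numeric(data[[j]])
    } else {
      v <- as.character(data[[j]])
      bad <- which(!is.na(v) & !(v %in% levs[[j]]))
      if (length(bad)) {
        stop("row ", bad[1L], ": value '", v[bad[1L]], "' outside declared domain of '",
             nm[j], "'")
      }
      data[[j]] <- factor(v, levels = levs[[j]])
    }
  }
  yv <- as.character(data[[cls]])
  badc <- which(!is.na(yv) & !(yv %in% schema_class_levels(schema)))
  if (length(badc)) {
    stop("row ", badc[1L], ": class value '", yv[badc[1L]], "' outside declared domain")
  }
  data[[cls]] <- factor(yv, levels = schema_class_levels(schema))
  if (!is.null(truth)) {
    stopifnot(is.data.frame(truth), nrow(truth) == nrow(data))
  }
  structure(list(schema = schema, data = data, truth = truth), class = "odr_stream")
}

# Type inference for headered tabular input: a column is numeric iff every
# non-missing value parses as a number; otherwise nominal with categories in
# order of first appearance.  All-or-nothing by design (deterministic).
infer_schema <- function(data, class_column = NULL) {
  if (!ncol(data)) stop("cannot infer a schema from a zero-column data.frame")
  if (is.null(class_column)) class_column <- ncol(data)
  if (is.character(class_column)) {
    ci <- match(class_column, names(data))
    if (is.na(ci)) stop("class column '", class_column, "' not found")
  } else {
    ci <- as.integer(class_column)
    if (ci < 1L || ci > ncol(data)) stop("class column index out of range")
  }
  specs <- vector("list", ncol(data) - 1L)
  k <- 0L
  for (j in seq_len(ncol(data))) {
    if (j == ci) next
    k <- k + 1L
    specs[[k]] <- infer_attribute(names(data)[j], data[[j]])
  }
  cv <- as.character(data[[ci]])
  cl <- unique(cv[!is.na(cv) & cv != ""])
  if (!length(cl)) stop("class column '", names(data)[ci], "' has no observed values")
  stream_schema(specs, attribute_spec(names(data)[ci], "nominal", cl))
}

infer_attribute <- function(name, v) {
  if (is.numeric(v)) return(attribute_spec(name, "numeric"))
  ch <- as.character(v)
  obs <- ch[!is.na(ch) & ch != ""]
  num <- suppressWarnings(as.numeric(obs))
  if (length(obs) && !anyNA(num)) {
    attribute_spec(name, "numeric")
  } else {
    attribute_spec(name, "nominal", unique(obs))
  }
}

#' @export
print.odr_stream <- function(x, ...) {
  cat("odr_stream:", nrow(x$data), "instances\n")
  print(x$schema)
  if (!is.null(x$truth)) {
    cat("ground truth:", sum(x$truth$truth_outlier), "flagged outliers\n")
  }
  invisible(x)
}

# Compile a stream to the numeric representation the learner and detector
# consume: X is an n x p matrix (nominal values coded as 1-based level
# indices), y an integer class vector.
compile_stream <- function(stream) {
  schema <- stream$schema
  nm <- schema_attr_names(schema)
  kinds <- schema_attr_kinds(schema)
  n <- nrow(stream$data)
  X <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
  for (j in seq_along(nm)) {
    col <- stream$data[[j]]
    X[, j] <- if (kinds[j] == "numeric") as.numeric(col) else as.numeric(as.integer(col))
  }
  y <- as.integer(stream$data[[schema$class_attribute$name]])
  list(X = X, y = y, kinds = kinds,
       levels = schema_attr_levels(schema),
       class_levels = schema_class_levels(schema))
}
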
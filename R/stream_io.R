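#' Read an ARFF file as a stream
#'
#' Parses the dense ARFF dialect (`@relation` / `@attribute` / `@data`,
#' `?` for missing, nominal domains in braces). String, date and sparse
#' declarations are not supported. Malformed headers raise a schema error
#' naming the offending line; data values outside a declared nominal domain
#' (or unparsable numerics) raise a record error naming the row.
#'
#' @param path Path to an ARFF file.
#' @param class_attribute Name of the class attribute; defaults to the last
#'   declared attribute. Must be nominal.
#' @return An [odr_stream()].
#' @export
read_arff <- function(path, class_attribute = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  specs <- list()
  data_at <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "%")) next
    low <- tolower(ln)
    if (startsWith(low, "@relation")) next
    if (startsWith(low, "@data")) { data_at <- i; break }
    if (startsWith(low, "@attribute")) {
      specs[[length(specs) + 1L]] <- parse_arff_attribute(ln, i)
      next
    }
    stop("line ", i, ": unexpected content before @data: ", ln)
  }
  if (is.na(data_at)) stop("malformed ARFF header: no @data section")
  if (length(specs) < 2L) {
    stop("ARFF header must declare at least one predictive attribute and a class")
  }
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (is.null(class_attribute)) class_attribute <- specs[[length(specs)]]$name
  ci <- match(class_attribute, names(specs))
  if (is.na(ci)) stop("class attribute '", class_attribute, "' not declared in header")
  if (specs[[ci]]$kind != "nominal") {
    stop("class attribute '", class_attribute, "' must be nominal")
  }
  schema <- stream_schema(specs[-ci], specs[[ci]])

  body <- lines[seq.int(data_at + 1L, length.out = max(0L, length(lines) - data_at))]
  body <- trimws(body)
  body <- body[nzchar(body) & !startsWith(body, "%")]
  p <- length(specs)
  cols <- rep(list(character(length(body))), p)
  for (r in seq_along(body)) {
    f <- trimws(strsplit(body[r], ",", fixed = TRUE)[[1]])
    if (length(f) != p) {
      stop("row ", r, ": expected ", p, " values, found ", length(f))
    }
    for (j in seq_len(p)) cols[[j]][r] <- f[j]
  }
  df <- data.frame(matrix(nrow = length(body), ncol = 0))
  for (j in seq_len(p)) {
    v <- unquote_arff(cols[[j]])
    v[v == "?"] <- NA_character_
    if (specs[[j]]$kind == "numeric") {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        stop("row ", bad[1L], ": value '", v[bad[1L]], "' of '", specs[[j]]$name,
             "' is not numeric")
      }
      df[[specs[[j]]$name]] <- num
    } else {
      df[[specs[[j]]$name]] <- v
    }
  }
  odr_stream(df, schema)
}

parse_arff_attribute <- function(ln, lineno) {
  rest <- trimws(sub("^@[Aa][Tt][Tt][Rr][Ii][Bb][Uu][Tt][Ee]\\s+", "", ln))
  if (startsWith(rest, "'")) {
    close <- regexpr("'", substring(rest, 2), fixed = TRUE)
    if (close < 0) stop("line ", lineno, ": unterminated quoted attribute name")
    nm <- substring(rest, 2, close)
    type <- trimws(substring(rest, close + 2))
  } else {
    sp <- regexpr("\\s", rest)
    if (sp < 0) stop("line ", lineno, ": attribute declaration lacks a type")
    nm <- substring(rest, 1, sp - 1)
    type <- trimws(substring(rest, sp + 1))
  }
  if (startsWith(type, "{")) {
    if (!endsWith(type, "}")) stop("line ", lineno, ": unterminated nominal domain")
    cats <- trimws(strsplit(substring(type, 2, nchar(type) - 1), ",", fixed = TRUE)[[1]])
    cats <- unquote_arff(cats)
    if (!length(cats)) stop("line ", lineno, ": empty nominal domain")
    attribute_spec(nm, "nominal", cats)
  } else if (tolower(type) %in% c("numeric", "real", "integer")) {
    attribute_spec(nm, "numeric")
  } else {
    stop("line ", lineno, ": unsupported attribute type '", type, "'")
  }
}

unquote_arff <- function(x) {
  q <- startsWith(x, "'") & endsWith(x, "'") & nchar(x) >= 2L
  x[q] <- substring(x[q], 2, nchar(x[q]) - 1L)
  x
}

#' Write a stream to an ARFF file
#'
#' Inverse of [read_arff()]: writing a parsed stream and re-reading it yields
#' an identical schema and identical values.
#'
#' @param stream An [odr_stream()].
#' @param path Output file path.
#' @param relation Relation name for the `@relation` line.
#' @return `path`, invisibly.
#' @export
write_arff <- function(stream, path, relation = "stream") {
  stopifnot(inherits(stream, "odr_stream"))
  schema <- stream$schema
  specs <- c(schema$attributes, list(schema$class_attribute))
  hdr <- c(paste0("@relation ", relation), "",
           vapply(specs, function(s) {
             type <- if (s$kind == "numeric") "numeric" else
               paste0("{", paste(s$categories, collapse = ","), "}")
             paste0("@attribute ", s$name, " ", type)
           }, ""),
           "", "@data")
  cols <- lapply(stream$data, function(col) {
    v <- if (is.numeric(col)) format_num(col) else as.character(col)
    v[is.na(col)] <- "?"
    v
  })
  writeLines(c(hdr, do.call(paste, c(cols, sep = ","))), path)
  invisible(path)
}

format_num <- function(x) {
  out <- vapply(x, function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE), "")
  out
}

#' Read a headered CSV file as a stream
#'
#' Column types are inferred: a column is numeric iff every non-missing value
#' parses as a number, otherwise nominal with categories in order of first
#' appearance. Empty strings and `?` are treated as missing. The class column
#' is always treated as nominal.
#'
#' @param path Path to a CSV file with a header row.
#' @param class_column Class column name or 1-based index (default: last column).
#' @param sep Field delimiter.
#' @return An [odr_stream()].
#' @export
read_stream_csv <- function(path, class_column = NULL, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    sep = sep, fill = FALSE, strip.white = TRUE),
    error = function(e) stop("malformed CSV: ", conditionMessage(e), call. = FALSE))
  if (!ncol(df)) stop("empty file: ", path)
  if (!nrow(df)) stop("CSV has a header but no data rows: ", path)
  for (j in seq_len(ncol(df))) df[[j]][df[[j]] %in% c("", "?")] <- NA_character_
  schema <- infer_schema(df, class_column)
  odr_stream(df, schema)
}

#' Slice a stream into (possibly overlapping) windows
#'
#' Window `k` covers 0-based stream indices `[k*m, k*m + omega)`. After the
#' last full window, a short tail window is emitted if it holds at least 4
#' still-uncovered instances (quartiles need four points); a shorter
#' uncovered tail is appended to the previous window instead.
#'
#' @param n_instances Stream length.
#' @param omega Window length (>= 4). The sliding-window length over which
#'   quartile fences are computed; default 1000.
#' @param m Step between window starts, `1 <= m <= omega`. With `m = omega`
#'   (the default) windows partition the stream.
#' @return A `data.frame` with columns `start` (0-based) and `length`; zero
#'   rows (with a warning) when the stream is shorter than 4.
#' @export
#' @examples
#' sliding_windows(10, 4)       # starts 0,4; tail of 2 appended to the second
#' sliding_windows(10, 4, m = 2)
sliding_windows <- function(n_instances, omega = 1000L, m = omega) {
  n <- as.integer(n_instances)
  omega <- as.integer(omega)
  m <- as.integer(m)
  if (is.na(omega) || omega < 4L) stop("omega must be at least 4 (quartiles need 4 points)")
  if (is.na(m) || m < 1L || m > omega) stop("step m must satisfy 1 <= m <= omega")
  empty <- data.frame(start = integer(0), length = integer(0))
  if (n < 4L) {
    warning("stream holds fewer than 4 instances; no windows emitted")
    return(empty)
  }
  if (n < omega) return(data.frame(start = 0L, length = n))
  starts <- seq.int(0L, n - omega, by = m)
  len <- rep(omega, length(starts))
  last <- starts[length(starts)]
  if (last + omega < n) {            # uncovered tail remains
    nxt <- last + m
    if (n - nxt >= 4L) {
      starts <- c(starts, nxt)
      len <- c(len, n - nxt)
    } else {
      len[length(len)] <- n - last   # absorb the short tail
    }
  }
  data.frame(start = starts, length = len)
}
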
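# Independent brute-force oracles, deliberately written from scratch (sort +
# closed-form interpolation + per-value checks) so they share no code with
# the implementation they verify.

oracle_quantile <- function(values, p) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (n == 1L) return(x)
  h <- p * (n - 1)
  lo <- floor(h)
  frac <- h - lo
  if (lo + 2 > n) return(x[n])
  x[lo + 1] + frac * (x[lo + 2] - x[lo + 1])
}

oracle_fences <- function(values, beta) {
  q1 <- oracle_quantile(values, 0.25)
  q3 <- oracle_quantile(values, 0.75)
  iqr <- q3 - q1
  c(lower = q1 - beta * iqr, upper = q3 + beta * iqr)
}

# Full-window brute-force outlier flags (rule = any, strict comparisons).
oracle_detect <- function(window_df, beta) {
  flags <- rep(FALSE, nrow(window_df))
  for (col in window_df) {
    if (!is.numeric(col)) next
    if (all(is.na(col))) next
    f <- oracle_fences(col[!is.na(col)], beta)
    flags <- flags | (!is.na(col) & (col < f["lower"] | col > f["upper"]))
  }
  flags
}

# Batch entropy gain over a branches x classes contingency table.
oracle_entropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

oracle_gain <- function(tab) {
  n <- sum(tab)
  parent <- oracle_entropy(colSums(tab))
  children <- sum(vapply(seq_len(nrow(tab)), function(b) {
    sum(tab[b, ]) / n * oracle_entropy(tab[b, ])
  }, 0))
  parent - children
}

# Small two-numeric-attribute schema used across tests.
two_attr_schema <- function(class_levels = c("a", "b")) {
  stream_schema(list(attribute_spec("x1", "numeric"),
                     attribute_spec("x2", "numeric")),
                attribute_spec("class", "nominal", class_levels))
}

# Write ARFF text to a temp file and return the path.
tmp_arff <- function(lines) {
  path <- tempfile(fileext = ".arff")
  writeLines(lines, path)
  path
}

# Train a tree on the first n rows of a generated stream's data.frame.
train_on <- function(model, df, rows) {
  p <- ncol(df) - 1L
  for (i in rows) {
    learn_one(model, df[i, seq_len(p), drop = FALSE], df$class[i])
  }
  model
}
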
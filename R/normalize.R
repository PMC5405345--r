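#' Normalize a feature table (schemes N1-N5)
#'
#' Applies one of five per-column normalization schemes to a feature table:
#' \describe{
#'   \item{n1}{none (raw values).}
#'   \item{n2}{range normalization to `[0, 1]`: `(x - min) / (max - min)`.}
#'   \item{n3}{z-scores (sample standard deviation, denominator L-1).}
#'   \item{n4}{rank transformation within the test set: a value maps to
#'     `l / L`, where `l` is its (mid-)rank among the table's own `L` values.}
#'   \item{n5}{rank transformation against a reference corpus: `l' / L'`, with
#'     `l'` the value's rank within the corpus column of size `L'`. Values
#'     tied with corpus values get the tied group's average rank; values
#'     absent from the corpus get their insertion rank (count of corpus
#'     values `<= x`), so a query below all corpus values maps to 0 and one
#'     above all maps to 1.}
#' }
#' Columns are normalized independently; tables normalized under different
#' schemes are never pooled.
#'
#' @param table Feature table (data.frame with `clip_id` column).
#' @param scheme One of `"n1"`..`"n5"`.
#' @param corpus Reference feature table, required for `"n5"`; must contain
#'   every feature column of `table`.
#' @return Feature table of the same shape with normalized values.
#' @export
normalize_features <- function(table, scheme = c("n1", "n2", "n3", "n4", "n5"),
                               corpus = NULL) {
  scheme <- match.arg(scheme)
  x <- feature_matrix(table)
  if (scheme == "n1") return(table)
  if (scheme == "n5") {
    if (is.null(corpus)) stop("scheme n5 requires a reference corpus")
    cx <- feature_matrix(corpus)
    missing <- setdiff(colnames(x), colnames(cx))
    if (length(missing))
      stop("corpus lacks feature columns: ", paste(missing, collapse = ", "))
  }
  out <- x
  for (f in colnames(x)) {
    v <- x[, f]
    out[, f] <- switch(scheme,
      n2 = {
        r <- range(v)
        if (r[1] == r[2])
          stop("cannot range-normalize constant feature '", f, "'")
        (v - r[1]) / (r[2] - r[1])
      },
      n3 = {
        s <- stats::sd(v)
        if (s == 0)
          stop("cannot z-score constant feature '", f, "'")
        (v - mean(v)) / s
      },
      n4 = rank(v, ties.method = "average") / length(v),
      n5 = {
        ref <- cx[, f]
        if (!length(ref) || all(is.na(ref)))
          stop("corpus column '", f, "' is empty")
        reference_rank(v, ref) / length(ref)
      }
    )
  }
  res <- table
  for (f in colnames(out)) res[[f]] <- unname(out[, f])
  res
}

# Rank of each query value within a reference sample: midrank of the tied
# group when the value occurs in the reference, insertion count (values <= x)
# otherwise.
reference_rank <- function(q, ref) {
  s <- sort(ref)
  n_le <- findInterval(q, s)                      # count of ref <= q
  n_lt <- findInterval(q, s, left.open = TRUE)    # count of ref <  q
  tied <- n_le > n_lt
  r <- as.numeric(n_le)
  r[tied] <- (n_lt[tied] + 1 + n_le[tied]) / 2
  r
}
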
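#' Pair index over n clips (column-major lower triangle)
#'
#' Fixed pair ordering shared by the design matrix, meta predictors, and the
#' response vector: (2,1), (3,1), ..., (n,1), (3,2), ... with `i > j`.
#'
#' @param n Number of clips (or a character vector of clip ids).
#' @return data.frame with integer columns `i`, `j` (i > j); if ids were
#'   given, also `clip_i`, `clip_j`.
#' @export
pair_index <- function(n) {
  ids <- NULL
  if (is.character(n)) { ids <- n; n <- length(n) }
  stopifnot(n >= 2L)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)  # column-major
  out <- data.frame(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]))
  if (!is.null(ids)) { out$clip_i <- ids[out$i]; out$clip_j <- ids[out$j] }
  out
}

#' Pairwise absolute-difference design matrix
#'
#' For every non-identical clip pair and every feature, the predictor is the
#' absolute difference of the pair's feature values. With 16 clips this gives
#' m = 120 = 16*15/2 rows.
#'
#' @param table Feature table (data.frame with `clip_id` column).
#' @return Object of class `design_matrix`: list with `X`
#'   (m x n_features matrix), `pair_index`, `feature_names`, `clip_ids`.
#' @export
pairwise_distances <- function(table) {
  x <- feature_matrix(table)
  if (nrow(x) < 2L) stop("at least 2 clips are required")
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite feature value for clip '", rownames(x)[bad[1L]],
         "', feature '", colnames(x)[bad[2L]], "'")
  }
  pi_ <- pair_index(rownames(x))
  X <- abs(x[pi_$i, , drop = FALSE] - x[pi_$j, , drop = FALSE])
  dimnames(X) <- list(paste(pi_$clip_i, pi_$clip_j, sep = ":"), colnames(x))
  structure(list(X = X, pair_index = pi_, feature_names = colnames(x),
                 clip_ids = rownames(x)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix: %d pairs x %d features>\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Meta predictors: genre mismatch and release-date distance
#'
#' Per pair: `meta.genre` is the binary genre predictor (0 = same genre,
#' 1 = different genre) and `meta.date` the absolute release-year difference.
#'
#' @param metadata data.frame with `clip_id`, `genre`, `release_year`.
#' @param clip_ids Clip ordering defining the pairs (default: metadata order).
#' @return m x 2 matrix with columns `meta.genre`, `meta.date`.
#' @export
meta_columns <- function(metadata, clip_ids = metadata$clip_id) {
  need <- c("clip_id", "genre", "release_year")
  if (!all(need %in% names(metadata)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  m <- metadata[match(clip_ids, metadata$clip_id), ]
  if (anyNA(m$clip_id) || anyNA(m$genre) || anyNA(m$release_year))
    stop("missing metadata for some clips")
  pi_ <- pair_index(clip_ids)
  out <- cbind(meta.genre = as.numeric(m$genre[pi_$i] != m$genre[pi_$j]),
               meta.date = abs(m$release_year[pi_$i] - m$release_year[pi_$j]))
  rownames(out) <- paste(clip_ids[pi_$i], clip_ids[pi_$j], sep = ":")
  out
}

#' Similarity response vector over non-identical pairs
#'
#' Extracts the lower-triangle off-diagonal entries of a symmetric similarity
#' matrix in the shared pair order of [pair_index()]. Diagonal entries are
#' never included.
#'
#' @param sim Symmetric similarity matrix (e.g. from
#'   [aggregate_similarity()]).
#' @param tol Asymmetry tolerance.
#' @return Named numeric vector of length `n*(n-1)/2`.
#' @export
response_vector <- function(sim, tol = 1e-8) {
  sim <- as.matrix(sim)
  if (nrow(sim) != ncol(sim) || max(abs(sim - t(sim))) > tol)
    stop("similarity matrix must be symmetric")
  ids <- rownames(sim)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(sim)))
  y <- sim[lower.tri(sim)]   # column-major lower triangle = pair_index order
  pi_ <- pair_index(ids)
  names(y) <- paste(pi_$clip_i, pi_$clip_j, sep = ":")
  y
}
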
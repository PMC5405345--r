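#' Bootstrap percentile confidence intervals for PLSR coefficients
#'
#' Resamples at the clip level: per replicate, `n_drop` clip indices are drawn
#' with replacement (so 1 to `n_drop` distinct clips are removed), every pair
#' touching a drawn clip is deleted, and the SIMPLS model is refit with `k`
#' components on the surviving pairs (with 16 clips and 4 draws this retains
#' on average about 60% of the 120 pairs). After `B` replicates the 0.025 and
#' 0.975 percentiles of each coefficient are taken as confidence boundaries;
#' a feature whose interval excludes zero is selected for the sparse model.
#' Replicates whose surviving design matrix has rank below `k` are refit with
#' the attainable number of components and counted in `reduced_k`.
#'
#' @param X A `design_matrix` (its `pair_index` identifies which clips each
#'   pair touches).
#' @param y Response vector over the same pairs.
#' @param B Number of bootstrap replicates (default 1000).
#' @param n_drop Clip draws (with replacement) per replicate (default 4).
#' @param k Latent components per refit (default 2).
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param level Confidence level (default 0.95, i.e. 0.025/0.975 percentiles).
#' @return Object of class `bootstrap_result`: `coefficient_samples` (B x n),
#'   `ci` (data.frame: feature, lo, hi, selected), `selected` (character),
#'   `B`, `n_drop`, `k`, `seed`, `reduced_k` (count of rank-reduced
#'   replicates), `retained` (per-replicate retained-pair fraction).
#' @export
bootstrap_coefficients <- function(X, y, B = 1000L, n_drop = 4L, k = 2L,
                                   seed = 1L, level = 0.95) {
  stopifnot(inherits(X, "design_matrix"))
  if (B < 1L) stop("B must be at least 1")
  Xm <- X$X
  y <- as.numeric(y)
  n_clips <- length(X$clip_ids)
  i <- X$pair_index$i
  j <- X$pair_index$j
  n <- ncol(Xm)
  withr::with_seed(seed, {
    samples <- matrix(NA_real_, B, n, dimnames = list(NULL, colnames(Xm)))
    retained <- numeric(B)
    reduced_k <- 0L
    for (b in seq_len(B)) {
      drawn <- sample.int(n_clips, n_drop, replace = TRUE)
      keep <- !(i %in% drawn | j %in% drawn)
      retained[b] <- mean(keep)
      if (sum(keep) < 3L) {        # degenerate replicate: no refittable model
        samples[b, ] <- 0
        reduced_k <- reduced_k + 1L
        next
      }
      Xb <- Xm[keep, , drop = FALSE]
      yb <- y[keep]
      rk <- qr(sweep(Xb, 2L, colMeans(Xb)))$rank
      kb <- min(k, rk, nrow(Xb) - 1L)
      if (kb < k) reduced_k <- reduced_k + 1L
      samples[b, ] <- if (kb >= 1L) fit_simpls(Xb, yb, k = kb)$beta else 0
    }
    alpha <- (1 - level) / 2
    lo <- apply(samples, 2L, stats::quantile, probs = alpha)
    hi <- apply(samples, 2L, stats::quantile, probs = 1 - alpha)
    sel <- lo > 0 | hi < 0
    structure(list(
      coefficient_samples = samples,
      ci = data.frame(feature = colnames(Xm), lo = unname(lo),
                      hi = unname(hi), selected = unname(sel),
                      row.names = NULL, stringsAsFactors = FALSE),
      selected = colnames(Xm)[sel],
      B = B, n_drop = n_drop, k = k, seed = seed, level = level,
      reduced_k = reduced_k, retained = retained),
      class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result: B = %d, %d/%d features selected>\n",
              x$B, length(x$selected), nrow(x$ci)))
  invisible(x)
}

#' Refit a sparse SIMPLS model on the selected features
#'
#' @param X A `design_matrix`.
#' @param y Response vector.
#' @param selected Nonempty character vector of feature names (typically the
#'   `selected` element of a [bootstrap_coefficients()] result).
#' @param k Latent components, capped at the number of selected features.
#' @return A `simpls_model` fit on the selected columns over all pairs.
#' @export
fit_sparse <- function(X, y, selected, k = 2L) {
  stopifnot(inherits(X, "design_matrix"))
  if (!length(selected))
    stop("empty feature selection: no confidence interval excluded zero; ",
         "fall back to the full model")
  missing <- setdiff(selected, X$feature_names)
  if (length(missing))
    stop("unknown features: ", paste(missing, collapse = ", "))
  Xs <- X$X[, selected, drop = FALSE]
  k <- min(k, length(selected))
  rk <- qr(sweep(Xs, 2L, colMeans(Xs)))$rank
  fit_simpls(Xs, y, k = min(k, rk))
}

#' Monte-Carlo retained-pair fraction under clip-level deletion
#'
#' Simulates the bootstrap deletion scheme: per replicate, `n_drop` clip
#' indices are drawn with replacement from `n_clips` and every pair touching
#' a drawn clip is deleted from the `n_clips * (n_clips - 1) / 2` pairs.
#' Returns the per-replicate retained fractions; their mean estimates the
#' closed-form value `((n_clips - 2) / n_clips)^n_drop` (about 0.586 for 16
#' clips and 4 draws).
#'
#' @param n_clips Number of clips (default 16).
#' @param n_drop Clip draws with replacement per replicate (default 4).
#' @param n_rep Number of replicates (default 10000).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_rep` of retained-pair fractions.
#' @export
simulate_retention <- function(n_clips = 16L, n_drop = 4L, n_rep = 10000L,
                               seed = 1L) {
  pi_ <- pair_index(n_clips)
  i <- pi_$i; j <- pi_$j
  withr::with_seed(seed, {
    vapply(seq_len(n_rep), function(b) {
      drawn <- sample.int(n_clips, n_drop, replace = TRUE)
      mean(!(i %in% drawn | j %in% drawn))
    }, 0)
  })
}
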
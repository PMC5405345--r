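as_X <- function(X) {
  if (inherits(X, "design_matrix")) X$X else as.matrix(X)
}

# SIMPLS core on centered data. Extracts up to k components; stops early if
# the deflated cross-product vector vanishes (y fully explained or constant).
simpls_core <- function(X0, y0, k) {
  m <- nrow(X0); n <- ncol(X0)
  R <- matrix(0, n, k); P <- matrix(0, n, k); V <- matrix(0, n, k)
  Tm <- matrix(0, m, k); U <- matrix(0, m, k); q <- numeric(k)
  s <- crossprod(X0, y0)          # n x 1 cross-product vector
  a <- 0L
  while (a < k) {
    if (sum(s^2) < 1e-24) break   # nothing left to extract
    a <- a + 1L
    r <- s                        # univariate y: dominant direction is s itself
    t <- X0 %*% r
    normt <- sqrt(sum(t^2))
    if (normt < 1e-12) { a <- a - 1L; break }
    t <- t / normt; r <- r / normt
    p <- crossprod(X0, t)
    qa <- sum(y0 * t)
    u <- y0 * qa
    v <- p
    if (a > 1L) {
      Vprev <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vprev %*% crossprod(Vprev, p)
      Tprev <- Tm[, seq_len(a - 1L), drop = FALSE]
      u <- u - Tprev %*% crossprod(Tprev, u)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r; P[, a] <- p; V[, a] <- v; Tm[, a] <- t; U[, a] <- u; q[a] <- qa
  }
  keep <- seq_len(a)
  list(R = R[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       T = Tm[, keep, drop = FALSE], U = U[, keep, drop = FALSE],
       q = q[keep], k = a)
}

#' Partial least-squares regression via SIMPLS
#'
#' Fits a univariate-response PLSR model with `k` latent components using the
#' SIMPLS algorithm: predictors and response are mean-centered (no variance
#' scaling; scaling is the job of the upstream normalization schemes), and
#' successive weight vectors maximize the covariance between predictor and
#' response scores subject to deflation of the cross-product vector, which
#' makes the predictor scores mutually orthogonal. Regression coefficients on
#' the original predictor scale are recovered as `beta = W* q'`.
#'
#' @param X A `design_matrix` or numeric matrix (m pairs x n features).
#' @param y Numeric response of length m (pairwise similarities).
#' @param k Number of latent components, `1 <= k <= min(m - 1, n)` and at
#'   most the rank of the centered predictor matrix.
#' @return Object of class `simpls_model` with elements `k`, `x_weights`
#'   (W*), `x_loadings` (P), `y_loadings` (q), `x_scores` (T), `y_scores`
#'   (U), `beta`, `beta_std` (standardized coefficients), `intercept`,
#'   `x_center`, `y_center`, `fitted`, `residuals`, `feature_names`.
#' @export
fit_simpls <- function(X, y, k = 2L) {
  Xm <- as_X(X)
  y <- as.numeric(y)
  m <- nrow(Xm); n <- ncol(Xm)
  stopifnot(length(y) == m)
  if (any(!is.finite(Xm)) || any(!is.finite(y)))
    stop("X and y must be finite")
  if (k < 1L || k > min(m - 1L, n))
    stop("k must satisfy 1 <= k <= min(m - 1, n) = ", min(m - 1L, n))
  x_center <- colMeans(Xm)
  y_center <- mean(y)
  X0 <- sweep(Xm, 2L, x_center)
  y0 <- y - y_center
  rk <- qr(X0)$rank
  if (k > rk)
    stop("k exceeds the rank of the centered design matrix; attainable maximum is ", rk)
  core <- simpls_core(X0, y0, k)
  beta <- as.numeric(core$R %*% core$q)
  intercept <- y_center - sum(x_center * beta)
  fitted <- as.numeric(Xm %*% beta) + intercept
  x_sd <- apply(Xm, 2L, stats::sd)
  y_sd <- stats::sd(y)
  beta_std <- if (y_sd > 0) beta * x_sd / y_sd else beta * 0
  names(beta) <- names(beta_std) <- colnames(Xm)
  structure(list(k = core$k, x_weights = core$R, x_loadings = core$P,
                 y_loadings = matrix(core$q, nrow = 1L), x_scores = core$T,
                 y_scores = core$U, beta = beta, beta_std = beta_std,
                 intercept = intercept, x_center = x_center,
                 y_center = y_center, fitted = fitted,
                 residuals = y - fitted, feature_names = colnames(Xm)),
            class = "simpls_model")
}

#' @export
print.simpls_model <- function(x, ...) {
  cat(sprintf("<simpls_model: k = %d, %d features>\n", x$k,
              length(x$beta)))
  invisible(x)
}

#' @export
coef.simpls_model <- function(object, standardized = FALSE, ...) {
  if (standardized) object$beta_std else object$beta
}

#' Predict similarities from a fitted SIMPLS model
#'
#' `yhat = (X_new - x_center) %*% beta + y_center`. Predictions are not
#' clipped to `[0, 1]`: the model is linear and clipping would silently
#' change correlation-based performance measures.
#'
#' @param object A `simpls_model`.
#' @param newdata A `design_matrix` or numeric matrix with the model's
#'   feature columns (matched by name when column names are present).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.simpls_model <- function(object, newdata, ...) {
  Xn <- as_X(newdata)
  if (!is.null(colnames(Xn)) && !is.null(object$feature_names)) {
    missing <- setdiff(object$feature_names, colnames(Xn))
    extra <- setdiff(colnames(Xn), object$feature_names)
    if (length(missing) || length(extra))
      stop("feature column mismatch; missing: [",
           paste(missing, collapse = ", "), "], extra: [",
           paste(extra, collapse = ", "), "]")
    Xn <- Xn[, object$feature_names, drop = FALSE]
  } else if (ncol(Xn) != length(object$beta)) {
    stop("newdata has ", ncol(Xn), " columns; model expects ",
         length(object$beta))
  }
  as.numeric(Xn %*% object$beta) + object$intercept
}

#' Select the number of latent components by cross-validation
#'
#' Pairs are randomly assigned to `folds` folds (seeded, balanced); for each
#' candidate `k` the mean squared prediction error over held-out folds is
#' computed, exploiting the nestedness of SIMPLS components (one fit at
#' `k_max` per fold yields all sub-models). Returns the `k` with minimal CV
#' error; ties go to the smallest `k`.
#'
#' @param X A `design_matrix` or matrix.
#' @param y Response vector.
#' @param folds Number of folds (default 8).
#' @param k_max Largest component count considered.
#' @param seed Integer seed for the fold assignment.
#' @return Integer `k`; attribute `"cv_mse"` holds the per-k CV errors.
#' @export
select_k <- function(X, y, folds = 8L, k_max = 10L, seed = 1L) {
  Xm <- as_X(X)
  y <- as.numeric(y)
  m <- nrow(Xm)
  if (k_max < 1L) stop("k_max must be at least 1")
  if (m < folds) stop("need at least as many pairs as folds")
  k_max <- min(k_max, ncol(Xm), m - ceiling(m / folds) - 1L)
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), m)))
  sse <- numeric(k_max)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    X_tr <- Xm[tr, , drop = FALSE]
    y_tr <- y[tr]
    x_center <- colMeans(X_tr)
    y_center <- mean(y_tr)
    X0 <- sweep(X_tr, 2L, x_center)
    kf <- min(k_max, qr(X0)$rank)
    core <- simpls_core(X0, y_tr - y_center, kf)
    X_te0 <- sweep(Xm[!tr, , drop = FALSE], 2L, x_center)
    for (k in seq_len(k_max)) {
      kk <- min(k, core$k)
      beta_k <- if (kk >= 1L)
        core$R[, seq_len(kk), drop = FALSE] %*% core$q[seq_len(kk)]
      else matrix(0, ncol(Xm), 1L)
      pred <- as.numeric(X_te0 %*% beta_k) + y_center
      sse[k] <- sse[k] + sum((y[!tr] - pred)^2)
    }
  }
  cv_mse <- sse / m
  k_best <- which.min(cv_mse)   # which.min returns the first (smallest k) tie
  structure(as.integer(k_best), cv_mse = cv_mse)
}
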
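test_that("SIMPLS collapses to least squares in the degenerate cases", {
  withr::with_seed(1, {
    X <- matrix(rnorm(150), 30, 5, dimnames = list(NULL, paste0("v", 1:5)))
    y <- rnorm(30)
  })
  # full rank, k = rank: identical to OLS via the normal equations
  fit <- fit_simpls(X, y, k = 5)
  beta_ols <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  yhat_ols <- cbind(1, X) %*% beta_ols
  expect_lt(max(abs(fit$fitted - yhat_ols)), 1e-8)

  # one predictor: the simple regression line
  f1 <- fit_simpls(X[, 1, drop = FALSE], y, k = 1)
  l1 <- stats::lm.fit(cbind(1, X[, 1]), y)
  expect_lt(max(abs(f1$fitted - l1$fitted.values)), 1e-10)

  # constant response: zero coefficients, intercept = the constant
  fc <- fit_simpls(X, rep(0.7, 30), k = 2)
  expect_equal(unname(fc$beta), rep(0, 5))
  expect_equal(fc$intercept, 0.7)
})

test_that("SIMPLS scores are orthogonal and covariance captured decays", {
  withr::with_seed(2, {
    X <- matrix(rnorm(40 * 8), 40, 8)
    y <- X %*% rnorm(8) + rnorm(40)
  })
  fit <- fit_simpls(X, y, k = 6)
  gram <- crossprod(fit$x_scores)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  q <- abs(as.numeric(fit$y_loadings))
  expect_true(all(diff(q) <= 1e-8))

  # training R^2 is non-decreasing in k
  r2k <- vapply(1:6, function(k)
    cor(fit_simpls(X, y, k = k)$fitted, as.numeric(y))^2, 0)
  expect_true(all(diff(r2k) >= -1e-10))

  expect_error(fit_simpls(X[, rep(1, 4)], y, k = 3), "rank")
})

test_that("predictions follow the centered affine formula", {
  withr::with_seed(3, {
    X <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- runif(20)
  })
  fit <- fit_simpls(X, y, k = 2)
  expect_equal(cor(predict(fit, X), fit$fitted), 1)

  # all-zero row: y_center + (0 - x_center) . beta
  z <- matrix(0, 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(predict(fit, z),
               fit$y_center + sum((0 - fit$x_center) * fit$beta))

  # duplicated row -> duplicated prediction; affine in row blends
  X2 <- X[c(1, 1, 2), ]
  p <- predict(fit, X2)
  expect_equal(p[1], p[2])
  blend <- 0.3 * X[1, , drop = FALSE] + 0.7 * X[2, , drop = FALSE]
  expect_equal(predict(fit, blend),
               unname(0.3 * p[1] + 0.7 * p[3]))

  bad <- X; colnames(bad) <- c("a", "b", "zz")
  expect_error(predict(fit, bad), "missing: \\[c\\], extra: \\[zz\\]")
})

test_that("cross-validated component selection finds low-rank structure", {
  ks <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      t1 <- rnorm(60); t2 <- rnorm(60)
      X <- outer(t1, rnorm(8)) + outer(t2, rnorm(8)) +
        matrix(rnorm(60 * 8, sd = 0.02), 60, 8)
      y <- t1 + t2 + rnorm(60, sd = 0.02)
      as.integer(select_k(X, y, k_max = 6, seed = s))
    })
  }, 1L)
  expect_gt(sum(ks == 2L), 10L)   # majority of seeds

  # pure noise: small k preferred (overfit guard)
  kn <- vapply(1:20, function(s) {
    withr::with_seed(s + 400, {
      X <- matrix(rnorm(60 * 8), 60, 8)
      as.integer(select_k(X, rnorm(60), k_max = 6, seed = s))
    })
  }, 1L)
  expect_gt(sum(kn <= 2L), 10L)

  # determinism: same seed, same folds, same k
  withr::with_seed(9, {
    X <- matrix(rnorm(200), 50, 4)
    y <- rnorm(50)
  })
  expect_identical(as.integer(select_k(X, y, k_max = 3, seed = 5)),
                   as.integer(select_k(X, y, k_max = 3, seed = 5)))
  expect_error(select_k(X, y, k_max = 0, seed = 1), "k_max")
})
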
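# Build a pair of synthetic datasets (feature tables with tt./mfcc. columns,
# similarities from the sorting simulation under a shared latent model).
make_datasets <- function(seed, noise_sd = 0.15, scramble = FALSE,
                          n_participants = 60) {
  make_one <- function(s) {
    withr::with_seed(s, {
      x <- matrix(runif(16 * 12), 16, 12)
      colnames(x) <- c(sprintf("tt.x%02d", 1:6), sprintf("mfcc.x%02d", 1:6))
      tab <- data.frame(clip_id = sprintf("c%02d", 1:16), x,
                        check.names = FALSE, stringsAsFactors = FALSE)
      md <- data.frame(clip_id = tab$clip_id,
                       genre = rep(c("g1", "g2", "g3", "g4"), each = 4),
                       release_year = sample(1960:2000, 16, replace = TRUE))
      list(tab = tab, md = md)
    })
  }
  latent <- latent_model(c(tt.x01 = 1, tt.x02 = 1, mfcc.x01 = 1))
  out <- list()
  for (i in 1:2) {
    d <- make_one(seed + i)
    ranked <- normalize_features(d$tab, "n4")
    td <- latent_distance_matrix(ranked, latent)
    sim <- if (scramble) {
      m <- random_distance_matrix(16, seed = seed + 50 + i, ids = d$tab$clip_id)
      m <- m / max(m); diag(m) <- 1
      attr(m, "diagonal_excluded") <- TRUE
      m
    } else {
      simulate_sorting_study(td, noise_sd = noise_sd,
                             n_participants = n_participants,
                             seed = seed + 10 + i)$similarity
    }
    out[[c("I", "II")[i]]] <- list(features = d$tab, metadata = d$md,
                                   similarity = sim)
  }
  out
}

test_that("r_squared is the squared Pearson correlation", {
  obs <- withr::with_seed(1, runif(120))
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(3 * obs - 2, obs), 1)        # affine invariance
  pred <- rev(obs)
  direct <- (sum((pred - mean(pred)) * (obs - mean(obs))) /
             sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2)))^2
  expect_equal(r_squared(pred, obs), direct)
  expect_warning(r2 <- r_squared(rep(1, 10), obs[1:10]), "zero variance")
  expect_true(is.na(r2))
})

test_that("correlation significance matches the t-distribution", {
  # exactly zero correlation -> p = 1
  pred <- c(1, -1, 1, -1, 1, -1, 1, -1)
  obs <- c(1, 1, -1, -1, 1, 1, -1, -1)
  ct0 <- correlation_test(pred, obs)
  expect_equal(abs(ct0$r), 0)
  expect_equal(ct0$p, 1)

  # df = m - 2 = 118 for 120 pairs; p agrees with stats::cor.test to 1e-6
  withr::with_seed(2, {
    x <- runif(120)
    y <- 0.5 * x + rnorm(120, sd = 0.3)
  })
  ct <- correlation_test(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(ct$df, 118L)
  expect_equal(ct$p, unname(ref$p.value), tolerance = 1e-6)

  ctp <- correlation_test(x, 2 * x + 1)
  expect_equal(ctp$p, 0)
  expect_true(ctp$significant)
})

test_that("the evaluation grid enumerates every condition", {
  ds <- make_datasets(seed = 100)
  corpus <- random_feature_table(150, 12, seed = 9)
  names(corpus)[-1] <- c(sprintf("tt.x%02d", 1:6), sprintf("mfcc.x%02d", 1:6))
  rep <- cross_evaluate(ds, corpus = corpus, B = 30, seed = 3)
  g <- rep$grid
  expect_equal(nrow(g), 3 * 5 * 2 * 4)   # fsets x norms x sparsity x cells
  expect_setequal(unique(g$model), c("full", "sparse"))
  expect_true(all(g$r2 >= 0 & g$r2 <= 1, na.rm = TRUE))

  # a train = test cell reproduces the training fit
  tab_n2 <- normalize_features(ds$I$features, "n2")
  dm <- pairwise_distances(tab_n2)
  y <- response_vector(ds$I$similarity)
  fit <- fit_simpls(dm, y, k = 2)
  cell <- g[g$train_set == "I" & g$test_set == "I" & g$feature_set == "tt+mfcc" &
            g$normalization == "n2" & g$model == "full", ]
  expect_equal(cell$r2, cor(fit$fitted, y)^2)
})

test_that("shared-latent datasets generalize better than scrambled ones", {
  ds_sig <- make_datasets(seed = 200, noise_sd = 0.1)
  ds_noise <- make_datasets(seed = 200, scramble = TRUE)
  run <- function(ds) {
    rep <- cross_evaluate(ds, feature_sets = "tt+mfcc", normalizations = "n4",
                          B = 100, seed = 4)
    g <- rep$grid
    mean(g$r2[g$train_set != g$test_set & g$model == "sparse"], na.rm = TRUE)
  }
  expect_gt(run(ds_sig), run(ds_noise))
})

test_that("meta predictors join the grid when requested", {
  ds <- make_datasets(seed = 300)
  rep <- cross_evaluate(ds, feature_sets = "tt", normalizations = "n2",
                        include_meta = TRUE, B = 30, seed = 5)
  expect_setequal(unique(rep$grid$model),
                  c("full", "sparse", "full+meta", "sparse+meta", "meta"))
  meta_cells <- rep$grid[rep$grid$model == "meta", ]
  expect_true(all(meta_cells$n_features == 2L))

  bad <- ds
  names(bad$II$features)[2] <- "tt.other"
  expect_error(cross_evaluate(bad, feature_sets = "tt", normalizations = "n2",
                              B = 10), "mismatch")
})

test_that("recovery metrics score selections against the generating support", {
  truth <- c("a", "b", "c")
  perfect <- recovery_report(truth, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  miss <- recovery_report(c("x", "y"), truth)
  expect_equal(miss$recall, 0)
  expect_equal(miss$precision, 0)

  part <- recovery_report(c("a", "x"), truth)
  expect_equal(part$precision, 0.5)
  expect_equal(part$recall, 1 / 3)
  expect_true(is.na(recovery_report(character(), truth)$precision))

  lm_ <- latent_model(c(a = 1, b = 2, c = 0))
  expect_equal(recovery_report(c("a", "b"), lm_)$recall, 1)
})
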
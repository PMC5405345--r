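#' Squared Pearson correlation between predictions and observations
#'
#' The performance measure used throughout the evaluation grid: the square of
#' the Pearson correlation coefficient, i.e. the proportion of variance
#' shared between model predictions and observations. This is deliberately
#' not `1 - SSE/SST`; a linear rescaling of the predictions does not change
#' it.
#'
#' @param pred,obs Numeric vectors of equal length (at least 3).
#' @return Scalar in `[0, 1]`, or `NA` (with a warning) if either input has
#'   zero variance.
#' @export
r_squared <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 3L)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    warning("undefined R^2: zero variance in predictions or observations")
    return(NA_real_)
  }
  stats::cor(pred, obs)^2
}

#' Significance of the prediction-observation correlation
#'
#' Two-sided t-test on the Pearson correlation with `df = m - 2` (df = 118
#' for the 120 clip pairs): `t = r * sqrt(df / (1 - r^2))`.
#'
#' @param pred,obs Numeric vectors of equal length (at least 4).
#' @param alpha Significance level (default 0.01).
#' @return List with `r`, `statistic`, `df`, `p`, `significant`.
#' @export
correlation_test <- function(pred, obs, alpha = 0.01) {
  stopifnot(length(pred) == length(obs), length(obs) >= 4L)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    warning("undefined correlation: zero variance")
    return(list(r = NA_real_, statistic = NA_real_,
                df = length(obs) - 2L, p = NA_real_, significant = FALSE))
  }
  r <- stats::cor(pred, obs)
  df <- length(obs) - 2L
  if (abs(r) >= 1) {
    p <- 0
    t <- Inf * sign(r)
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(r = r, statistic = t, df = df, p = p, significant = p < alpha)
}

fset_columns <- function(feature_names, fset) {
  pref <- switch(fset,
                 "tt" = "^tt\\.",
                 "mfcc" = "^mfcc\\.",
                 "tt+mfcc" = "^(tt|mfcc)\\.",
                 stop("unknown feature set: ", fset))
  cols <- grep(pref, feature_names, value = TRUE)
  if (!length(cols)) stop("no columns found for feature set ", fset)
  cols
}

subset_design <- function(dm, cols) {
  structure(list(X = dm$X[, cols, drop = FALSE], pair_index = dm$pair_index,
                 feature_names = cols, clip_ids = dm$clip_ids),
            class = "design_matrix")
}

augment_design <- function(dm, meta) {
  stopifnot(nrow(meta) == nrow(dm$X))
  X <- cbind(dm$X, meta)
  structure(list(X = X, pair_index = dm$pair_index,
                 feature_names = colnames(X), clip_ids = dm$clip_ids),
            class = "design_matrix")
}

#' Train/test generalization grid
#'
#' Evaluates every combination of feature set, normalization scheme, model
#' sparsity and train/test dataset pairing. For each training condition a
#' SIMPLS model (and, if requested, its bootstrap-selected sparse version) is
#' fit on the training set's pairwise distances and evaluated on both
#' datasets. The test design matrix always uses the test set's own
#' normalization (for the test-rank scheme n4 this means ranks are computed
#' within the test set, mirroring how each 16-clip sample defines its own
#' context); only the model's centers and coefficients come from training.
#'
#' With 2 datasets, 3 feature sets, 5 normalizations and full+sparse models
#' the grid has 3 x 5 x 2 x 4 = 120 cells. `include_meta = TRUE` adds
#' `full+meta`, `sparse+meta` (genre/date columns participate in bootstrap
#' selection like any predictor) and a meta-only model.
#'
#' @param datasets Named list of 2 datasets, each a list with `features`
#'   (feature table), `metadata`, `similarity` (symmetric matrix).
#' @param feature_sets Subset of `c("tt", "mfcc", "tt+mfcc")`.
#' @param normalizations Subset of `c("n1", ..., "n5")`.
#' @param corpus Reference feature table, required when `"n5"` is evaluated.
#' @param sparse Evaluate sparse models too (default TRUE).
#' @param include_meta Add genre/release-date predictor variants.
#' @param B,n_drop,k Bootstrap and model parameters (defaults 1000, 4, 2).
#' @param alpha Significance level for the correlation test (default 0.01).
#' @param seed Integer seed (bootstrap fold of every condition derives from
#'   it deterministically).
#' @return Object of class `eval_report`: list with `grid` (data.frame, one
#'   row per cell: train_set, test_set, feature_set, normalization, model,
#'   n_features, r2, p, significant, selected) and `selected` (named list of
#'   selected feature sets per sparse training condition).
#' @export
cross_evaluate <- function(datasets,
                           feature_sets = c("tt", "mfcc", "tt+mfcc"),
                           normalizations = c("n1", "n2", "n3", "n4", "n5"),
                           corpus = NULL, sparse = TRUE, include_meta = FALSE,
                           B = 1000L, n_drop = 4L, k = 2L, alpha = 0.01,
                           seed = 1L) {
  stopifnot(length(datasets) == 2L, !is.null(names(datasets)))
  if ("n5" %in% normalizations && is.null(corpus))
    stop("normalization n5 requires a corpus feature table")
  set_names <- names(datasets)

  # normalized design matrices and responses per (dataset, normalization)
  dms <- list(); ys <- list(); metas <- list()
  for (s in set_names) {
    d <- datasets[[s]]
    fn_train <- setdiff(names(d$features), "clip_id")
    for (s2 in set_names) {
      fn2 <- setdiff(names(datasets[[s2]]$features), "clip_id")
      if (!identical(sort(fn_train), sort(fn2)))
        stop("feature-name mismatch between datasets ", s, " and ", s2)
    }
    ys[[s]] <- response_vector(d$similarity)
    metas[[s]] <- meta_columns(d$metadata,
                               clip_ids = rownames(as.matrix(d$similarity)))
    for (nm in normalizations) {
      tab <- normalize_features(d$features, nm, corpus = corpus)
      tab <- tab[match(rownames(as.matrix(d$similarity)), tab$clip_id), ]
      dms[[paste(s, nm, sep = ".")]] <- pairwise_distances(tab)
    }
  }

  models <- "full"
  if (sparse) models <- c(models, "sparse")
  if (include_meta) models <- c(models, "full+meta",
                                if (sparse) "sparse+meta", "meta")

  n_cond <- length(set_names) * length(feature_sets) * length(normalizations) *
    length(models)
  cond_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_cond))
  rows <- list(); selected_sets <- list()
  ci <- 0L
  for (train in set_names) {
    for (fset in feature_sets) {
      for (nm in normalizations) {
        dm_tr_full <- dms[[paste(train, nm, sep = ".")]]
        cols <- fset_columns(dm_tr_full$feature_names, fset)
        dm_tr <- subset_design(dm_tr_full, cols)
        y_tr <- ys[[train]]
        for (model in models) {
          ci <- ci + 1L
          cond <- sprintf("%s.%s.%s.%s", train, fset, nm, model)
          fit <- NULL; sel <- NULL
          base_tr <- switch(model,
            "full" = , "sparse" = dm_tr,
            "full+meta" = , "sparse+meta" = augment_design(dm_tr, metas[[train]]),
            "meta" = {
              m <- metas[[train]]
              structure(list(X = m, pair_index = dm_tr$pair_index,
                             feature_names = colnames(m),
                             clip_ids = dm_tr$clip_ids),
                        class = "design_matrix")
            })
          if (model %in% c("sparse", "sparse+meta")) {
            bs <- bootstrap_coefficients(base_tr, y_tr, B = B, n_drop = n_drop,
                                         k = k, seed = cond_seeds[ci])
            sel <- bs$selected
            selected_sets[[cond]] <- sel
            fit <- if (length(sel)) fit_sparse(base_tr, y_tr, sel, k = k) else NULL
          } else {
            kk <- min(k, ncol(base_tr$X))
            fit <- fit_simpls(base_tr, y_tr, k = kk)
          }
          for (test in set_names) {
            dm_te_full <- dms[[paste(test, nm, sep = ".")]]
            base_te <- switch(model,
              "full" = , "sparse" = subset_design(dm_te_full, cols),
              "full+meta" = , "sparse+meta" =
                augment_design(subset_design(dm_te_full, cols), metas[[test]]),
              "meta" = {
                m <- metas[[test]]
                structure(list(X = m, pair_index = dm_te_full$pair_index,
                               feature_names = colnames(m),
                               clip_ids = dm_te_full$clip_ids),
                          class = "design_matrix")
              })
            if (is.null(fit)) {
              r2 <- NA_real_; p <- NA_real_; sig <- NA
            } else {
              Xte <- base_te$X[, fit$feature_names, drop = FALSE]
              pred <- predict(fit, Xte)
              ct <- suppressWarnings(
                correlation_test(pred, ys[[test]], alpha = alpha))
              r2 <- if (is.na(ct$r)) NA_real_ else ct$r^2
              p <- ct$p; sig <- ct$significant
            }
            rows[[length(rows) + 1L]] <- data.frame(
              train_set = train, test_set = test, feature_set = fset,
              normalization = nm, model = model,
              n_features = if (is.null(fit)) 0L else length(fit$beta),
              r2 = r2, p = p, significant = sig,
              selected = if (is.null(sel)) NA_character_ else
                paste(sel, collapse = ";"),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  structure(list(grid = do.call(rbind, rows), selected = selected_sets,
                 alpha = alpha),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<eval_report: %d cells, %d significant at alpha = %g>\n",
              nrow(g), sum(g$significant, na.rm = TRUE), x$alpha))
  invisible(x)
}

#' Summarize training fit vs generalization per condition
#'
#' @param report An `eval_report`.
#' @return data.frame with one row per (feature_set, normalization, model):
#'   `mean_train_r2` (train = test cells) and `mean_generalization_r2`
#'   (train != test cells), NA cells excluded.
#' @export
generalization_summary <- function(report) {
  g <- report$grid
  key <- interaction(g$feature_set, g$normalization, g$model, drop = TRUE)
  out <- do.call(rbind, lapply(split(g, key), function(d) {
    data.frame(feature_set = d$feature_set[1L],
               normalization = d$normalization[1L], model = d$model[1L],
               mean_train_r2 = mean(d$r2[d$train_set == d$test_set], na.rm = TRUE),
               mean_generalization_r2 =
                 mean(d$r2[d$train_set != d$test_set], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Plot mean training fit against mean generalization
#'
#' One point per (feature set, normalization, model) condition: x = mean R^2
#' on unseen sets, y = mean R^2 on the training sets. Sparse models are drawn
#' as triangles, full models as circles.
#'
#' @param report An `eval_report`.
#' @param ... Passed to [graphics::plot()].
#' @return The summary data.frame, invisibly.
#' @export
plot_generalization <- function(report, ...) {
  s <- generalization_summary(report)
  pch <- ifelse(grepl("sparse", s$model), 17, 1)
  graphics::plot(s$mean_generalization_r2, s$mean_train_r2, pch = pch,
                 xlab = expression(mean ~ generalization ~ R^2),
                 ylab = expression(mean ~ training ~ R^2), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::text(s$mean_generalization_r2, s$mean_train_r2,
                 paste(s$feature_set, s$normalization), cex = 0.6, pos = 3)
  invisible(s)
}

#' Precision/recall of selected features against a known support
#'
#' Scores a sparse selection against the generating features of a synthetic
#' run (the support of the latent model's true weights).
#'
#' @param selected Character vector of selected feature names.
#' @param true_features Character vector of generating feature names, or a
#'   `latent_model` (support of its positive weights).
#' @return List with `precision` (NA when nothing selected), `recall`,
#'   `n_selected`, `n_true`, `intersection`.
#' @export
recovery_report <- function(selected, true_features) {
  if (inherits(true_features, "latent_model")) {
    w <- true_features$true_weights
    true_features <- names(w)[w > 0]
  }
  inter <- intersect(selected, true_features)
  list(precision = if (length(selected)) length(inter) / length(selected)
                   else NA_real_,
       recall = length(inter) / length(true_features),
       n_selected = length(selected), n_true = length(true_features),
       intersection = inter)
}
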
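#' One parameter-recovery run of the sparse pipeline
#'
#' The recovery harness checks that the full downstream pipeline (distances ->
#' SIMPLS -> clip-level bootstrap -> percentile-CI selection) can find a known
#' generating structure. A synthetic feature table (`n_clips` x `n_features`,
#' iid uniform) is drawn; ground-truth dissimilarity is the equally weighted
#' city-block distance over `n_true` designated features; `n_participants`
#' noisy constrained sorts are simulated and aggregated; the design matrix is
#' built from the rank-normalized (n4) features and the bootstrap selection is
#' scored against the generating support.
#'
#' @param seed Integer seed for the whole run.
#' @param n_clips Clips (default 16, sorted into 4 groups of 4).
#' @param n_features Feature columns (default 24).
#' @param n_true Number of generating features (default 3; the first
#'   `n_true` columns).
#' @param n_participants Simulated participants (default 200).
#' @param noise_sd Perceptual noise SD (default 0.3).
#' @param B,n_drop,k Bootstrap parameters (defaults 1000, 4, 2).
#' @param normalization Scheme for the design matrix (default `"n4"`).
#' @return List: `selected`, `true_features`, `recovery` (see
#'   [recovery_report()]), `bootstrap`, `similarity`, `features`.
#' @export
recovery_run <- function(seed = 1L, n_clips = 16L, n_features = 24L,
                         n_true = 3L, n_participants = 200L, noise_sd = 0.3,
                         B = 1000L, n_drop = 4L, k = 2L,
                         normalization = "n4") {
  stopifnot(n_true >= 1L, n_true <= n_features)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  feature_names <- sprintf("f%02d", seq_len(n_features))
  true_features <- feature_names[seq_len(n_true)]
  features <- withr::with_seed(seeds[1L], {
    x <- matrix(stats::runif(n_clips * n_features), n_clips, n_features,
                dimnames = list(NULL, feature_names))
    data.frame(clip_id = sprintf("c%02d", seq_len(n_clips)), x,
               stringsAsFactors = FALSE)
  })
  normed <- normalize_features(features, normalization)
  w <- stats::setNames(rep(1, n_true), true_features)
  true_d <- latent_distance_matrix(normed, latent_model(w))
  study <- simulate_sorting_study(true_d, noise_sd = noise_sd,
                                  n_participants = n_participants,
                                  seed = seeds[2L])
  y <- response_vector(study$similarity)
  dm <- pairwise_distances(normed)
  bs <- bootstrap_coefficients(dm, y, B = B, n_drop = n_drop, k = k,
                               seed = seeds[3L])
  list(selected = bs$selected, true_features = true_features,
       recovery = recovery_report(bs$selected, true_features),
       bootstrap = bs, similarity = study$similarity, features = features)
}

#' One null-calibration run of the bootstrap selector
#'
#' Under the null of no association (`beta = 0`: the response is pure noise,
#' independent of every predictor), a 95% percentile interval should exclude
#' zero for roughly 5% of features. This helper performs one such run and
#' reports which features were (spuriously) selected.
#'
#' @param seed Integer seed.
#' @param n_clips Clips (default 16).
#' @param n_features Feature columns (default 8).
#' @param B,n_drop,k Bootstrap parameters (defaults 1000, 4, 2).
#' @return Named logical vector: selection indicator per feature.
#' @export
null_selection_run <- function(seed = 1L, n_clips = 16L, n_features = 8L,
                               B = 1000L, n_drop = 4L, k = 2L) {
  feature_names <- sprintf("f%02d", seq_len(n_features))
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  features <- withr::with_seed(seeds[1L], {
    x <- matrix(stats::runif(n_clips * n_features), n_clips, n_features,
                dimnames = list(NULL, feature_names))
    data.frame(clip_id = sprintf("c%02d", seq_len(n_clips)), x,
               stringsAsFactors = FALSE)
  })
  dm <- pairwise_distances(features)
  y <- withr::with_seed(seeds[2L], stats::rnorm(nrow(dm$X)))
  bs <- bootstrap_coefficients(dm, y, B = B, n_drop = n_drop, k = k,
                               seed = seed)
  stats::setNames(bs$ci$selected, bs$ci$feature)
}
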
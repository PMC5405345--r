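#' Default end-to-end pipeline configuration
#'
#' Bundles every tunable of the simulate -> extract -> normalize -> design ->
#' fit/select -> evaluate pipeline, with one explicit seed per stochastic
#' stage (all derived deterministically from `seed`). Defaults mirror the
#' study design: two 16-clip stimulus sets of 400 and 800 ms, a
#' 4 x 110 x 10 = 4,400-clip reference corpus for corpus ranking, bootstrap
#' selection with B = 1000 replicates dropping 4 clips drawn with
#' replacement, k = 2 latent components, and significance at alpha = 0.01.
#'
#' @param seed Master seed.
#' @param participants Simulated participants per stimulus set (default 500).
#' @param noise_sd Perceptual noise SD of the sorting model (default 0.3, on
#'   the scale of rank-normalized feature distances).
#' @param durations Clip durations in seconds for the two sets.
#' @param latent_weights Named true feature weights of the generating latent
#'   model (defaults: three timbre features with unit weight).
#' @param genre_bonus Additive cross-genre distance increment (default 0.25),
#'   emulating genre information beyond the acoustic features.
#' @param feature_sets,normalizations Grid axes for [cross_evaluate()].
#' @param corpus_songs_per_genre,corpus_clips_per_song Corpus recipe
#'   (defaults 110 and 10; used only when `"n5"` is evaluated).
#' @param B,n_drop,k,alpha Bootstrap/model/test parameters.
#' @param include_meta Evaluate genre/release-date predictor variants.
#' @param write_wav Also write one WAV file per stimulus clip.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            participants = 500L,
                            noise_sd = 0.3,
                            durations = c(I = 0.4, II = 0.8),
                            latent_weights = c(tt.centroid.med = 1,
                                               tt.flatness.med = 1,
                                               tt.modfreq = 1),
                            genre_bonus = 0.25,
                            feature_sets = c("tt", "mfcc", "tt+mfcc"),
                            normalizations = c("n1", "n2", "n3", "n4", "n5"),
                            corpus_songs_per_genre = 110L,
                            corpus_clips_per_song = 10L,
                            B = 1000L, n_drop = 4L, k = 2L, alpha = 0.01,
                            include_meta = TRUE, write_wav = FALSE) {
  stage_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 4L))
  structure(list(
    seed = seed,
    seeds = list(audio = stage_seeds[1L], participants = stage_seeds[2L],
                 bootstrap = stage_seeds[3L], corpus = stage_seeds[4L]),
    participants = participants, noise_sd = noise_sd, durations = durations,
    latent_weights = latent_weights, genre_bonus = genre_bonus,
    feature_sets = feature_sets, normalizations = normalizations,
    corpus_songs_per_genre = corpus_songs_per_genre,
    corpus_clips_per_song = corpus_clips_per_song,
    B = B, n_drop = n_drop, k = k, alpha = alpha,
    include_meta = include_meta, write_wav = write_wav),
    class = "pipeline_config")
}

write_similarity_csv <- function(sim, path) {
  df <- data.frame(clip_id = rownames(sim), as.data.frame(sim),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

write_partitions_csv <- function(partitions, path) {
  rows <- lapply(seq_along(partitions), function(p) {
    g <- partitions[[p]]
    data.frame(participant_id = p, clip_id = names(g),
               group_index = as.integer(g), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Serialize a SIMPLS model to JSON
#'
#' @param model A `simpls_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    k = model$k, intercept = model$intercept,
    y_center = model$y_center, x_center = as.list(model$x_center),
    beta = as.list(model$beta), beta_std = as.list(model$beta_std),
    x_loadings = model$x_loadings, y_loadings = model$y_loadings,
    feature_names = model$feature_names),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes every stage end to end: synthesize the two stimulus sets, extract
#' tt/mfcc features, build ground-truth distances from the latent model on
#' test-rank-normalized features, simulate the constrained sorting of
#' `participants` participants per set, aggregate similarities, synthesize
#' the reference corpus (when scheme n5 is evaluated), and run the full
#' train/test evaluation grid. All tables are written as CSV to `out_dir`
#' together with a JSON manifest of the configuration and seeds; re-running
#' with the same configuration reproduces the outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `datasets`, `corpus`, `report`, `latent`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("timbresim_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  latent <- latent_model(config$latent_weights,
                         genre_bonus = config$genre_bonus,
                         noise_sd = config$noise_sd)
  datasets <- list()
  for (idx in seq_along(config$durations)) {
    sname <- names(config$durations)[idx]
    if (is.null(sname) || sname == "") sname <- as.character(idx)
    stim <- stage("simulate", generate_stimulus_set(
      duration_s = config$durations[[idx]],
      seed = config$seeds$audio + idx - 1L))
    feats <- stage("extract", build_feature_table(stim$clips))
    ranked <- stage("normalize", normalize_features(feats, "n4"))
    true_d <- stage("design", latent_distance_matrix(ranked, latent,
                                                     metadata = stim$metadata))
    study <- stage("simulate", simulate_sorting_study(
      true_d, noise_sd = config$noise_sd,
      n_participants = config$participants,
      seed = config$seeds$participants + idx - 1L))
    datasets[[sname]] <- list(features = feats, metadata = stim$metadata,
                              similarity = study$similarity,
                              partitions = study$partitions, stimulus = stim)
    utils::write.csv(stim$metadata,
                     file.path(out_dir, paste0("metadata_", sname, ".csv")),
                     row.names = FALSE)
    utils::write.csv(feats,
                     file.path(out_dir, paste0("features_", sname, ".csv")),
                     row.names = FALSE)
    write_similarity_csv(study$similarity,
                         file.path(out_dir, paste0("similarity_", sname, ".csv")))
    write_partitions_csv(study$partitions,
                         file.path(out_dir, paste0("partitions_", sname, ".csv")))
    if (isTRUE(config$write_wav)) {
      wav_dir <- file.path(out_dir, paste0("wav_", sname))
      dir.create(wav_dir, showWarnings = FALSE)
      for (cl in stim$clips)
        write_wav(cl$samples, file.path(wav_dir, paste0(cl$clip_id, ".wav")))
    }
  }
  corpus <- NULL
  if ("n5" %in% config$normalizations) {
    corpus <- stage("corpus", generate_corpus(
      songs_per_genre = config$corpus_songs_per_genre,
      clips_per_song = config$corpus_clips_per_song,
      seed = config$seeds$corpus))
    utils::write.csv(corpus, file.path(out_dir, "corpus_features.csv"),
                     row.names = FALSE)
  }
  report <- stage("evaluate", cross_evaluate(
    datasets, feature_sets = config$feature_sets,
    normalizations = config$normalizations, corpus = corpus,
    sparse = TRUE, include_meta = config$include_meta,
    B = config$B, n_drop = config$n_drop, k = config$k,
    alpha = config$alpha, seed = config$seeds$bootstrap))
  utils::write.csv(report$grid, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$selected,
                       file.path(out_dir, "selected_features.json"),
                       auto_unbox = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("timbresim")),
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(datasets = datasets, corpus = corpus, report = report,
                 latent = latent, out_dir = out_dir))
}
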
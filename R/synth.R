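#' @importFrom stats rnorm runif median quantile sd
#' @importFrom utils head
NULL

NYQUIST_HZ <- 22050
CLIP_RATE_HZ <- 44100L
FADE_S <- 0.02

#' Specification of one synthetic music clip
#'
#' A clip is modeled as a sum of sinusoidal partials plus band-limited noise,
#' amplitude-modulated at a given rate and depth, peak-normalized and faded.
#' This parametric family stands in for short excerpts of commercial
#' recordings: the partial structure controls the spectral envelope (centroid,
#' flatness), the noise band its noisiness, and the modulation its
#' spectrotemporal variability.
#'
#' @param clip_id Character id.
#' @param genre Genre label.
#' @param release_year Integer year.
#' @param duration_s Clip duration in seconds (study values: 0.4 or 0.8).
#' @param partial_freqs Partial frequencies in Hz (all below 22050).
#' @param partial_amps Linear partial amplitudes (same length).
#' @param noise_band Length-2 numeric `(low, high)` Hz, or `NULL` for no noise.
#' @param noise_gain Linear RMS gain of the band-limited noise component.
#' @param am_rate Amplitude-modulation rate in Hz (0 = none).
#' @param am_depth Modulation depth in `[0, 1]`.
#' @return An object of class `clip_spec`.
#' @export
clip_spec <- function(clip_id, genre = NA_character_, release_year = NA_integer_,
                      duration_s = 0.8,
                      partial_freqs = numeric(), partial_amps = numeric(),
                      noise_band = NULL, noise_gain = 0,
                      am_rate = 0, am_depth = 0) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (length(partial_freqs) != length(partial_amps))
    stop("partial_freqs and partial_amps must have equal length")
  if (any(partial_freqs >= NYQUIST_HZ))
    stop("partial frequency out of range: all partials must lie below the Nyquist frequency (",
         NYQUIST_HZ, " Hz)")
  if (am_depth < 0 || am_depth > 1) stop("am_depth must lie in [0, 1]")
  if (!is.null(noise_band)) {
    stopifnot(length(noise_band) == 2L, noise_band[1] < noise_band[2])
  }
  structure(list(clip_id = as.character(clip_id), genre = genre,
                 release_year = as.integer(release_year),
                 duration_s = duration_s,
                 partial_freqs = as.numeric(partial_freqs),
                 partial_amps = as.numeric(partial_amps),
                 noise_band = noise_band, noise_gain = noise_gain,
                 am_rate = am_rate, am_depth = am_depth),
            class = "clip_spec")
}

raised_cosine_fades <- function(n, rate_hz, fade_s = FADE_S) {
  env <- rep(1, n)
  nf <- min(round(fade_s * rate_hz), floor(n / 2))
  if (nf > 0) {
    u <- seq_len(nf) / nf
    ramp <- 0.5 * (1 - cos(pi * u))
    env[seq_len(nf)] <- ramp
    env[n + 1L - seq_len(nf)] <- ramp
  }
  env
}

band_limited_noise <- function(n, rate_hz, band) {
  z <- stats::rnorm(n)
  spec <- stats::fft(z)
  freq <- (seq_len(n) - 1L) / n * rate_hz
  freq <- pmin(freq, rate_hz - freq)   # fold to [0, Nyquist]
  keep <- freq >= band[1] & freq <= band[2]
  spec[!keep] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

#' Synthesize an audio clip from a clip specification
#'
#' Deterministic given `(spec, seed)`: partials are summed, band-limited
#' Gaussian noise added (RMS scaled to `noise_gain`), the mixture is
#' amplitude-modulated (`env = (1 - depth) + depth * (1 + sin(2 pi r t)) / 2`),
#' peak-normalized to 0.9 and given 20 ms raised-cosine fades at both ends.
#'
#' @param spec A [clip_spec()].
#' @param seed Integer seed for the noise component.
#' @param rate_hz Sampling rate (default 44100 Hz).
#' @return An object of class `audio_clip`: list with `samples`, `rate_hz`,
#'   `clip_id`, `duration_s`, `fade_s`.
#' @export
generate_clip <- function(spec, seed = 1L, rate_hz = CLIP_RATE_HZ) {
  stopifnot(inherits(spec, "clip_spec"))
  if (any(spec$partial_freqs >= rate_hz / 2))
    stop("partial frequency out of range: all partials must lie below the Nyquist frequency (",
         rate_hz / 2, " Hz)")
  n <- round(spec$duration_s * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  x <- numeric(n)
  for (i in seq_along(spec$partial_freqs)) {
    x <- x + spec$partial_amps[i] * sin(2 * pi * spec$partial_freqs[i] * t)
  }
  if (!is.null(spec$noise_band) && spec$noise_gain > 0) {
    x <- x + spec$noise_gain *
      withr::with_seed(seed, band_limited_noise(n, rate_hz, spec$noise_band))
  }
  if (spec$am_rate > 0 && spec$am_depth > 0) {
    x <- x * ((1 - spec$am_depth) + spec$am_depth * 0.5 * (1 + sin(2 * pi * spec$am_rate * t)))
  }
  peak <- max(abs(x))
  if (peak > 0) x <- x * (0.9 / peak)
  x <- x * raised_cosine_fades(n, rate_hz)
  structure(list(samples = x, rate_hz = rate_hz, clip_id = spec$clip_id,
                 duration_s = spec$duration_s, fade_s = FADE_S),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip %s: %.3f s @ %d Hz, %d samples>\n",
              x$clip_id, x$duration_s, x$rate_hz, length(x$samples)))
  invisible(x)
}

#' Default genre templates for synthetic stimulus sets
#'
#' Four parametric genre templates (jazz, rock, pop, hiphop) whose parameter
#' ranges separate the genres on spectral centroid, flatness/noisiness and
#' modulation rate, and whose release-year bands follow the genre-decade
#' coupling of the study design (jazz 1960-70s, rock 1970-80s, pop and hiphop
#' 1990-2000).
#'
#' Each template lists ranges from which per-clip parameters are jittered:
#' `fundamental_hz`, `n_partials`, `tilt` (amplitude of partial k is
#' `k^-tilt`), `noise_band`, `noise_gain`, `am_rate`, `am_depth`, `years`.
#'
#' @return Named list of 4 genre templates.
#' @export
genre_templates <- function() {
  list(
    jazz = list(fundamental_hz = c(196, 262), n_partials = 8L, tilt = 1.8,
                noise_band = c(2000, 6000), noise_gain = c(0.02, 0.08),
                am_rate = c(1.5, 3), am_depth = c(0.1, 0.3),
                years = c(1960L, 1979L)),
    rock = list(fundamental_hz = c(98, 131), n_partials = 14L, tilt = 1.0,
                noise_band = c(1000, 9000), noise_gain = c(0.2, 0.4),
                am_rate = c(3.5, 5.5), am_depth = c(0.3, 0.5),
                years = c(1970L, 1989L)),
    pop = list(fundamental_hz = c(392, 523), n_partials = 10L, tilt = 0.7,
               noise_band = c(4000, 12000), noise_gain = c(0.1, 0.2),
               am_rate = c(5.5, 7.5), am_depth = c(0.2, 0.4),
               years = c(1990L, 2000L)),
    hiphop = list(fundamental_hz = c(55, 82), n_partials = 6L, tilt = 1.4,
                  noise_band = c(500, 11000), noise_gain = c(0.35, 0.6),
                  am_rate = c(7.5, 9.5), am_depth = c(0.5, 0.8),
                  years = c(1990L, 2000L))
  )
}

draw_spec_from_template <- function(clip_id, genre, tpl, duration_s) {
  f0 <- stats::runif(1, tpl$fundamental_hz[1], tpl$fundamental_hz[2])
  k <- seq_len(tpl$n_partials)
  freqs <- f0 * k * stats::runif(tpl$n_partials, 0.999, 1.001)
  freqs <- freqs[freqs < NYQUIST_HZ * 0.95]
  amps <- (seq_along(freqs))^(-tpl$tilt) * stats::runif(length(freqs), 0.8, 1.2)
  clip_spec(
    clip_id = clip_id, genre = genre,
    release_year = as.integer(round(stats::runif(1, tpl$years[1], tpl$years[2]))),
    duration_s = duration_s,
    partial_freqs = freqs, partial_amps = amps,
    noise_band = tpl$noise_band,
    noise_gain = stats::runif(1, tpl$noise_gain[1], tpl$noise_gain[2]),
    am_rate = stats::runif(1, tpl$am_rate[1], tpl$am_rate[2]),
    am_depth = stats::runif(1, tpl$am_depth[1], tpl$am_depth[2])
  )
}

#' Generate a 16-clip stimulus set (4 genres x 4 clips)
#'
#' Draws 4 clips per genre from the genre templates with within-genre
#' parameter jitter, mirroring the study design of 16 short excerpts from four
#' genres with genre-specific release decades.
#'
#' @param duration_s Clip duration in seconds (0.4 or 0.8 in the study).
#' @param templates Named list of exactly 4 genre templates
#'   (see [genre_templates()]).
#' @param clips_per_genre Clips drawn per genre (default 4).
#' @param seed Integer seed; the whole set is deterministic given the seed.
#' @return An object of class `stimulus_set`: list with `clips` (named list of
#'   `audio_clip`) and `metadata` (data.frame: clip_id, genre, release_year,
#'   duration_s).
#' @export
generate_stimulus_set <- function(duration_s = 0.4, templates = genre_templates(),
                                  clips_per_genre = 4L, seed = 1L) {
  if (length(templates) != 4L)
    stop("configuration error: exactly 4 genre templates are required, got ",
         length(templates))
  if (is.null(names(templates)) || anyNA(names(templates)))
    stop("configuration error: genre templates must be named")
  out <- withr::with_seed(seed, {
    specs <- list()
    for (g in names(templates)) {
      for (i in seq_len(clips_per_genre)) {
        id <- sprintf("%s_%02d", g, i)
        specs[[id]] <- draw_spec_from_template(id, g, templates[[g]], duration_s)
      }
    }
    clip_seeds <- sample.int(.Machine$integer.max - 1L, length(specs))
    list(specs = specs, clip_seeds = clip_seeds)
  })
  clips <- Map(generate_clip, out$specs, out$clip_seeds)
  metadata <- data.frame(
    clip_id = vapply(out$specs, `[[`, "", "clip_id"),
    genre = vapply(out$specs, `[[`, "", "genre"),
    release_year = vapply(out$specs, `[[`, 1L, "release_year"),
    duration_s = duration_s,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(clips = clips, metadata = metadata, seed = seed),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set: %d clips, %.1f ms, genres: %s>\n",
              length(x$clips), 1000 * x$metadata$duration_s[1],
              paste(unique(x$metadata$genre), collapse = ", ")))
  invisible(x)
}

#' Clip specifications for the reference corpus
#'
#' Builds the clip plan for a rank-normalization reference corpus: for each of
#' the 4 genres, `songs_per_genre` synthetic "songs" (a song-level draw from
#' the genre template) each contributing `clips_per_song` clips (clip-level
#' jitter around the song's parameters). Defaults give
#' 4 x 110 x 10 = 4,400 clips of 800 ms.
#'
#' @param templates Named list of 4 genre templates.
#' @param songs_per_genre Songs per genre (default 110).
#' @param clips_per_song Clips per song (default 10).
#' @param duration_s Clip duration (default 0.8 s).
#' @param seed Integer seed.
#' @return List with `specs` (list of `clip_spec`) and `clip_seeds`.
#' @export
corpus_clip_specs <- function(templates = genre_templates(),
                              songs_per_genre = 110L, clips_per_song = 10L,
                              duration_s = 0.8, seed = 1L) {
  withr::with_seed(seed, {
    specs <- vector("list", length(templates) * songs_per_genre * clips_per_song)
    idx <- 0L
    for (g in names(templates)) {
      tpl <- templates[[g]]
      for (s in seq_len(songs_per_genre)) {
        # song identity: a narrowed template around one draw
        f0 <- stats::runif(1, tpl$fundamental_hz[1], tpl$fundamental_hz[2])
        song_tpl <- tpl
        song_tpl$fundamental_hz <- f0 * c(0.99, 1.01)
        song_tpl$years <- rep(as.integer(round(stats::runif(1, tpl$years[1], tpl$years[2]))), 2L)
        for (cl in seq_len(clips_per_song)) {
          idx <- idx + 1L
          id <- sprintf("%s_s%03d_c%02d", g, s, cl)
          specs[[idx]] <- draw_spec_from_template(id, g, song_tpl, duration_s)
        }
      }
    }
    names(specs) <- vapply(specs, `[[`, "", "clip_id")
    list(specs = specs,
         clip_seeds = sample.int(.Machine$integer.max - 1L, length(specs)))
  })
}

#' Generate the reference corpus feature table
#'
#' Synthesizes every corpus clip and extracts the requested feature sets,
#' yielding the reference table used by corpus rank normalization (scheme N5).
#' The default configuration produces 4 genres x 110 songs x 10 clips =
#' 4,400 rows.
#'
#' @inheritParams corpus_clip_specs
#' @param sets Character subset of `c("tt", "mfcc")`.
#' @return A feature table (data.frame, first column `clip_id`) with one row
#'   per corpus clip; genre metadata in attribute `"metadata"`.
#' @export
generate_corpus <- function(templates = genre_templates(),
                            songs_per_genre = 110L, clips_per_song = 10L,
                            duration_s = 0.8, seed = 1L,
                            sets = c("tt", "mfcc")) {
  plan <- corpus_clip_specs(templates, songs_per_genre, clips_per_song,
                            duration_s, seed)
  clips <- Map(generate_clip, plan$specs, plan$clip_seeds)
  tab <- build_feature_table(clips, sets = sets)
  attr(tab, "metadata") <- data.frame(
    clip_id = vapply(plan$specs, `[[`, "", "clip_id"),
    genre = vapply(plan$specs, `[[`, "", "genre"),
    release_year = vapply(plan$specs, `[[`, 1L, "release_year"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab
}

#' Latent perceptual model for the sorting simulation
#'
#' Ground-truth dissimilarity is a weighted city-block distance over a known
#' subset of features, plus an optional additive increment for cross-genre
#' pairs; each simulated participant perceives these distances through
#' additive Gaussian noise. This is the parameter-recovery harness: the
#' generating feature support is known, so downstream sparse selection can be
#' scored against it.
#'
#' @param true_weights Named nonnegative feature weights (at least one > 0).
#' @param genre_bonus Additive distance increment for cross-genre pairs.
#' @param noise_sd Standard deviation of per-participant perceptual noise.
#' @return Object of class `latent_model`.
#' @export
latent_model <- function(true_weights, genre_bonus = 0, noise_sd = 0) {
  stopifnot(is.numeric(true_weights), !is.null(names(true_weights)))
  if (!any(true_weights > 0)) stop("at least one true weight must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(true_weights = true_weights, genre_bonus = genre_bonus,
                 noise_sd = noise_sd), class = "latent_model")
}

#' Ground-truth distance matrix under a latent model
#'
#' @param features Feature table (data.frame with `clip_id` column).
#' @param latent A [latent_model()].
#' @param metadata Optional metadata data.frame with `clip_id` and `genre`
#'   (required when `genre_bonus > 0`).
#' @return Symmetric nonnegative distance matrix with zero diagonal,
#'   dimnames = clip ids.
#' @export
latent_distance_matrix <- function(features, latent, metadata = NULL) {
  stopifnot(inherits(latent, "latent_model"))
  x <- feature_matrix(features)
  w <- latent$true_weights
  missing <- setdiff(names(w), colnames(x))
  if (length(missing))
    stop("latent weights name unknown features: ", paste(missing, collapse = ", "))
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (f in names(w)) {
    if (w[[f]] == 0) next
    d <- d + w[[f]] * abs(outer(x[, f], x[, f], "-"))
  }
  if (latent$genre_bonus != 0) {
    if (is.null(metadata)) stop("metadata with genre is required when genre_bonus != 0")
    g <- metadata$genre[match(rownames(x), metadata$clip_id)]
    d <- d + latent$genre_bonus * outer(g, g, "!=")
  }
  d
}

#' Simulate one participant's constrained sort
#'
#' Perceived distances are the true distances plus symmetric additive Gaussian
#' noise. The participant's partition into `n_groups` equal groups is found by
#' local search: a random equal-size initial assignment, then repeated
#' best-improving cross-group item swaps (minimizing total within-group
#' perceived distance) until no swap improves; ties among equally improving
#' swaps are broken by the lexicographically lowest item-index pair.
#' Deterministic given `seed`.
#'
#' @param true_dist Symmetric nonnegative distance matrix with zero diagonal.
#' @param noise_sd Perceptual noise standard deviation (or a [latent_model()],
#'   whose `noise_sd` is used).
#' @param seed Integer seed.
#' @param n_groups Number of groups (default 4).
#' @return Named integer vector: group index (1..n_groups) per clip.
#' @export
simulate_participant <- function(true_dist, noise_sd = 0, seed = 1L, n_groups = 4L) {
  if (inherits(noise_sd, "latent_model")) noise_sd <- noise_sd$noise_sd
  n <- nrow(true_dist)
  if (!isTRUE(all.equal(true_dist, t(true_dist), tolerance = 1e-8)))
    stop("true_dist must be symmetric")
  if (any(diag(true_dist) != 0)) stop("true_dist must have a zero diagonal")
  if (any(true_dist < 0)) stop("true_dist must be nonnegative")
  if (n %% n_groups != 0L)
    stop("number of items (", n, ") must be divisible by n_groups (", n_groups, ")")
  group_size <- n %/% n_groups
  ids <- rownames(true_dist)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  withr::with_seed(seed, {
    d <- true_dist
    if (noise_sd > 0) {
      e <- matrix(0, n, n)
      e[upper.tri(e)] <- stats::rnorm(n * (n - 1) / 2, sd = noise_sd)
      d <- d + e + t(e)
    }
    g <- sample(rep.int(seq_len(n_groups), group_size))
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    # order pairs lexicographically by (i, j) for deterministic tie-breaking
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    repeat {
      memb <- outer(g, seq_len(n_groups), "==") * 1
      s <- d %*% memb                       # s[i, grp] = sum of d[i, k] over k in grp
      i <- pairs[, 1L]; j <- pairs[, 2L]
      gi <- g[i]; gj <- g[j]
      cross <- gi != gj
      if (!any(cross)) break
      ic <- i[cross]; jc <- j[cross]; gic <- gi[cross]; gjc <- gj[cross]
      delta <- s[cbind(ic, gjc)] + s[cbind(jc, gic)] -
        s[cbind(ic, gic)] - s[cbind(jc, gjc)] - 2 * d[cbind(ic, jc)]
      best <- which(delta < -1e-12)
      if (!length(best)) break
      pick <- best[which.min(delta[best])]  # first index among minima = lowest pair
      tmp <- g[ic[pick]]
      g[ic[pick]] <- g[jc[pick]]
      g[jc[pick]] <- tmp
    }
    names(g) <- ids
    g
  })
}

#' Aggregate sorted partitions into a similarity matrix
#'
#' Pairwise similarity is the relative number of partitions in which two clips
#' share a group. The diagonal is set to 1 by construction but flagged as
#' excluded from modeling (attribute `diagonal_excluded`), since identical
#' pairs were never presented.
#'
#' @param partitions Nonempty list of named group-assignment vectors over the
#'   same clips (as returned by [simulate_participant()]).
#' @return Symmetric numeric matrix with entries in `[0, 1]`, dimnames = clip
#'   ids, `attr(, "diagonal_excluded") = TRUE`.
#' @export
aggregate_similarity <- function(partitions) {
  if (!length(partitions)) stop("at least one partition is required")
  ids <- names(partitions[[1L]])
  n <- length(ids)
  counts <- matrix(0, n, n, dimnames = list(ids, ids))
  for (p in partitions) {
    if (!setequal(names(p), ids))
      stop("all partitions must cover the same clips")
    g <- p[ids]
    counts <- counts + (outer(g, g, "==") * 1)
  }
  s <- counts / length(partitions)
  diag(s) <- 1
  attr(s, "diagonal_excluded") <- TRUE
  s
}

#' Simulate a full sorting study
#'
#' Runs [simulate_participant()] for `n_participants` independent participants
#' (per-participant seeds derived from `seed`) and aggregates the partitions
#' into a similarity matrix.
#'
#' @inheritParams simulate_participant
#' @param n_participants Number of simulated participants.
#' @return List with `partitions` and `similarity`.
#' @export
simulate_sorting_study <- function(true_dist, noise_sd = 0, n_participants = 100L,
                                   seed = 1L, n_groups = 4L) {
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_participants))
  partitions <- lapply(seeds, function(s)
    simulate_participant(true_dist, noise_sd, seed = s, n_groups = n_groups))
  list(partitions = partitions, similarity = aggregate_similarity(partitions))
}
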
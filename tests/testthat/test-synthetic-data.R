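test_that("generate_clip honors duration, silence, normalization and fades", {
  cl <- tone_clip(1000, duration_s = 0.4)
  expect_length(cl$samples, round(0.4 * 44100))
  expect_lte(max(abs(cl$samples)), 0.9 + 1e-12)

  # silence spec -> all-zero samples
  silent <- generate_clip(clip_spec("z", duration_s = 0.4))
  expect_identical(max(abs(silent$samples)), 0)

  # first/last 20 ms lie under a monotone raised-cosine ramp
  nf <- round(0.02 * 44100)
  ramp <- 0.5 * (1 - cos(pi * seq_len(nf) / nf))
  expect_true(all(abs(cl$samples[seq_len(nf)]) <= 0.9 * ramp + 1e-9))
  expect_true(all(abs(rev(cl$samples)[seq_len(nf)]) <= 0.9 * ramp + 1e-9))

  # frequency-range validation
  expect_error(clip_spec("bad", partial_freqs = 23000, partial_amps = 1),
               "Nyquist")
  expect_error(clip_spec("bad", am_depth = 1.2, partial_freqs = 100,
                         partial_amps = 1), "am_depth")
})

test_that("a pure 1 kHz partial yields a periodogram centroid at 1 kHz", {
  cl <- tone_clip(1000, duration_s = 0.4)
  expect_lt(abs(periodogram_centroid(cl$samples) - 1000), 10)
})

test_that("clip synthesis is deterministic in the seed", {
  spec <- clip_spec("n", duration_s = 0.4, partial_freqs = 500,
                    partial_amps = 1, noise_band = c(1000, 4000),
                    noise_gain = 0.3)
  expect_identical(generate_clip(spec, seed = 7)$samples,
                   generate_clip(spec, seed = 7)$samples)
  expect_false(identical(generate_clip(spec, seed = 7)$samples,
                         generate_clip(spec, seed = 8)$samples))
})

test_that("stimulus sets have 16 clips, 4 per genre, with decade-banded years", {
  ss <- generate_stimulus_set(duration_s = 0.4, seed = 11)
  expect_length(ss$clips, 16L)
  expect_equal(as.integer(table(ss$metadata$genre)), rep(4L, 4))
  tpl <- genre_templates()
  for (g in names(tpl)) {
    yrs <- ss$metadata$release_year[ss$metadata$genre == g]
    expect_true(all(yrs >= tpl[[g]]$years[1] & yrs <= tpl[[g]]$years[2]))
  }
  # determinism: bit-identical waveforms for the same seed
  ss2 <- generate_stimulus_set(duration_s = 0.4, seed = 11)
  expect_identical(lapply(ss$clips, `[[`, "samples"),
                   lapply(ss2$clips, `[[`, "samples"))
  ss3 <- generate_stimulus_set(duration_s = 0.4, seed = 12)
  expect_false(identical(ss$clips[[1]]$samples, ss3$clips[[1]]$samples))
  expect_error(generate_stimulus_set(templates = genre_templates()[1:3]),
               "configuration")
})

test_that("corpus recipe yields genres x songs x clips rows", {
  plan <- corpus_clip_specs(songs_per_genre = 3L, clips_per_song = 2L)
  expect_length(plan$specs, 4 * 3 * 2)
  co <- generate_corpus(songs_per_genre = 3L, clips_per_song = 2L, seed = 5)
  expect_equal(nrow(co), 24L)
  expect_equal(ncol(co) - 1L, 48L)
  # informative columns: rank normalization needs > 1 distinct value
  expect_true(all(vapply(co[-1], function(x) length(unique(x)) > 1, TRUE)))
})

test_that("participant simulation finds the exact blocks when noise-free", {
  d <- block_distance_16()
  g <- simulate_participant(d, noise_sd = 0, seed = 3)
  expect_equal(partition_objective(d, g), 0)
  expect_equal(as.integer(table(g)), rep(4L, 4))
  # determinism
  expect_identical(g, simulate_participant(d, noise_sd = 0, seed = 3))
  expect_error(simulate_participant(matrix(runif(256), 16), seed = 1),
               "symmetric")
})

test_that("every simulated partition is 4 disjoint groups of 4", {
  d <- random_distance_matrix(16, seed = 21)
  for (s in 1:15) {
    g <- simulate_participant(d, noise_sd = 0.4, seed = s)
    expect_equal(as.integer(table(g)), rep(4L, 4))
    expect_setequal(names(g), rownames(d))
  }
})

test_that("aggregate_similarity computes shared-group fractions", {
  d <- block_distance_16()
  g <- simulate_participant(d, noise_sd = 0, seed = 1)
  s1 <- aggregate_similarity(list(g, g, g))
  off <- s1[lower.tri(s1)]
  expect_true(all(off %in% c(0, 1)))
  expect_true(isTRUE(attr(s1, "diagonal_excluded")))
  expect_equal(unname(diag(s1)), rep(1, 16))

  # a pair co-grouped in exactly one of two partitions scores 0.5
  p1 <- setNames(rep(1:4, each = 4), sprintf("c%02d", 1:16))
  p2 <- p1
  p2[c("c01", "c05")] <- p2[c("c05", "c01")]   # move c01 out of c02's group
  s2 <- aggregate_similarity(list(p1, p2))
  expect_equal(s2["c01", "c02"], 0.5)
  expect_equal(s2, t(s2))
  expect_true(all(s2[lower.tri(s2)] >= 0 & s2[lower.tri(s2)] <= 1))
  expect_error(aggregate_similarity(list()), "at least one")
})

test_that("aggregate_similarity is permutation-equivariant", {
  d <- random_distance_matrix(16, seed = 31)
  study <- simulate_sorting_study(d, noise_sd = 0.3, n_participants = 25, seed = 4)
  s <- study$similarity
  perm <- withr::with_seed(9, sample(rownames(d)))
  permuted <- lapply(study$partitions, function(g) g[perm])
  s_perm <- aggregate_similarity(permuted)
  expect_equal(unclass(s_perm), unclass(s[perm, perm]), ignore_attr = TRUE)
})

test_that("similarity estimates stabilize as participants increase", {
  # sd over batches should shrink roughly like 1/sqrt(P)
  d <- random_distance_matrix(16, seed = 41)
  ent <- function(P, seeds) {
    vapply(seeds, function(s)
      simulate_sorting_study(d, noise_sd = 0.4, n_participants = P,
                             seed = s)$similarity["c01", "c02"], 0)
  }
  sd_small <- sd(ent(10, 1:12))
  sd_large <- sd(ent(90, 101:112))
  expect_lt(sd_large, sd_small / 1.5)
})
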
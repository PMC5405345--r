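test_that("gammatone decomposition localizes tones and handles silence", {
  cl <- tone_clip(1000, duration_s = 0.4)
  g <- gammatone_decompose(cl)
  expect_true(all(g$energy >= 0))
  # band whose center is nearest 1 kHz carries maximal time-averaged energy
  nearest <- which.min(abs(g$center_hz - 1000))
  expect_equal(which.max(rowMeans(g$energy)), nearest)

  silent <- generate_clip(clip_spec("z", duration_s = 0.4))
  expect_true(all(gammatone_decompose(silent)$energy == 0))

  # framing arithmetic for an 800 ms clip
  cl8 <- tone_clip(500, duration_s = 0.8)
  g8 <- gammatone_decompose(cl8)
  L <- length(cl8$samples); w <- g8$frame_len; h <- g8$hop
  expect_equal(g8$n_frames, (L - w) %/% h + 1L)
  expect_equal(h, w %/% 2L)

  expect_error(gammatone_decompose(rnorm(100)), "too short")
})

test_that("spectral descriptors match their definitions on degenerate spectra", {
  f <- c(100, 200, 400, 800)
  flat <- matrix(1, 4, 3)
  sp <- spectral_descriptors(flat, center_hz = f)
  expect_equal(sp$flatness, rep(1, 3))
  expect_equal(sp$crest, rep(1, 3))
  expect_equal(sp$variation[-1], rep(0, 2))
  expect_true(is.na(sp$variation[1]))

  single <- matrix(c(0, 0, 5, 0), 4, 2)
  sp1 <- spectral_descriptors(single, center_hz = f)
  expect_equal(sp1$spread, rep(0, 2))
  expect_equal(sp1$centroid, rep(400, 2))

  # all-zero frame flagged undefined
  z <- cbind(c(1, 2, 3, 4), 0)
  spz <- spectral_descriptors(z, center_hz = f)
  expect_true(all(is.na(spz[2, ])))
  expect_false(anyNA(spz[1, -which(names(spz) == "variation")]))
})

test_that("temporal descriptors recover modulation rate and zero-crossing rate", {
  am <- tone_clip(1000, duration_s = 0.8, am_rate = 4, am_depth = 0.9)
  td <- temporal_descriptors(am)
  expect_lt(abs(td[["modfreq"]] - 4), 0.5)
  expect_gt(td[["modamp"]], 0)

  pure <- tone_clip(1000, duration_s = 0.4)
  tdp <- temporal_descriptors(pure)
  expect_lt(abs(tdp[["zcr_med"]] - 2000), 10)

  const <- structure(list(samples = rep(0.5, 44100 %/% 2), rate_hz = 44100L,
                          clip_id = "const", duration_s = 0.5, fade_s = 0),
                     class = "audio_clip")
  tdc <- temporal_descriptors(const)
  expect_equal(tdc[["zcr_med"]], 0)
  expect_equal(tdc[["zcr_iqr"]], 0)

  silent <- generate_clip(clip_spec("z", duration_s = 0.4))
  expect_equal(unname(temporal_descriptors(silent)),
               c(0, 0, 0, 0))
})

test_that("extract_tt returns 24 finite, gain-invariant descriptors", {
  cl <- tone_clip(800, duration_s = 0.4)
  v <- extract_tt(cl)
  expect_length(v, 24L)
  expect_true(all(is.finite(v)))

  # stationary tone: spectral IQR entries near zero
  iqr_names <- grep("\\.iqr$", names(v), value = TRUE)
  iqr_names <- setdiff(iqr_names, "tt.zcr.iqr")
  rel <- abs(v[iqr_names]) / pmax(abs(v[sub("iqr", "med", iqr_names)]), 1e-6)
  expect_true(all(rel < 0.05))

  # global gain leaves energy-normalized descriptors unchanged
  half <- cl; half$samples <- cl$samples * 0.5
  v2 <- extract_tt(half)
  for (f in c("tt.centroid.med", "tt.spread.med", "tt.flatness.med",
              "tt.crest.med", "tt.slope.med", "tt.decrease.med",
              "tt.rolloff.med", "tt.modfreq", "tt.modamp", "tt.zcr.med")) {
    expect_equal(v2[[f]], v[[f]], tolerance = 1e-6, label = f)
  }
})

test_that("extract_mfcc returns 24 medians with near-zero deltas for steady tones", {
  cl <- tone_clip(800, duration_s = 0.4)
  v <- extract_mfcc(cl)
  expect_length(v, 24L)
  expect_true(all(is.finite(v)))
  deltas <- v[grep("^mfcc\\.d", names(v))]
  expect_lt(max(abs(deltas)), 0.05)

  # broadband noise and a low tone separate on the first coefficient
  noise <- tone_clip(0, amp = 0, duration_s = 0.4, noise_band = c(100, 20000),
                     noise_gain = 1, seed = 5, id = "noise")
  tone200 <- tone_clip(200, duration_s = 0.4, id = "t200")
  expect_gt(abs(extract_mfcc(noise)[["mfcc.c01"]] -
                extract_mfcc(tone200)[["mfcc.c01"]]), 1)

  expect_error(extract_mfcc(tone_clip(500, duration_s = 0.03)), "3 analysis frames")
})

test_that("MFCC medians agree with an independently coded oracle", {
  clips <- withr::with_seed(77, lapply(1:20, function(i) {
    tone_clip(runif(1, 100, 4000), duration_s = 0.4,
              am_rate = runif(1, 0, 8), am_depth = runif(1, 0, 0.8),
              noise_band = sort(runif(2, 100, 15000)),
              noise_gain = runif(1, 0, 0.5), seed = i, id = paste0("r", i))
  }))
  mine <- t(vapply(clips, extract_mfcc, numeric(24)))
  oracle <- t(vapply(clips, oracle_mfcc_medians, numeric(24)))
  for (j in seq_len(24)) {
    expect_gt(cor(mine[, j], oracle[, j], method = "spearman"), 0.95)
  }
})

test_that("feature tables assemble the requested sets deterministically", {
  ss <- generate_stimulus_set(duration_s = 0.4, seed = 2)
  tab <- build_feature_table(ss$clips, sets = c("tt", "mfcc"))
  expect_equal(dim(tab), c(16L, 49L))    # clip_id + 48 features
  tt_only <- build_feature_table(ss$clips, sets = "tt")
  expect_equal(ncol(tt_only) - 1L, 24L)
  tab2 <- build_feature_table(ss$clips, sets = c("tt", "mfcc"))
  expect_identical(tab, tab2)
  expect_error(build_feature_table(ss$clips[1]), "at least 2")

  short <- generate_clip(clip_spec("stub", duration_s = 0.01,
                                   partial_freqs = 500, partial_amps = 1))
  expect_error(build_feature_table(c(ss$clips[1], list(stub = short))),
               "stub")
})
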
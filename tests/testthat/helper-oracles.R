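# Shared fixtures and independent oracles, built in code at test time.

tone_clip <- function(freq = 1000, duration_s = 0.4, amp = 1,
                      am_rate = 0, am_depth = 0, noise_band = NULL,
                      noise_gain = 0, seed = 1L, id = "tone") {
  generate_clip(clip_spec(id, duration_s = duration_s,
                          partial_freqs = freq, partial_amps = amp,
                          noise_band = noise_band, noise_gain = noise_gain,
                          am_rate = am_rate, am_depth = am_depth),
                seed = seed)
}

# Periodogram spectral centroid, independent of the feature module.
periodogram_centroid <- function(x, rate_hz = 44100) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- seq_len(n %/% 2L)
  f <- (half - 1) * rate_hz / n
  sum(f * p[half]) / sum(p[half])
}

# Independent MFCC-median oracle: same analysis dialect (25 ms Hann frames,
# 1/2 overlap, 40 HTK-mel bands, 80 dB log clamp, orthonormal DCT-II coefs
# 1..12, first-difference deltas, medians) coded from the definitions with
# explicit loops, sharing no code with the package internals.
oracle_mfcc_medians <- function(clip, n_coef = 12L, n_mels = 40L) {
  x <- clip$samples
  rate <- clip$rate_hz
  w <- 1102L; h <- 551L
  n_frames <- (length(x) - w) %/% h + 1L
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(w - 1)) / (w - 1))
  n_bins <- w %/% 2L + 1L
  binf <- (0:(n_bins - 1)) * rate / w
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(0, mel(rate / 2), length.out = n_mels + 2L))
  melmat <- matrix(0, n_mels, n_frames)
  for (fr in seq_len(n_frames)) {
    seg <- x[((fr - 1L) * h + 1L):((fr - 1L) * h + w)] * win
    pw <- Mod(stats::fft(seg)[1:n_bins])^2
    for (m in seq_len(n_mels)) {
      lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
      wgt <- pmax(0, pmin((binf - lo) / (ce - lo), (hi - binf) / (hi - ce)))
      melmat[m, fr] <- sum(wgt * pw)
    }
  }
  flo <- max(1e-10, max(melmat) * 1e-8)
  cc <- matrix(0, n_coef, n_frames)
  for (fr in seq_len(n_frames)) {
    lg <- log(pmax(melmat[, fr], flo))
    for (i in seq_len(n_coef)) {
      cc[i, fr] <- sqrt(2 / n_mels) *
        sum(lg * cos(pi * i * (2 * seq_len(n_mels) - 1) / (2 * n_mels)))
    }
  }
  dd <- cc[, -1L, drop = FALSE] - cc[, -n_frames, drop = FALSE]
  c(apply(cc, 1, median), apply(dd, 1, median))
}

# Total within-group distance of a partition.
partition_objective <- function(d, g) {
  memb <- outer(g, g, "==")
  sum(d[memb & upper.tri(d)])
}

# Exhaustive optimum over all 4+4 bipartitions of 8 items.
exhaustive_best_2group <- function(d) {
  min(apply(utils::combn(8L, 4L), 2L, function(ix) {
    g <- rep(2L, 8L); g[ix] <- 1L
    partition_objective(d, g)
  }))
}

# Random symmetric nonnegative distance matrix with zero diagonal.
random_distance_matrix <- function(n, seed, ids = sprintf("c%02d", seq_len(n))) {
  withr::with_seed(seed, {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m + t(m)
  })
}

# Random feature table: n_clips x n_features iid uniform.
random_feature_table <- function(n_clips = 16L, n_features = 5L, seed = 1L,
                                 prefix = "f") {
  withr::with_seed(seed, {
    x <- matrix(runif(n_clips * n_features), n_clips, n_features,
                dimnames = list(NULL, sprintf("%s%02d", prefix, seq_len(n_features))))
    data.frame(clip_id = sprintf("c%02d", seq_len(n_clips)), x,
               stringsAsFactors = FALSE)
  })
}

# Block-structured 16x16 distance matrix: 0 within 4 blocks, 1 between.
block_distance_16 <- function() {
  d <- matrix(1, 16, 16)
  for (b in 0:3) d[b * 4 + 1:4, b * 4 + 1:4] <- 0
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("c%02d", 1:16)
  d
}

# Matrix view of a feature table (test-local; mirrors the package contract
# that the first column is clip_id and the rest are numeric features).
fm <- function(tab) {
  m <- as.matrix(tab[setdiff(names(tab), "clip_id")])
  rownames(m) <- tab$clip_id
  m
}
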
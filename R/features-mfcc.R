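hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular Mel filterbank (n_mels x n_bins) over FFT bin frequencies,
# spanning 0 Hz to Nyquist.
mel_filterbank <- function(n_mels, bin_hz, f_max) {
  edges <- mel_to_hz(seq(0, hz_to_mel(f_max), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, length(bin_hz))
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix rows for coefficients 1..n_coef over n_mels bands
# (the 0th, overall-energy coefficient is excluded).
dct_matrix <- function(n_coef, n_mels) {
  i <- seq_len(n_coef)
  j <- seq_len(n_mels)
  sqrt(2 / n_mels) * cos(pi * outer(i, 2 * j - 1) / (2 * n_mels))
}

#' MFCC and delta-MFCC medians for a clip
#'
#' Computes Mel-frequency cepstral coefficients per 25 ms frame (1/2 overlap):
#' power spectrum -> 40-band triangular Mel filterbank (0 Hz to Nyquist) ->
#' log power (clamped 80 dB below the clip's peak mel power) -> orthonormal
#' DCT-II, keeping coefficients
#' 1-12 (the 0th energy coefficient is excluded). Delta coefficients are the
#' frame-to-frame first differences. Each of the 24 coefficient time series is
#' summarized by its median.
#'
#' @param clip An `audio_clip` (or numeric vector at 44.1 kHz).
#' @param n_coef Number of cepstral coefficients (default 12).
#' @param n_mels Number of Mel bands (default 40).
#' @return Named numeric vector of length `2 * n_coef`
#'   (`mfcc.c01` .. `mfcc.c12`, `mfcc.d01` .. `mfcc.d12`).
#' @export
extract_mfcc <- function(clip, n_coef = 12L, n_mels = 40L) {
  x <- if (inherits(clip, "audio_clip")) clip$samples else clip
  rate <- if (inherits(clip, "audio_clip")) clip$rate_hz else CLIP_RATE_HZ
  ps <- frame_power_spectrum(x, rate)
  if (ncol(ps$power) < 3L)
    stop("clip too short for delta coefficients: at least 3 analysis frames are required")
  fb <- mel_filterbank(n_mels, ps$freq_hz, rate / 2)
  mel_power <- fb %*% ps$power
  # clamp the dynamic range at 80 dB below the clip peak (absolute floor for
  # silence): bands dominated by numerical leakage would otherwise inject
  # large log-domain fluctuations into the cepstrum
  floor_val <- max(1e-10, max(mel_power) * 1e-8)
  log_mel <- log(pmax(mel_power, floor_val))
  cc <- dct_matrix(n_coef, n_mels) %*% log_mel        # n_coef x n_frames
  delta <- cc[, -1L, drop = FALSE] - cc[, -ncol(cc), drop = FALSE]
  out <- c(apply(cc, 1L, stats::median), apply(delta, 1L, stats::median))
  names(out) <- c(sprintf("mfcc.c%02d", seq_len(n_coef)),
                  sprintf("mfcc.d%02d", seq_len(n_coef)))
  out
}
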
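# ERB-rate scale (Glasberg & Moore): number of ERBs below frequency f,
# and the ERB bandwidth at f.
hz_to_erb_rate <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_rate_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437
erb_bandwidth <- function(f) 24.7 * (1 + 0.00437 * f)

#' ERB-spaced gammatone center frequencies
#'
#' @param n_bands Number of bands.
#' @param f_min,f_max Frequency range in Hz (defaults ~26 Hz to Nyquist).
#' @return Numeric vector of center frequencies.
#' @export
erb_centers <- function(n_bands = 64L, f_min = 26, f_max = NYQUIST_HZ) {
  erb_rate_to_hz(seq(hz_to_erb_rate(f_min), hz_to_erb_rate(f_max),
                     length.out = n_bands))
}

# Squared-magnitude response of 4th-order gammatone filters sampled at the
# FFT bin frequencies: |H(f)|^2 = (1 + ((f - fc) / b)^2)^-4 with
# b = 1.019 * ERB(fc).
gammatone_weight_matrix <- function(center_hz, bin_hz) {
  b <- 1.019 * erb_bandwidth(center_hz)
  w <- matrix(0, length(center_hz), length(bin_hz))
  for (k in seq_along(center_hz)) {
    w[k, ] <- (1 + ((bin_hz - center_hz[k]) / b[k])^2)^(-4)
  }
  w
}

#' Gammatone (ERB) band-energy decomposition of a clip
#'
#' Computes a band x frame energy matrix: per-frame power spectra (25 ms Hann
#' frames, 1/2 overlap) are weighted by the squared magnitude responses of an
#' ERB-spaced 4th-order gammatone filterbank spanning ~26 Hz to the Nyquist
#' frequency. All energies are nonnegative; a silent clip yields all zeros.
#'
#' @param clip An `audio_clip` (or plain numeric vector at 44.1 kHz).
#' @param n_bands Number of ERB-spaced bands (default 64).
#' @return List of class `gammatone_tf`: `energy` (n_bands x n_frames),
#'   `center_hz`, `n_frames`, `frame_len`, `hop`.
#' @export
gammatone_decompose <- function(clip, n_bands = 64L) {
  x <- if (inherits(clip, "audio_clip")) clip$samples else clip
  rate <- if (inherits(clip, "audio_clip")) clip$rate_hz else CLIP_RATE_HZ
  ps <- frame_power_spectrum(x, rate)
  centers <- erb_centers(n_bands, f_max = rate / 2)
  w <- gammatone_weight_matrix(centers, ps$freq_hz)
  energy <- w %*% ps$power
  structure(list(energy = energy, center_hz = centers,
                 n_frames = ncol(energy), frame_len = ps$frame_len,
                 hop = ps$hop),
            class = "gammatone_tf")
}
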
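#' Temporal descriptors: energy modulation and zero-crossing statistics
#'
#' Four time-domain descriptors per clip:
#' \describe{
#'   \item{modfreq}{frequency (Hz) of the maximal non-DC peak of the spectrum
#'     of the clip's energy envelope. The envelope is obtained by full-wave
#'     rectification followed by a 4th-order Butterworth low-pass at 50 Hz,
#'     then decimated to ~400 Hz (it is band-limited well below that); the
#'     mean (DC) is removed and the envelope zero-padded (4x) before the FFT.
#'     Undefined for silence, mapped to 0.}
#'   \item{modamp}{relative amplitude of that peak: twice its FFT magnitude
#'     over the clip length, divided by the mean envelope (0 for silence).}
#'   \item{zcr_med, zcr_iqr}{median and interquartile range over frames of the
#'     zero-crossing rate (sign changes per second), using the common 25 ms /
#'     1/2-overlap framing.}
#' }
#'
#' @param clip An `audio_clip` (or numeric vector at 44.1 kHz).
#' @return Named numeric vector of length 4:
#'   `modfreq`, `modamp`, `zcr_med`, `zcr_iqr`.
#' @export
temporal_descriptors <- function(clip) {
  x <- if (inherits(clip, "audio_clip")) clip$samples else clip
  rate <- if (inherits(clip, "audio_clip")) clip$rate_hz else CLIP_RATE_HZ
  fp <- frame_params(rate)
  frames <- frame_signal(x, fp$w, fp$h)

  pos <- frames > 0
  crossings <- colSums(abs(apply(pos, 2L, function(col) diff(col))))
  zcr <- crossings / (fp$w / rate)
  zcr_med <- stats::median(zcr)
  zcr_iqr <- stats::IQR(zcr)

  env_raw <- abs(x)
  if (max(env_raw) == 0) {
    return(c(modfreq = 0, modamp = 0, zcr_med = 0, zcr_iqr = 0))
  }
  bf <- signal::butter(4, 50 / (rate / 2), type = "low")
  env <- as.numeric(signal::filtfilt(bf, env_raw))
  # the envelope is band-limited to 50 Hz: decimate to ~400 Hz before the FFT
  dec <- max(1L, floor(rate / 400))
  env <- env[seq(1L, length(env), by = dec)]
  rate_ds <- rate / dec
  env_mean <- mean(env)
  env0 <- env - env_mean
  n <- length(env0)
  nfft <- 2^ceiling(log2(4 * n))
  spec <- stats::fft(c(env0, numeric(nfft - n)))
  freq <- (seq_len(nfft %/% 2L) - 1) * rate_ds / nfft
  mag <- Mod(spec[seq_len(nfft %/% 2L)])
  cand <- which(freq > 0.5 & freq <= 50)
  if (!length(cand) || env_mean <= 0 || max(mag[cand]) == 0) {
    modfreq <- 0; modamp <- 0
  } else {
    peak <- cand[which.max(mag[cand])]
    modfreq <- freq[peak]
    modamp <- 2 * mag[peak] / n / env_mean
  }
  c(modfreq = modfreq, modamp = modamp, zcr_med = zcr_med, zcr_iqr = zcr_iqr)
}
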
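# Frame settings shared by all descriptor series: 25 ms frames with 1/2
# overlap at 44.1 kHz -> 1102-sample frames (rounded to even), 551-sample hop.
FRAME_S <- 0.025

frame_params <- function(rate_hz, frame_s = FRAME_S) {
  w <- round(frame_s * rate_hz)
  if (w %% 2L == 1L) w <- w - 1L
  list(w = as.integer(w), h = as.integer(w %/% 2L))
}

# Slice a signal into overlapping frames (columns). Frame count is
# floor((L - w) / h) + 1; trailing samples that do not fill a frame are dropped.
frame_signal <- function(x, w, h) {
  n <- length(x)
  if (n < w) stop("clip too short: at least ", w, " samples (", w / CLIP_RATE_HZ,
                  " s at 44.1 kHz) are required for one analysis frame")
  n_frames <- (n - w) %/% h + 1L
  starts <- (seq_len(n_frames) - 1L) * h + 1L
  idx <- outer(seq_len(w) - 1L, starts, "+")
  matrix(x[idx], nrow = w)
}

hann_window <- function(w) 0.5 * (1 - cos(2 * pi * (seq_len(w) - 1L) / (w - 1L)))

# Per-frame one-sided power spectrum: bins 0 .. w/2 (frequencies k * rate / w).
frame_power_spectrum <- function(x, rate_hz, frame_s = FRAME_S) {
  fp <- frame_params(rate_hz, frame_s)
  frames <- frame_signal(x, fp$w, fp$h) * hann_window(fp$w)
  spec <- stats::mvfft(frames)
  n_bins <- fp$w %/% 2L + 1L
  p <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2
  list(power = p, freq_hz = (seq_len(n_bins) - 1L) * rate_hz / fp$w,
       frame_len = fp$w, hop = fp$h)
}
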
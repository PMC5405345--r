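#' Per-frame spectral shape descriptors from a band-energy matrix
#'
#' Computes, for every frame of a gammatone band-energy decomposition, ten
#' spectral descriptors of the energy distribution over band center
#' frequencies:
#' \describe{
#'   \item{centroid, spread, skewness, kurtosis}{first four moments of the
#'     energy-normalized spectral distribution (Hz, Hz, unitless, unitless);
#'     skewness/kurtosis are 0 when spread is 0.}
#'   \item{slope}{least-squares slope of energy against frequency, normalized
#'     by total energy (gain-invariant).}
#'   \item{decrease}{low-frequency-weighted average slope relative to the
#'     first band.}
#'   \item{rolloff}{frequency below which 95% of the energy lies.}
#'   \item{flatness}{geometric over arithmetic mean of band energies, in
#'     (0, 1] for strictly positive spectra.}
#'   \item{crest}{maximum over arithmetic mean of band energies (>= 1).}
#'   \item{variation}{spectrotemporal variation (flux): 1 minus the normalized
#'     correlation between consecutive frame spectra; undefined (NA) for the
#'     first frame.}
#' }
#' All-zero frames yield NA for every descriptor and are excluded from
#' downstream summaries.
#'
#' @param tf A `gammatone_tf` (see [gammatone_decompose()]) or a nonnegative
#'   band x frame matrix plus `center_hz`.
#' @param center_hz Band center frequencies (taken from `tf` if omitted).
#' @return data.frame with one row per frame and 10 descriptor columns.
#' @export
spectral_descriptors <- function(tf, center_hz = NULL) {
  if (inherits(tf, "gammatone_tf")) {
    e <- tf$energy
    f <- tf$center_hz
  } else {
    e <- tf
    f <- center_hz
  }
  if (any(e < 0)) stop("band energies must be nonnegative")
  n_frames <- ncol(e)
  k <- nrow(e)
  out <- matrix(NA_real_, n_frames, 10,
                dimnames = list(NULL, c("centroid", "spread", "skewness",
                                        "kurtosis", "slope", "decrease",
                                        "rolloff", "flatness", "crest",
                                        "variation")))
  tot <- colSums(e)
  sum_f <- sum(f)
  sum_f2 <- sum(f^2)
  for (j in seq_len(n_frames)) {
    a <- e[, j]
    if (tot[j] <= 0) next
    p <- a / tot[j]
    mu <- sum(p * f)
    v <- sum(p * (f - mu)^2)
    sdev <- sqrt(v)
    out[j, "centroid"] <- mu
    out[j, "spread"] <- sdev
    out[j, "skewness"] <- if (sdev > 0) sum(p * (f - mu)^3) / sdev^3 else 0
    out[j, "kurtosis"] <- if (sdev > 0) sum(p * (f - mu)^4) / sdev^4 else 0
    out[j, "slope"] <- (k * sum(f * a) - sum_f * tot[j]) /
      (tot[j] * (k * sum_f2 - sum_f^2))
    tail_sum <- tot[j] - a[1L]
    out[j, "decrease"] <- if (tail_sum > 0)
      sum((a[-1L] - a[1L]) / (seq_len(k - 1L))) / tail_sum else 0
    out[j, "rolloff"] <- f[which(cumsum(a) >= 0.95 * tot[j])[1L]]
    out[j, "flatness"] <- if (all(a > 0)) exp(mean(log(a))) / mean(a) else 0
    out[j, "crest"] <- max(a) / mean(a)
    if (j > 1L && tot[j - 1L] > 0) {
      b <- e[, j - 1L]
      out[j, "variation"] <- 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }
  }
  as.data.frame(out)
}
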
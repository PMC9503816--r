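# Shared spectral machinery: Welch power spectral density and spectral-moment
# summaries. Used by both the sway metrics and the gait stability metrics
# (frequency dispersion of the ML axis).

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann window. Defaults (10 s segments,
#' 50% overlap) resolve 0.1 Hz on the 30 s minimum standing bout at the
#' sensors' 31.25 Hz sampling rate. Each segment is mean-removed before
#' windowing. The one-sided PSD is scaled so that `sum(psd) * df` equals the
#' signal variance.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param segment_s Segment length in seconds; shortened to the signal length
#'   when the signal is shorter than one segment.
#' @param overlap Fractional overlap between successive segments.
#' @return List with `freq` (Hz) and `psd` (signal units squared per Hz).
#' @export
welch_psd <- function(x, fs, segment_s = 10, overlap = 0.5) {
  n <- length(x)
  if (n < 2) abort("welch_psd needs at least 2 samples",
                   class = "weartime_signal_error")
  nper <- min(n, max(8, round(segment_s * fs)))
  step <- max(1, floor(nper * (1 - overlap)))
  starts <- seq(1, n - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  scale <- fs * sum(w^2)
  nfreq <- floor(nper / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / scale
    acc <- acc + p[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nper is even)
  if (nper %% 2 == 0) {
    psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)]
  } else {
    psd[2:nfreq] <- 2 * psd[2:nfreq]
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nper, psd = psd)
}

#' Spectral-moment summary of a power spectrum
#'
#' Computes the stabilogram frequency-domain summary from spectral moments
#' `mu_k = sum(psd * f^k) * df`: total power `mu_0`, centroidal frequency
#' `sqrt(mu_2 / mu_0)`, frequency dispersion `1 - mu_1^2 / (mu_0 * mu_2)`
#' (0 for a line spectrum, approaching 1 for maximally spread spectra), and
#' the interpolated 50th and 95th percentiles of cumulative power.
#'
#' @param freq Frequency grid (Hz).
#' @param psd One-sided PSD on `freq`.
#' @return Named list: `power`, `f50`, `f95`, `centroidal_frequency`,
#'   `frequency_dispersion`.
#' @export
spectral_summary <- function(freq, psd) {
  df <- if (length(freq) > 1) freq[2] - freq[1] else 1
  mu0 <- sum(psd) * df
  if (mu0 <= 0) {
    return(list(power = 0, f50 = NA_real_, f95 = NA_real_,
                centroidal_frequency = NA_real_,
                frequency_dispersion = NA_real_))
  }
  mu1 <- sum(psd * freq) * df
  mu2 <- sum(psd * freq^2) * df
  cum <- cumsum(psd) * df
  quant <- function(p) {
    target <- p * mu0
    i <- which(cum >= target)[1]
    if (i == 1) return(freq[1])
    # linear interpolation between bin centres
    f0 <- freq[i - 1]; f1 <- freq[i]
    c0 <- cum[i - 1]; c1 <- cum[i]
    f0 + (target - c0) / (c1 - c0) * (f1 - f0)
  }
  list(
    power = mu0,
    f50 = quant(0.5),
    f95 = quant(0.95),
    centroidal_frequency = sqrt(mu2 / mu0),
    frequency_dispersion = 1 - mu1^2 / (mu0 * mu2)
  )
}
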
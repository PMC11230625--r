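#' Welch power spectral density
#'
#' Averaged modified periodogram (Hann window, mean-detrended, 50% overlap).
#'
#' @param x numeric series
#' @param fs sampling rate (Hz)
#' @param seg_len_s segment length (s)
#' @param overlap fractional segment overlap
#' @return data frame with columns `freq` (Hz) and `power`
#' @export
welch_psd <- function(x, fs, seg_len_s = 2, overlap = 0.5) {
  nseg <- max(8, round(seg_len_s * fs))
  nseg <- min(nseg, length(x))
  hop <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  scale <- sum(w^2) * fs
  nfreq <- floor(nseg / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2 / scale
    acc <- acc + sp[seq_len(nfreq)]
  }
  data.frame(freq = (seq_len(nfreq) - 1) * fs / nseg,
             power = acc / length(starts))
}

band_power <- function(psd, lo, hi) {
  sum(psd$power[psd$freq >= lo & psd$freq <= hi])
}

spectral_peak <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq <= hi
  if (!any(sel)) return(NA_real_)
  psd$freq[sel][which.max(psd$power[sel])]
}

#' Convert a sound-pressure level difference to an amplitude ratio
#'
#' @param delta_db level difference in dB SPL
#' @return amplitude (sound-pressure) ratio `10^(delta_db / 20)`
#' @export
db_to_amplitude_ratio <- function(delta_db) {
  if (!all(is.finite(delta_db))) stop("delta_db must be finite")
  10^(delta_db / 20)
}
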
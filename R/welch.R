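#' Welch spectral estimation settings
#'
#' Segment length and overlap used for every spectral quantity in the
#' package (power spectra, cross-spectra, SEF95), so that all modules
#' share one frequency grid. The defaults (4-s Hann segments, 50%
#' overlap) give a 0.25 Hz grid at 63 Hz sampling and at least 29
#' averages per 60-s epoch.
#'
#' @param seg_s Segment length in seconds.
#' @param overlap Fractional overlap between consecutive segments.
#' @return A list of class `welch_control`.
#' @export
welch_control <- function(seg_s = 4, overlap = 0.5) {
  stopifnot(seg_s > 0, overlap >= 0, overlap < 1)
  structure(list(seg_s = seg_s, overlap = overlap), class = "welch_control")
}

## windowed segment FFTs shared by PSD and cross-spectral estimation.
## x: channels x samples. Returns nf x nseg x nchan complex array.
welch_fft <- function(x, fs, control = welch_control()) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  L <- round(control$seg_s * fs)
  step <- max(1L, round(L * (1 - control$overlap)))
  n <- ncol(x)
  if (n < L) stop_arg("signal shorter than one Welch segment")
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)
  nf <- floor(L / 2) + 1L
  out <- array(0i, c(nf, length(starts), nrow(x)))
  for (c_ in seq_len(nrow(x))) {
    segs <- vapply(starts, function(s) {
      v <- x[c_, s:(s + L - 1L)]
      (v - mean(v)) * w
    }, numeric(L))
    out[, , c_] <- mvfft(segs)[1:nf, , drop = FALSE]
  }
  attr(out, "freqs") <- (0:(nf - 1)) * fs / L
  attr(out, "u") <- sum(w^2)
  out
}

#' Welch power spectral density
#'
#' Averaged-periodogram PSD with Hann windows and mean detrending per
#' segment; one-sided scaling so that the PSD integrates to the signal
#' variance.
#'
#' @param x Numeric vector or channels-by-samples matrix (uV).
#' @param fs Sampling rate in Hz.
#' @param control A [welch_control()].
#' @param fmax Highest frequency retained (Hz).
#' @return A list with `freqs_hz` and `psd` (channels x frequencies,
#'   uV^2/Hz).
#' @export
welch_psd <- function(x, fs, control = welch_control(), fmax = 30) {
  Fts <- welch_fft(x, fs, control)
  freqs <- attr(Fts, "freqs")
  scale <- 2 / (fs * attr(Fts, "u") * dim(Fts)[2])
  psd <- t(apply(Fts, 3, function(Fc) rowSums(Mod(Fc)^2) * scale))
  psd[, 1] <- psd[, 1] / 2                       # DC not one-sided-doubled
  if (freqs[length(freqs)] == fs / 2) psd[, length(freqs)] <-
      psd[, length(freqs)] / 2
  keep <- freqs <= fmax
  list(freqs_hz = freqs[keep], psd = psd[, keep, drop = FALSE])
}

#' Welch co-spectra between all channel pairs
#'
#' Real part of the cross-spectral density for every channel pair, with
#' the same windowing and scaling as [welch_psd()]. Integrating the
#' co-spectra over a frequency band gives the channel covariance of the
#' ideally band-filtered signal; the diagonal equals the PSD.
#'
#' @inheritParams welch_psd
#' @return A list with `freqs_hz` and `csd` (channels x channels x
#'   frequencies, uV^2/Hz).
#' @export
welch_cross <- function(x, fs, control = welch_control(), fmax = 30) {
  Fts <- welch_fft(x, fs, control)
  freqs <- attr(Fts, "freqs")
  nch <- dim(Fts)[3]
  scale <- 2 / (fs * attr(Fts, "u") * dim(Fts)[2])
  nf <- length(freqs)
  csd <- array(0, c(nch, nch, nf))
  for (a in seq_len(nch)) for (b in a:nch) {
    v <- rowSums(Re(Fts[, , a] * Conj(Fts[, , b]))) * scale
    csd[a, b, ] <- v
    csd[b, a, ] <- v
  }
  csd[, , 1] <- csd[, , 1] / 2
  if (freqs[nf] == fs / 2) csd[, , nf] <- csd[, , nf] / 2
  keep <- freqs <= fmax
  list(freqs_hz = freqs[keep], csd = csd[, , keep, drop = FALSE])
}
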
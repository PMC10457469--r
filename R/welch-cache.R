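## Record-level cache of Welch segment FFTs. Sliding epochs overlap, so
## the same 4-s segments are reused by up to six epochs; computing all
## segment FFTs once per record makes SEF95 and feature extraction cheap.
## The per-epoch results are numerically identical to welch_psd() /
## welch_cross() on the epoch slice (same windowing, demeaning, scaling).

welch_cache <- function(record, control = welch_control()) {
  fs <- record$fs_hz
  L <- round(control$seg_s * fs)
  step <- max(1L, round(L * (1 - control$overlap)))
  n <- ncol(record$signal)
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)
  nf <- floor(L / 2) + 1L
  ## one big FFT: columns = segments x channels
  seg_mat <- matrix(0, L, length(starts) * 4)
  for (c_ in 1:4) {
    cols <- (c_ - 1) * length(starts) + seq_along(starts)
    segs <- vapply(starts, function(s) {
      v <- record$signal[c_, s:(s + L - 1L)]
      (v - mean(v)) * w
    }, numeric(L))
    seg_mat[, cols] <- segs
  }
  Fall <- mvfft(seg_mat)[1:nf, , drop = FALSE]
  list(F = Fall, n_starts = length(starts), step = step, L = L, fs = fs,
       freqs = (0:(nf - 1)) * fs / L, u = sum(w^2),
       start_s = (starts - 1) / fs)
}

## segment columns (within one channel block) covering an epoch
cache_epoch_cols <- function(cache, onset_s, win_s) {
  fs <- cache$fs
  first <- round(onset_s * fs) + 1L
  last_start <- first + round(win_s * fs) - cache$L
  idx <- which((cache$start_s * fs + 1 - first) %% cache$step == 0 &
                 cache$start_s * fs + 1 >= first &
                 cache$start_s * fs + 1 <= last_start)
  idx
}

cache_psd <- function(cache, onset_s, win_s, fmax = 30) {
  idx <- cache_epoch_cols(cache, onset_s, win_s)
  scale <- 2 / (cache$fs * cache$u * length(idx))
  psd <- vapply(1:4, function(c_) {
    cols <- (c_ - 1) * cache$n_starts + idx
    rowSums(Mod(cache$F[, cols, drop = FALSE])^2) * scale
  }, numeric(length(cache$freqs)))
  psd <- t(psd)
  psd[, 1] <- psd[, 1] / 2
  nf <- length(cache$freqs)
  if (cache$freqs[nf] == cache$fs / 2) psd[, nf] <- psd[, nf] / 2
  keep <- cache$freqs <= fmax
  list(freqs_hz = cache$freqs[keep], psd = psd[, keep, drop = FALSE])
}

cache_csd <- function(cache, onset_s, win_s, fmax = 30) {
  idx <- cache_epoch_cols(cache, onset_s, win_s)
  scale <- 2 / (cache$fs * cache$u * length(idx))
  nf <- length(cache$freqs)
  Fc <- lapply(1:4, function(c_)
    cache$F[, (c_ - 1) * cache$n_starts + idx, drop = FALSE])
  csd <- array(0, c(4, 4, nf))
  for (a in 1:4) for (b in a:4) {
    v <- rowSums(Re(Fc[[a]] * Conj(Fc[[b]]))) * scale
    csd[a, b, ] <- v; csd[b, a, ] <- v
  }
  csd[, , 1] <- csd[, , 1] / 2
  if (cache$freqs[nf] == cache$fs / 2) csd[, , nf] <- csd[, , nf] / 2
  keep <- cache$freqs <= fmax
  list(freqs_hz = cache$freqs[keep], csd = csd[, , keep, drop = FALSE])
}
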
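#' Split a recording into sliding-window epochs
#'
#' 60-s windows advanced by 10 s, so `n_epochs = floor((T - win)/shift) + 1`.
#' Per-epoch per-channel peak-to-peak amplitudes are computed immediately;
#' retention flags, SEF95 and burst-suppression overlap are filled in by
#' [reject_epochs()] and [compute_sef95()].
#'
#' @param record An [eeg_record()].
#' @param win_s Window length in seconds.
#' @param shift_s Window shift in seconds.
#' @return An object of class `epoch_set`. A recording shorter than one
#'   window yields an empty set with a warning (the patient is unusable).
#' @export
epoch_record <- function(record, win_s = 60, shift_s = 10) {
  dur <- record_duration_s(record)
  fs <- record$fs_hz
  if (dur < win_s) {
    warning("recording shorter than one window (", dur, " s < ", win_s,
            " s); no epochs", call. = FALSE)
    onsets <- numeric(0)
  } else {
    n_ep <- floor((dur - win_s) / shift_s) + 1
    onsets <- (seq_len(n_ep) - 1) * shift_s
  }
  n_ep <- length(onsets)
  ptp <- matrix(NA_real_, n_ep, 4,
                dimnames = list(NULL, record$channels))
  for (i in seq_len(n_ep)) {
    sl <- epoch_slice(record, onsets[i], win_s)
    ptp[i, ] <- apply(sl, 1, function(v) max(v) - min(v))
  }
  structure(list(record = record, onsets_s = onsets, win_s = win_s,
                 shift_s = shift_s, n_epochs = n_ep, ptp = ptp,
                 retained = rep(TRUE, n_ep),
                 bs_overlap = rep(FALSE, n_ep),
                 sef95 = matrix(NA_real_, n_ep, 4),
                 sef95_mean = rep(NA_real_, n_ep)),
            class = "epoch_set")
}

epoch_slice <- function(record, onset_s, win_s) {
  fs <- record$fs_hz
  i0 <- round(onset_s * fs) + 1L
  record$signal[, i0:(i0 + round(win_s * fs) - 1L), drop = FALSE]
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", x$n_epochs, "epochs of", x$win_s, "s (shift",
      x$shift_s, "s);", sum(x$retained), "retained\n")
  invisible(x)
}

#' Flag epochs usable for feature extraction
#'
#' An epoch is retained only if every channel's peak-to-peak amplitude
#' lies strictly inside `(low_ptp, high_ptp)`: near-flat channels signal
#' sensor dropout or isoelectric suppression, very large amplitudes
#' signal artifacts. With `exclude_bs = TRUE` (default) epochs overlapping
#' suppression intervals found by [detect_suppression()] are additionally
#' excluded, reproducing upstream cleaning of burst suppression before
#' modelling.
#'
#' @param eset An [epoch_record()] result.
#' @param low_ptp,high_ptp Peak-to-peak bounds in uV.
#' @param exclude_bs Exclude epochs overlapping detected suppression.
#' @param bs_intervals Optional pre-computed suppression intervals
#'   (two-column matrix of start/end seconds); detected from the record
#'   when `NULL` and `exclude_bs` is `TRUE`.
#' @return The epoch set with `retained` and `bs_overlap` updated.
#' @export
reject_epochs <- function(eset, low_ptp = 0.1, high_ptp = 250,
                          exclude_bs = TRUE, bs_intervals = NULL) {
  ok <- apply(eset$ptp, 1, function(p) all(p > low_ptp & p < high_ptp))
  if (eset$n_epochs == 0) {
    eset$retained <- logical(0)
    return(eset)
  }
  bs_ov <- rep(FALSE, eset$n_epochs)
  if (exclude_bs) {
    if (is.null(bs_intervals))
      bs_intervals <- detect_suppression(eset$record)$intervals
    if (nrow(bs_intervals)) {
      ep_start <- eset$onsets_s
      ep_end <- eset$onsets_s + eset$win_s
      for (j in seq_len(nrow(bs_intervals)))
        bs_ov <- bs_ov | (ep_start < bs_intervals[j, 2] &
                            ep_end > bs_intervals[j, 1])
    }
  }
  eset$bs_overlap <- bs_ov
  eset$retained <- ok & !bs_ov
  eset
}

#' 95% spectral edge frequency of one epoch
#'
#' The SEF95 of a channel is the smallest grid frequency below which 95%
#' of the Welch power in `[fmin, fmax]` lies. Anaesthesia is considered
#' stable when the mean SEF95 across the four channels falls in 8-13 Hz.
#'
#' @param x Numeric vector or channels-by-samples matrix (one epoch).
#' @param fs Sampling rate in Hz.
#' @param fmin,fmax Integration bounds in Hz.
#' @param control A [welch_control()].
#' @return List with `per_channel` (Hz, `NA` where a channel has no power
#'   in range) and `mean` (arithmetic mean over channels).
#' @export
sef95 <- function(x, fs, fmin = 0.5, fmax = 30, control = welch_control()) {
  est <- welch_psd(x, fs, control, fmax = fmax)
  per <- apply(est$psd, 1, function(p)
    sef95_from_psd(est$freqs_hz, p, fmin, fmax))
  list(per_channel = per, mean = mean(per))
}

sef95_from_psd <- function(freqs, psd, fmin = 0.5, fmax = 30) {
  sel <- freqs >= fmin & freqs <= fmax
  p <- psd[sel]; f <- freqs[sel]
  tot <- sum(p)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  f[which(cumsum(p) >= 0.95 * tot)[1]]
}

#' Compute SEF95 for every epoch of a set
#'
#' Epochs whose SEF95 is undefined on any channel (zero in-range power)
#' are marked not retained.
#'
#' @param eset An [epoch_record()] result.
#' @inheritParams sef95
#' @return The epoch set with `sef95` (epochs x channels) and
#'   `sef95_mean` filled in.
#' @export
compute_sef95 <- function(eset, fmin = 0.5, fmax = 30,
                          control = welch_control(), cache = NULL) {
  for (i in seq_len(eset$n_epochs)) {
    if (!is.null(cache)) {
      est <- cache_psd(cache, eset$onsets_s[i], eset$win_s, fmax = fmax)
      per <- apply(est$psd, 1, function(p)
        sef95_from_psd(est$freqs_hz, p, fmin, fmax))
      s <- list(per_channel = per, mean = mean(per))
    } else {
      s <- sef95(epoch_slice(eset$record, eset$onsets_s[i], eset$win_s),
                 eset$record$fs_hz, fmin, fmax, control)
    }
    eset$sef95[i, ] <- s$per_channel
    eset$sef95_mean[i] <- s$mean
  }
  bad <- apply(eset$sef95, 1, anyNA)
  eset$retained <- eset$retained & !bad
  eset
}

#' Longest run of stable-anaesthesia epochs
#'
#' Returns the longest run of consecutive retained epochs whose
#' channel-mean SEF95 lies within `band`; ties are broken in favour of
#' the earliest run. A rejected epoch breaks a run.
#'
#' @param eset An epoch set with retention flags and SEF95 computed.
#' @param band Two-element frequency band in Hz (default 8-13).
#' @return A list of class `stable_segment` with `first_epoch`,
#'   `last_epoch`, `n_epochs`, `mean_sef95_hz`, or `NULL` when no epoch
#'   qualifies (the patient is excluded from modelling).
#' @export
select_stable_segment <- function(eset, band = c(8, 13)) {
  ok <- eset$retained & !is.na(eset$sef95_mean) &
    eset$sef95_mean >= band[1] & eset$sef95_mean <= band[2]
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]     # earliest maximal run
  first <- starts[best]; last <- ends[best]
  structure(list(first_epoch = first, last_epoch = last,
                 n_epochs = last - first + 1L,
                 mean_sef95_hz = mean(eset$sef95_mean[first:last]),
                 onset_s = eset$onsets_s[first],
                 end_s = eset$onsets_s[last] + eset$win_s),
            class = "stable_segment")
}

#' @export
print.stable_segment <- function(x, ...) {
  cat("<stable_segment> epochs", x$first_epoch, "-", x$last_epoch,
      sprintf("(n=%d), mean SEF95 %.2f Hz\n", x$n_epochs, x$mean_sef95_hz))
  invisible(x)
}

#' Detect isoelectric suppression intervals
#'
#' Amplitude-envelope detector: the recording is scanned in short
#' windows; a window is quiet when the maximum absolute amplitude on
#' every channel is below `supp_thresh`, and runs of quiet windows
#' lasting at least `min_supp_s` count as suppression.
#'
#' @param record An [eeg_record()].
#' @param supp_thresh Envelope threshold in uV.
#' @param min_supp_s Minimum sustained duration in seconds.
#' @param win_s Envelope window in seconds.
#' @return List with `intervals` (two-column matrix, start/end seconds)
#'   and `ratio` (suppressed fraction of the recording).
#' @export
detect_suppression <- function(record, supp_thresh = 5, min_supp_s = 0.5,
                               win_s = 0.1) {
  fs <- record$fs_hz
  n <- ncol(record$signal)
  w <- max(1L, round(win_s * fs))
  n_win <- floor(n / w)
  env <- vapply(seq_len(n_win), function(k) {
    max(abs(record$signal[, ((k - 1) * w + 1):(k * w)]))
  }, numeric(1))
  quiet <- env < supp_thresh
  r <- rle(quiet)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  min_win <- ceiling(min_supp_s / (w / fs))
  keep <- which(r$values & r$lengths >= min_win)
  if (!length(keep))
    return(list(intervals = matrix(numeric(0), 0, 2), ratio = 0))
  iv <- cbind(start_s = (starts[keep] - 1) * w / fs,
              end_s = ends[keep] * w / fs)
  list(intervals = iv, ratio = sum(iv[, 2] - iv[, 1]) * fs / n)
}

#' Proportion of the recording spent in burst suppression
#'
#' @inheritParams detect_suppression
#' @return Suppressed fraction of total recording time, in `[0, 1]`.
#' @export
burst_suppression_ratio <- function(record, supp_thresh = 5,
                                    min_supp_s = 0.5) {
  detect_suppression(record, supp_thresh, min_supp_s)$ratio
}

#' Full preprocessing of one recording
#'
#' Epoching, amplitude-based rejection, burst-suppression exclusion,
#' SEF95 computation and stable-segment selection in one call, together
#' with a per-patient QC summary mirroring a selection flowchart.
#'
#' @param record An [eeg_record()].
#' @param win_s,shift_s Epoching geometry (seconds).
#' @param low_ptp,high_ptp Retention bounds in uV.
#' @param band SEF95 stability band in Hz.
#' @param exclude_bs Exclude epochs overlapping detected suppression.
#' @param control A [welch_control()].
#' @return List with the finished `epochs` ([epoch_record()] result),
#'   `segment` ([select_stable_segment()] result or `NULL`), `bs_ratio`,
#'   and a one-row `qc` data frame (patient_id, n_epochs, n_retained,
#'   n_bs_overlap, segment bounds, bs_ratio, usable, reason).
#' @export
preprocess_record <- function(record, win_s = 60, shift_s = 10,
                              low_ptp = 0.1, high_ptp = 250,
                              band = c(8, 13), exclude_bs = TRUE,
                              control = welch_control()) {
  supp <- detect_suppression(record)
  eset <- suppressWarnings(epoch_record(record, win_s, shift_s))
  reason <- NA_character_
  seg <- NULL
  if (eset$n_epochs == 0) {
    reason <- "recording shorter than one window"
  } else {
    eset <- reject_epochs(eset, low_ptp, high_ptp, exclude_bs,
                          bs_intervals = supp$intervals)
    cache <- welch_cache(record, control)
    if (length(cache_epoch_cols(cache, eset$onsets_s[1], win_s)) !=
        floor((win_s * record$fs_hz - cache$L) / cache$step) + 1)
      cache <- NULL                    # epoch grid not aligned to segments
    eset$cache <- cache
    eset <- compute_sef95(eset, control = control, cache = cache)
    seg <- select_stable_segment(eset, band)
    if (is.null(seg)) reason <- "no stable-anaesthesia epoch (SEF95 out of band)"
  }
  qc <- data.frame(
    patient_id = record$meta$patient_id %||% NA_character_,
    n_epochs = eset$n_epochs,
    n_retained = sum(eset$retained),
    n_bs_overlap = sum(eset$bs_overlap),
    seg_first = if (is.null(seg)) NA_integer_ else seg$first_epoch,
    seg_last = if (is.null(seg)) NA_integer_ else seg$last_epoch,
    seg_n = if (is.null(seg)) 0L else seg$n_epochs,
    bs_ratio = supp$ratio,
    usable = !is.null(seg),
    reason = reason,
    stringsAsFactors = FALSE)
  list(epochs = eset, segment = seg, bs_ratio = supp$ratio, qc = qc)
}
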
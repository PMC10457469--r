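## Minimal European Data Format (EDF) writer/reader, sufficient for the
## four-channel frontal montage this package works with: one data record
## per second, 16-bit samples, physical units in microvolts.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  pad_field(s, width)
}

#' Write a recording to an EDF file
#'
#' Stores the four channels with 1-s data records, 16-bit samples and a
#' symmetric physical range adapted to the signal. Quantisation error is
#' at most half the physical range divided by 2^16 - 2.
#'
#' @param record An [eeg_record()]; its duration must be an integer
#'   number of seconds.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  sig <- record$signal
  fs <- record$fs_hz
  n_rec <- ncol(sig) / fs
  if (abs(n_rec - round(n_rec)) > 1e-9)
    stop_arg("record duration must be an integer number of seconds")
  n_rec <- as.integer(round(n_rec))
  ns <- nrow(sig)
  pmax_ <- max(1, ceiling(max(abs(sig)) * 1.001))
  dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(record$meta$patient_id %||% "X", 80),
    pad_field("synthetic anaesthesia EEG", 80),
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(ns, 4))
  writeBin(charToRaw(hdr), con)
  lab <- record$channels
  fields <- c(
    vapply(lab, pad_field, "", width = 16),
    rep(pad_field("", 80), ns),
    rep(pad_field("uV", 8), ns),
    rep(edf_num(-pmax_), ns),
    rep(edf_num(pmax_), ns),
    rep(pad_field(-dmax, 8), ns),
    rep(pad_field(dmax, 8), ns),
    rep(pad_field("", 80), ns),
    rep(pad_field(fs, 8), ns),
    rep(pad_field("", 32), ns))
  writeBin(charToRaw(paste(fields, collapse = "")), con)

  scale <- dmax / pmax_
  dig <- round(pmin(pmax(sig, -pmax_), pmax_) * scale)
  ## interleave: per record, all samples of signal 1, then signal 2, ...
  idx <- matrix(seq_len(ncol(sig)), nrow = fs)      # fs x n_rec
  for (r in seq_len(n_rec))
    writeBin(as.integer(t(dig[, idx[, r]])), con, size = 2,
             endian = "little")
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) rawToChar(readBin(con, "raw", w))
  version <- trimws(rd(8))
  patient <- trimws(rd(80)); recording <- trimws(rd(80))
  rd(8); rd(8)                                      # date, time
  n_hdr <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop_arg("unreadable EDF header")
  per <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- per(16); per(80)
  dims <- per(8)
  pmin_ <- as.numeric(per(8)); pmax_ <- as.numeric(per(8))
  dmin <- as.numeric(per(8)); dmax <- as.numeric(per(8))
  per(80)
  spr <- as.integer(per(8)); per(32)
  list(patient = patient, recording = recording, n_rec = n_rec,
       rec_dur = rec_dur, ns = ns, labels = labels, dims = dims,
       pmin = pmin_, pmax = pmax_, dmin = dmin, dmax = dmax, spr = spr)
}

#' Read an EDF file into an [eeg_record()]
#'
#' The four frontal channels (Fp1, Fp2, F7, F8) are located by label
#' (case-insensitive, ignoring an optional `"EEG "` prefix), reordered to
#' the canonical montage and converted to microvolts.
#'
#' @param path EDF file path.
#' @param meta Optional metadata list attached to the record.
#' @return An [eeg_record()].
#' @export
read_edf <- function(path, meta = NULL) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  want <- eeg_channels()
  clean <- sub("^eeg[ _]*", "", tolower(h$labels))
  pos <- match(tolower(want), clean)
  if (anyNA(pos))
    stop_arg("missing channel(s) ", paste(want[is.na(pos)], collapse = ", "),
             "; labels found: ", paste(h$labels, collapse = ", "))
  raw_all <- readBin(con, "integer", n = sum(h$spr) * h$n_rec, size = 2,
                     endian = "little")
  sig <- matrix(0, h$ns, h$spr[1] * h$n_rec)
  offsets <- cumsum(c(0, h$spr))
  per_rec <- sum(h$spr)
  for (s in seq_len(h$ns)) {
    take <- as.vector(outer(seq_len(h$spr[s]) + offsets[s],
                            (seq_len(h$n_rec) - 1) * per_rec, `+`))
    gain <- (h$pmax[s] - h$pmin[s]) / (h$dmax[s] - h$dmin[s])
    sig[s, ] <- (raw_all[take] - h$dmin[s]) * gain + h$pmin[s]
  }
  unit_scale <- ifelse(tolower(h$dims) %in% c("mv"), 1000,
                       ifelse(tolower(h$dims) %in% c("v"), 1e6, 1))
  sig <- sig * unit_scale
  fs <- h$spr[pos[1]] / h$rec_dur
  eeg_record(sig[pos, , drop = FALSE], fs_hz = fs,
             meta = meta %||% list(patient_id = h$patient))
}
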
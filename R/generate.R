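#' Construct a raw EEG record object
#'
#' Container for one patient's four-channel frontal recording (Fp1, Fp2,
#' F7, F8 referenced to Cz) in microvolts.
#'
#' @param signal Numeric matrix, 4 x n_samples, in uV.
#' @param fs_hz Sampling rate in Hz.
#' @param meta Named list of patient metadata (patient_id, age_yr, sex,
#'   drug, asa, ...).
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(signal, fs_hz = 63, meta = list()) {
  if (!is.matrix(signal) || nrow(signal) != 4)
    stop_arg("signal must be a 4 x n_samples matrix")
  if (anyNA(signal)) stop_arg("signal must not contain missing samples")
  structure(list(signal = signal, fs_hz = fs_hz,
                 channels = eeg_channels(), meta = meta),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat("<eeg_record>", nrow(x$signal), "channels x",
      ncol(x$signal), "samples at", x$fs_hz, "Hz (",
      round(ncol(x$signal) / x$fs_hz, 1), "s )\n")
  if (length(x$meta))
    cat("  patient:", x$meta$patient_id %||% "?",
        " age:", round(x$meta$age_yr %||% NA, 1),
        " drug:", x$meta$drug %||% "?",
        " ASA:", x$meta$asa %||% "?", "\n")
  invisible(x)
}

record_duration_s <- function(record) ncol(record$signal) / record$fs_hz

## Gaussian (or fixed-magnitude, random-phase) noise with a prescribed
## one-sided PSD, synthesised in the frequency domain. `psd` gives the
## target in uV^2/Hz at frequencies k * fs / n, k = 1 .. floor(n/2).
colored_noise <- function(n, fs, psd, n_series = 1, random_mag = TRUE) {
  nf <- floor(n / 2)
  stopifnot(length(psd) == nf)
  amp <- sqrt(psd * fs * n / 2)
  X <- matrix(0i, n, n_series)
  if (random_mag) {
    z <- matrix(complex(real = rnorm((nf - 1) * n_series),
                        imaginary = rnorm((nf - 1) * n_series)) / sqrt(2),
                nf - 1, n_series)
  } else {
    phi <- matrix(runif((nf - 1) * n_series, 0, 2 * pi), nf - 1, n_series)
    z <- exp(1i * phi)
  }
  X[2:nf, ] <- amp[1:(nf - 1)] * z
  X[n:(n - nf + 2), ] <- Conj(X[2:nf, ])
  Re(mvfft(X, inverse = TRUE)) / n
}

## one contiguous burst-suppression bout: alternating suppression and
## burst intervals whose suppressed time totals proportion * duration
bs_bout_intervals <- function(duration_s, proportion, truth) {
  target <- proportion * duration_s
  if (target <= 0) return(matrix(numeric(0), 0, 2))
  supp <- numeric(0)
  while (sum(supp) < target)
    supp <- c(supp, runif(1, truth$bs_supp_range_s[1], truth$bs_supp_range_s[2]))
  supp[length(supp)] <- supp[length(supp)] - (sum(supp) - target)
  k <- length(supp)
  gaps <- if (k > 1) runif(k - 1, truth$bs_burst_range_s[1],
                           truth$bs_burst_range_s[2]) else numeric(0)
  bout_len <- sum(supp) + sum(gaps)
  if (bout_len > duration_s) {        # shrink burst gaps so the bout fits
    excess <- bout_len - duration_s
    gaps <- gaps * max(0, 1 - excess / max(sum(gaps), 1e-9))
    bout_len <- sum(supp) + sum(gaps)
  }
  start <- runif(1, 0, max(0, duration_s - bout_len))
  onsets <- start + cumsum(c(0, head(supp, -1) + gaps))
  cbind(start_s = onsets, end_s = pmin(onsets + supp, duration_s))
}

## multiplicative mask implementing suppression with raised-cosine edges
bs_mask <- function(n, fs, intervals, attenuation, ramp_s) {
  mask <- rep(1, n)
  if (!nrow(intervals)) return(mask)
  nr <- max(1L, round(ramp_s * fs))
  ramp <- (1 + cos(seq(0, pi, length.out = nr))) / 2   # 1 -> 0
  for (i in seq_len(nrow(intervals))) {
    i0 <- max(1L, floor(intervals[i, 1] * fs) + 1L)
    i1 <- min(n, ceiling(intervals[i, 2] * fs))
    if (i1 <= i0) next
    mask[i0:i1] <- attenuation
    dn <- min(nr, i0 - 1L)
    if (dn > 0)
      mask[(i0 - dn):(i0 - 1L)] <-
        pmin(mask[(i0 - dn):(i0 - 1L)],
             attenuation + (1 - attenuation) * ramp[seq_len(dn)])
    up <- min(nr, n - i1)
    if (up > 0)
      mask[(i1 + 1L):(i1 + up)] <-
        pmin(mask[(i1 + 1L):(i1 + up)],
             attenuation + (1 - attenuation) * rev(ramp)[seq_len(up)])
  }
  mask
}

## biphasic high-voltage transients; returns modified signal + onset times
add_artifacts <- function(signal, fs, duration_s, truth) {
  k <- rpois(1, truth$artifact_rate_per_min * duration_s / 60)
  times <- numeric(0)
  if (k > 0) {
    for (j in seq_len(k)) {
      dur <- runif(1, truth$artifact_dur_range_s[1], truth$artifact_dur_range_s[2])
      t0 <- runif(1, 0, duration_s - dur)
      ptp <- runif(1, truth$artifact_ptp_range_uv[1], truth$artifact_ptp_range_uv[2])
      i0 <- floor(t0 * fs) + 1L
      len <- max(4L, round(dur * fs))
      tt <- seq(0, 1, length.out = len)
      shape <- sin(2 * pi * tt) * (0.5 - 0.5 * cos(2 * pi * tt))
      shape <- shape / diff(range(shape)) * ptp
      w <- runif(4, 0.7, 1)
      idx <- i0:min(ncol(signal), i0 + len - 1L)
      signal[, idx] <- signal[, idx] +
        outer(w, shape[seq_along(idx)])
      times <- c(times, t0)
    }
  }
  list(signal = signal, times = times)
}

#' Generate one synthetic patient
#'
#' Draws patient-level characteristics (or uses the ones supplied),
#' synthesises a four-channel recording whose Welch spectrum converges to
#' [target_spectrum()] evaluated at the patient's *effective* age
#' (chronological age plus a latent brain-age offset), applies
#' age-dependent spatial mixing, injects one burst-suppression bout whose
#' suppressed time matches the patient's logistic-model proportion, and
#' adds high-voltage artifact transients.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [generator_truth()].
#' @param patient_seed Integer seed; the same seed reproduces the patient
#'   bit-identically.
#' @param patient_id Identifier stored in the metadata.
#' @param age_yr,sex,drug,asa Optional demographics; drawn from `spec`
#'   when `NULL`.
#' @param with_bs,with_artifacts Logical switches for burst suppression
#'   and artifact injection (both on by default).
#' @return A list with elements `record` (an [eeg_record()]), `truth`
#'   (one-row data frame of ground-truth values), `bs_intervals`
#'   (suppression intervals, seconds) and `artifact_s` (artifact onsets).
#' @export
generate_patient <- function(spec, truth, patient_seed,
                             patient_id = "P001",
                             age_yr = NULL, sex = NULL, drug = NULL,
                             asa = NULL, with_bs = TRUE,
                             with_artifacts = TRUE) {
  set.seed(patient_seed)
  fs <- spec$fs_hz
  n <- as.integer(round(spec$duration_s * fs))

  if (is.null(age_yr)) age_yr <- runif(1, spec$age_range[1], spec$age_range[2])
  if (is.null(sex)) sex <- if (runif(1) < 0.653) "F" else "M"
  if (is.null(drug)) drug <- if (runif(1) < spec$drug_mix) "propofol" else "sevoflurane"
  if (is.null(asa)) asa <- if (runif(1) < spec$asa_mix) sample(1:2, 1) else 3L

  offset <- rnorm(1, 0, truth$brainage_offset_sd_yr)
  level_noise <- rnorm(1, 0, truth$level_noise_sd_db)
  alpha_noise <- rnorm(1, 0, truth$alpha_amp_noise_sd_db)
  peak_jitter <- rnorm(1, 0, truth$alpha_peak_jitter_sd_hz)
  mix_jitter <- rnorm(4, 0, truth$mixing_jitter_sd_rad)

  age_eff <- age_yr + offset
  ## burst-suppression proportion from the logistic ground-truth model
  cf <- truth$bs_logit_coefs
  age_s <- (age_yr - truth$bs_age_center) / truth$bs_age_scale
  ba_s <- (age_eff - truth$bs_brainage_center) / truth$bs_brainage_scale
  asa_bin <- as.integer(asa >= 3)
  lin <- cf[["intercept"]] + cf[["age"]] * age_s + cf[["brainage"]] * ba_s +
    cf[["asa"]] * asa_bin + cf[["brainage_asa"]] * ba_s * asa_bin +
    rnorm(1, 0, truth$bs_logit_noise_sd)
  p_bs <- if (with_bs) plogis(lin) else 0

  ## spectrum on the synthesis grid
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  psd <- db_to_power(.spectrum_db(f, age_eff, drug, truth,
                                  level_noise, alpha_noise, peak_jitter))
  series <- colored_noise(n, fs, psd, n_series = 6)

  ## age-dependent spatial mixing of two latent sources + sensor noise
  age_mix <- age_eff
  if (drug == "sevoflurane")
    age_mix <- truth$age_ref_yr + truth$sevo_age_factor *
      (age_eff - truth$age_ref_yr)
  theta <- truth$mixing_base_rad +
    truth$mixing_slope_rad_per_yr * (age_mix - truth$age_ref_yr) + mix_jitter
  w_src <- sqrt(1 - truth$indep_noise_frac)
  w_ns <- sqrt(truth$indep_noise_frac)
  signal <- t(vapply(1:4, function(c_) {
    w_src * (cos(theta[c_]) * series[, 1] + sin(theta[c_]) * series[, 2]) +
      w_ns * series[, 2 + c_]
  }, numeric(n)))

  intervals <- bs_bout_intervals(spec$duration_s, p_bs, truth)
  signal <- signal * rep(bs_mask(n, fs, intervals, truth$bs_attenuation,
                                 truth$bs_ramp_s), each = 4)
  art <- if (with_artifacts)
    add_artifacts(signal, fs, spec$duration_s, truth)
  else list(signal = signal, times = numeric(0))

  meta <- list(patient_id = patient_id, age_yr = age_yr, sex = sex,
               drug = drug, asa = asa)
  truth_row <- data.frame(
    patient_id = patient_id, age_yr = age_yr, sex = sex, drug = drug,
    asa = asa, latent_brainage_offset_yr = offset,
    true_bs_proportion = p_bs, seed = patient_seed,
    level_noise_db = level_noise, alpha_noise_db = alpha_noise,
    peak_jitter_hz = peak_jitter,
    stringsAsFactors = FALSE)
  list(record = eeg_record(art$signal, fs, meta), truth = truth_row,
       bs_intervals = intervals, artifact_s = art$times)
}

## deterministic drug/ASA assignment honouring group quotas (or mixes)
cohort_demographics <- function(spec) {
  n <- spec$n_patients
  set.seed(derive_seed(spec$seed, 0L, 1L))
  if (!is.null(spec$group_sizes)) {
    g <- spec$group_sizes
    lab <- rep(names(g), times = g)
  } else {
    n_prop <- round(spec$drug_mix * n)
    n_low <- round(spec$asa_mix * n)
    drugv <- sample(rep(c("prop", "sevo"), c(n_prop, n - n_prop)))
    asav <- sample(rep(c("asa12", "asa3"), c(n_low, n - n_low)))
    lab <- paste(drugv, asav, sep = "_")
  }
  lab <- sample(lab)
  data.frame(
    drug = ifelse(startsWith(lab, "prop"), "propofol", "sevoflurane"),
    asa = ifelse(endsWith(lab, "asa3"), 3L, sample(1:2, n, replace = TRUE)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Calls [generate_patient()] once per patient with deterministic derived
#' seeds, optionally writing each recording to an EDF file.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [generator_truth()].
#' @param out_dir Optional directory; when given, one EDF file per patient
#'   plus `metadata.csv` and `truth.csv` are written there.
#' @param keep_signals Keep the generated [eeg_record()] objects in the
#'   returned list (set `FALSE` for large cohorts when only files or
#'   tables are needed).
#' @param with_bs,with_artifacts Passed to [generate_patient()].
#' @return A list with `records` (list of [eeg_record()] or `NULL`s),
#'   `metadata` (data frame: patient_id, age_yr, sex, drug, asa,
#'   bs_annotated), `truth` (ground-truth data frame), `bs_intervals`
#'   (per-patient suppression intervals) and `paths` (EDF files written,
#'   if any).
#' @export
generate_cohort <- function(spec, truth = generator_truth(), out_dir = NULL,
                            keep_signals = TRUE, with_bs = TRUE,
                            with_artifacts = TRUE) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  demo <- cohort_demographics(spec)
  n <- spec$n_patients
  records <- vector("list", n)
  bs_intervals <- vector("list", n)
  truth_rows <- vector("list", n)
  paths <- character(0)
  for (i in seq_len(n)) {
    id <- sprintf("P%03d", i)
    pt <- generate_patient(spec, truth, derive_seed(spec$seed, i),
                           patient_id = id, drug = demo$drug[i],
                           asa = demo$asa[i], with_bs = with_bs,
                           with_artifacts = with_artifacts)
    truth_rows[[i]] <- pt$truth
    bs_intervals[[i]] <- pt$bs_intervals
    if (keep_signals) records[[i]] <- pt$record
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, paste0(id, ".edf"))
      write_edf(pt$record, path)
      paths <- c(paths, path)
    }
  }
  truth_df <- do.call(rbind, truth_rows)
  metadata <- truth_df[, c("patient_id", "age_yr", "sex", "drug", "asa")]
  metadata$bs_annotated <- TRUE
  if (!is.null(out_dir)) {
    write.csv(metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
    write.csv(truth_df, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  list(records = records, metadata = metadata, truth = truth_df,
       bs_intervals = bs_intervals, paths = paths)
}
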
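#' Noiseless target power spectrum of the generator
#'
#' Evaluates the generator's analytic log power spectral density for a
#' patient of a given (effective) age under a given drug: aperiodic 1/f
#' background, Gaussian alpha peak whose centre decreases with age, a
#' linear broadband age slope, and for sevoflurane an offset plus a
#' log-frequency interaction. Deterministic in its arguments; patient
#' nuisance variability is added only inside [generate_patient()].
#'
#' @param freq_hz Frequencies in Hz, each in (0, 31.5].
#' @param age_yr Age in years.
#' @param drug `"propofol"` or `"sevoflurane"`.
#' @param truth A [generator_truth()] object.
#' @return Power density in dB (relative to 1 uV^2/Hz), one value per
#'   frequency.
#' @export
#' @examples
#' tr <- generator_truth()
#' f <- seq(1, 30, by = 0.25)
#' s40 <- target_spectrum(f, 40, "propofol", tr)
#' s50 <- target_spectrum(f, 50, "propofol", tr)
#' unique(round(s50 - s40, 10))  # -1 dB: ten years of broadband decline
target_spectrum <- function(freq_hz, age_yr, drug = c("propofol", "sevoflurane"),
                            truth = generator_truth()) {
  drug <- match.arg(drug)
  if (any(freq_hz <= 0 | freq_hz > 31.5))
    stop_arg("freq_hz must lie in (0, 31.5] Hz")
  .spectrum_db(freq_hz, age_yr, drug, truth,
               level_noise = 0, alpha_noise = 0, peak_jitter = 0)
}

#' Patient-specific target spectrum
#'
#' Evaluates the generator's analytic spectrum at one generated
#' patient's own parameters: effective age (chronological age plus the
#' latent brain-age offset) and the patient's broadband-level, alpha
#' amplitude and alpha peak nuisance draws, as recorded in the
#' ground-truth row returned by [generate_patient()]. The Welch spectrum
#' of the patient's artifact-free, suppression-free signal converges to
#' this curve.
#'
#' @param freq_hz Frequencies in Hz.
#' @param truth_row One row of the ground-truth table.
#' @param truth The [generator_truth()] used for generation.
#' @return Power density in dB.
#' @export
patient_target_spectrum <- function(freq_hz, truth_row,
                                    truth = generator_truth()) {
  .spectrum_db(freq_hz,
               truth_row$age_yr + truth_row$latent_brainage_offset_yr,
               truth_row$drug, truth,
               level_noise = truth_row$level_noise_db,
               alpha_noise = truth_row$alpha_noise_db,
               peak_jitter = truth_row$peak_jitter_hz)
}

## shared spectrum kernel: population parameters plus patient perturbations
.spectrum_db <- function(freq_hz, age_yr, drug, truth,
                         level_noise = 0, alpha_noise = 0, peak_jitter = 0) {
  is_sevo <- drug == "sevoflurane"
  age_eff <- age_yr
  if (is_sevo) {
    age_eff <- truth$age_ref_yr +
      truth$sevo_age_factor * (age_yr - truth$age_ref_yr)
  }
  peak <- truth$alpha_peak_hz_at_18 +
    truth$alpha_peak_slope_hz_per_yr * (age_eff - 18) + peak_jitter
  peak <- min(max(peak, truth$alpha_peak_range[1]), truth$alpha_peak_range[2])
  db <- truth$power_intercept_db + level_noise -
    10 * truth$spectral_exponent * log10(pmax(freq_hz, truth$lf_knee_hz)) +
    (truth$alpha_peak_amp_db + alpha_noise) *
      exp(-(freq_hz - peak)^2 / (2 * truth$alpha_peak_sd_hz^2)) +
    truth$power_slope_db_per_yr * (age_eff - truth$age_ref_yr)
  if (is_sevo) {
    db <- db + truth$sevo_offset_db +
      truth$sevo_freq_slope_db * (log(freq_hz) - truth$log_freq_ref)
  }
  db
}
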
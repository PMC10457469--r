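#' Cohort-level simulation settings
#'
#' Describes a synthetic surgical cohort: how many patients, their age
#' distribution, the anaesthetic drug mix, ASA mix, and the common
#' recording geometry. The defaults match the study conditions the
#' pipeline is designed for: ages spanning 18-90 years, 63 Hz four-channel
#' frontal recordings of 20 minutes.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer base seed; every downstream draw is derived from it.
#' @param age_range Two-element numeric vector, uniform age bounds in years.
#' @param drug_mix Proportion of patients under propofol (the rest get
#'   sevoflurane).
#' @param asa_mix Proportion of patients with ASA physical status 1-2
#'   (the rest are ASA 3).
#' @param duration_s Recording length in seconds (>= 60; integer seconds).
#' @param fs_hz Sampling rate in Hz; must exceed twice the 30 Hz analysis
#'   bandwidth.
#' @param group_sizes Optional named integer vector with exact subgroup
#'   sizes `c(prop_asa12=, sevo_asa12=, prop_asa3=, sevo_asa3=)`. When
#'   supplied it overrides `n_patients`, `drug_mix` and `asa_mix` so that
#'   analysis subsets have deterministic sizes.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_patients = 10, seed = 1, duration_s = 120)
cohort_spec <- function(n_patients = 317,
                        seed = 1L,
                        age_range = c(18, 90),
                        drug_mix = 216 / 317,
                        asa_mix = 249 / 317,
                        duration_s = 1200,
                        fs_hz = 63,
                        group_sizes = NULL) {
  if (!is.null(group_sizes)) {
    need <- c("prop_asa12", "sevo_asa12", "prop_asa3", "sevo_asa3")
    if (!all(need %in% names(group_sizes)))
      stop_arg("group_sizes must be named: ", paste(need, collapse = ", "))
    n_patients <- sum(group_sizes)
  }
  if (n_patients < 1) stop_arg("n_patients must be >= 1")
  if (drug_mix < 0 || drug_mix > 1 || asa_mix < 0 || asa_mix > 1)
    stop_arg("drug_mix and asa_mix must be proportions in [0, 1]")
  if (duration_s < 60) stop_arg("duration_s must be >= 60")
  if (duration_s != round(duration_s))
    stop_arg("duration_s must be an integer number of seconds")
  if (fs_hz <= 2 * 30) stop_arg("fs_hz must exceed 60 Hz (2 x 30 Hz bandwidth)")
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         age_range = age_range, drug_mix = drug_mix, asa_mix = asa_mix,
         duration_s = duration_s, fs_hz = fs_hz, group_sizes = group_sizes),
    class = "cohort_spec")
}

#' Ground-truth generator coefficients
#'
#' All coefficients of the synthetic EEG generator. The noiseless target
#' spectrum of a patient of effective age \eqn{a} under drug \eqn{d} is,
#' in dB relative to 1 uV^2/Hz,
#' \deqn{S(f) = b_0 - 10\chi \log_{10} f + A e^{-(f-p(a))^2 / 2\sigma^2}
#'   + \beta_{age}(a - a_{ref}) + d \,[\beta_{sevo} +
#'   \beta_{sevo:f}(\log f - \overline{\log f})]}
#' with an aperiodic 1/f background (exponent \eqn{\chi}), a Gaussian
#' alpha-band peak whose centre \eqn{p(a)} decreases with age, a broadband
#' age slope of -0.10 dB per year, and a sevoflurane offset of +3.6 dB at
#' the reference log-frequency with a negative log-frequency interaction.
#' The spatial side mixes two latent sources into the four channels with
#' age-dependent mixing angles, so channel covariances carry age
#' information beyond the power spectrum.
#'
#' Burst-suppression proportions follow a logistic model in scaled age,
#' scaled latent brain age and binarised ASA, with the brain-age
#' coefficient 0.85 (odds ratio 2.34 per 16 yr of brain age) and the
#' brain-age-by-ASA interaction -0.99 (odds ratio 0.37).
#'
#' @param power_slope_db_per_yr Broadband ageing slope (dB per year).
#' @param power_intercept_db Aperiodic level at 1 Hz for the reference age.
#' @param spectral_exponent Aperiodic 1/f exponent \eqn{\chi}.
#' @param lf_knee_hz Low-frequency knee of the aperiodic background: the
#'   1/f rise is capped below this frequency (models the acquisition
#'   high-pass; keeps total signal power physiological).
#' @param alpha_peak_amp_db,alpha_peak_sd_hz Height (dB) and width (Hz) of
#'   the alpha peak.
#' @param alpha_peak_hz_at_18,alpha_peak_slope_hz_per_yr,alpha_peak_range
#'   Affine map from age to alpha peak frequency, clamped to a range.
#' @param age_ref_yr Reference age at which the intercept applies.
#' @param sevo_offset_db Sevoflurane minus propofol power offset (dB) at
#'   the reference log-frequency.
#' @param sevo_freq_slope_db Additional sevoflurane slope per unit centred
#'   natural-log frequency (dB).
#' @param log_freq_ref Centre of the log-frequency axis for the drug terms;
#'   the default is the mean natural-log frequency of the 1-30 Hz analysis
#'   grid, so the drug main effect is interpretable at that reference.
#' @param sevo_age_factor Multiplier on all age-dependent spectrum and
#'   mixing terms for sevoflurane patients (1 = same age coding as
#'   propofol; 0 = sevoflurane EEG carries no age information).
#' @param brainage_offset_sd_yr SD (years) of the latent brain-age offset
#'   added to chronological age inside the spectrum only.
#' @param level_noise_sd_db,alpha_amp_noise_sd_db,alpha_peak_jitter_sd_hz
#'   Patient-level nuisance variability: broadband level, alpha amplitude,
#'   alpha peak frequency.
#' @param mixing_base_rad,mixing_slope_rad_per_yr,mixing_jitter_sd_rad
#'   Spatial mixing angles per channel: baseline, age slope, patient jitter.
#' @param indep_noise_frac Fraction of channel variance from independent
#'   sensor noise (keeps covariances positive definite).
#' @param bs_logit_coefs Named vector `c(intercept, age, brainage, asa,
#'   brainage_asa)` of the burst-suppression logistic model.
#' @param bs_logit_noise_sd SD of patient-level noise on the logit scale.
#' @param bs_age_center,bs_age_scale,bs_brainage_center,bs_brainage_scale
#'   Centring/scaling constants used inside the logistic model (age scaled
#'   by the uniform 18-90 SD; brain age by 16 yr).
#' @param bs_supp_range_s,bs_burst_range_s Uniform bounds for suppression
#'   and within-bout burst interval durations (seconds).
#' @param bs_attenuation Multiplicative attenuation during suppression
#'   (0.02 leaves < 2 uV peak-to-peak).
#' @param bs_ramp_s Raised-cosine ramp at suppression edges (seconds).
#' @param artifact_rate_per_min Expected high-voltage transients per minute.
#' @param artifact_ptp_range_uv,artifact_dur_range_s Artifact peak-to-peak
#'   amplitude (uV) and duration (s) bounds.
#' @return An object of class `generator_truth`.
#' @export
generator_truth <- function(power_slope_db_per_yr = -0.10,
                            power_intercept_db = 14,
                            spectral_exponent = 2,
                            lf_knee_hz = 0.5,
                            alpha_peak_amp_db = 12,
                            alpha_peak_sd_hz = 1.5,
                            alpha_peak_hz_at_18 = 11.5,
                            alpha_peak_slope_hz_per_yr = -0.04,
                            alpha_peak_range = c(8.5, 12.5),
                            age_ref_yr = 54,
                            sevo_offset_db = 3.6,
                            sevo_freq_slope_db = -1.00,
                            log_freq_ref = mean(log(seq(1, 30, by = 0.25))),
                            sevo_age_factor = 1,
                            brainage_offset_sd_yr = 8,
                            level_noise_sd_db = 1.5,
                            alpha_amp_noise_sd_db = 1.5,
                            alpha_peak_jitter_sd_hz = 0.3,
                            mixing_base_rad = c(0.3, 0.5, 1.1, 1.3),
                            mixing_slope_rad_per_yr =
                              c(0.006, -0.002, 0.002, -0.006),
                            mixing_jitter_sd_rad = 0.05,
                            indep_noise_frac = 0.1,
                            bs_logit_coefs = c(intercept = -3.2, age = 0.4,
                                               brainage = 0.85, asa = 0.5,
                                               brainage_asa = -0.99),
                            bs_logit_noise_sd = 0.3,
                            bs_age_center = 54,
                            bs_age_scale = (90 - 18) / sqrt(12),
                            bs_brainage_center = 54,
                            bs_brainage_scale = 16,
                            bs_supp_range_s = c(2, 10),
                            bs_burst_range_s = c(2, 6),
                            bs_attenuation = 0.02,
                            bs_ramp_s = 0.1,
                            artifact_rate_per_min = 0.3,
                            artifact_ptp_range_uv = c(320, 600),
                            artifact_dur_range_s = c(0.2, 1)) {
  if (indep_noise_frac <= 0 || indep_noise_frac >= 1)
    stop_arg("indep_noise_frac must lie strictly between 0 and 1")
  need <- c("intercept", "age", "brainage", "asa", "brainage_asa")
  if (!all(need %in% names(bs_logit_coefs)))
    stop_arg("bs_logit_coefs must be named: ", paste(need, collapse = ", "))
  truth <- as.list(environment())
  structure(truth, class = "generator_truth")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_patients, "patients,",
      x$duration_s, "s at", x$fs_hz, "Hz, ages",
      paste(x$age_range, collapse = "-"), "\n")
  invisible(x)
}

#' @export
print.generator_truth <- function(x, ...) {
  cat("<generator_truth> age slope", x$power_slope_db_per_yr,
      "dB/yr; sevoflurane offset", x$sevo_offset_db,
      "dB; BS logit brainage coef", x$bs_logit_coefs[["brainage"]], "\n")
  invisible(x)
}

## canonical montage shared across the package
eeg_channels <- function() c("Fp1", "Fp2", "F7", "F8")
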
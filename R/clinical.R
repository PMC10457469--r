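#' Long-format log-power table for the spectral ageing models
#'
#' One row per patient and frequency bin: the channel-mean Welch PSD of
#' the stable segment converted to dB, with age, drug and centred
#' natural-log frequency.
#'
#' @param features A [cohort_features()] object.
#' @param fmin,fmax Frequency range retained (Hz).
#' @param decimate Keep every k-th frequency bin (1 = all).
#' @return Data frame: patient_id, freq_hz, log_power_db, age_yr, drug,
#'   log_freq, log_freq_c (centred at the sample mean). Zero-power bins
#'   are dropped with a message when present.
#' @export
build_long_power_table <- function(features, fmin = 1, fmax = 30,
                                   decimate = 1) {
  f <- features$freqs_hz
  sel <- which(f >= fmin & f <= fmax)
  sel <- sel[seq(1, length(sel), by = decimate)]
  n <- nrow(features$meta)
  tab <- data.frame(
    patient_id = rep(features$meta$patient_id, each = length(sel)),
    freq_hz = rep(f[sel], times = n),
    power = as.vector(t(features$psd_mean[, sel, drop = FALSE])),
    age_yr = rep(features$meta$age_yr, each = length(sel)),
    drug = rep(features$meta$drug, each = length(sel)),
    stringsAsFactors = FALSE)
  bad <- tab$power <= 0
  if (any(bad)) {
    message(sum(bad), " zero-power rows dropped")
    tab <- tab[!bad, ]
  }
  tab$log_power_db <- power_to_db(tab$power)
  tab$log_freq <- log(tab$freq_hz)
  tab$log_freq_c <- tab$log_freq - mean(tab$log_freq)
  tab$power <- NULL
  tab
}

#' Mixed-effects model of log EEG power across age and frequency
#'
#' Regresses log power (dB) on age, centred log frequency and their
#' interaction with patient-varying intercepts (REML). With
#' `with_drug_terms = TRUE` drug type and all its interactions are
#' added, so the drug main effect is the sevoflurane-propofol offset at
#' the reference (mean) log frequency. Confidence intervals are Wald
#' intervals.
#'
#' @param table A [build_long_power_table()] result.
#' @param with_drug_terms Include drug type and its interactions.
#' @param conf_level Confidence level for the Wald intervals.
#' @return Object of class `power_lmm`: `coefficients` data frame (term,
#'   estimate, se, stat, ci_low, ci_high), `ranef_sd`, `fit` (the lme4
#'   fit, or an `lm` fallback when the random-intercept fit is
#'   singular/degenerate, flagged by `fallback_ols`).
#' @export
fit_power_lmm <- function(table, with_drug_terms = FALSE,
                          conf_level = 0.95) {
  if (length(unique(table$patient_id)) < 2 ||
      length(unique(table$freq_hz)) < 2)
    stop_arg("need at least 2 patients and 2 frequencies")
  table$age_c <- table$age_yr - mean(table$age_yr)
  fallback <- FALSE
  if (with_drug_terms) {
    table$drug <- factor(table$drug, levels = c("propofol", "sevoflurane"))
    form <- log_power_db ~ age_c * log_freq_c * drug + (1 | patient_id)
    form_ols <- log_power_db ~ age_c * log_freq_c * drug
  } else {
    form <- log_power_db ~ age_c * log_freq_c + (1 | patient_id)
    form_ols <- log_power_db ~ age_c * log_freq_c
  }
  fit <- tryCatch(
    lme4::lmer(form, data = table, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular =
                 lme4::.makeCC(action = "ignore", tol = 1e-4))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("random-intercept fit failed; falling back to fixed ",
            "intercepts (OLS)", call. = FALSE)
    fit <- lm(form_ols, data = table)
    fallback <- TRUE
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    ranef_sd <- NA_real_
  } else {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    ranef_sd <- sqrt(unlist(lme4::VarCorr(fit))[[1]])
  }
  zc <- qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), stat = unname(est / se),
                      ci_low = unname(est - zc * se),
                      ci_high = unname(est + zc * se),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, ranef_sd = ranef_sd, fit = fit,
                 fallback_ols = fallback, conf_level = conf_level),
            class = "power_lmm")
}

#' @export
print.power_lmm <- function(x, digits = 3, ...) {
  cat("<power_lmm> log EEG power (dB) ~ age x log frequency",
      if (x$fallback_ols) "(OLS fallback)" else
        sprintf("+ (1 | patient), intercept SD %.2f dB", x$ranef_sd), "\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Assemble the burst-suppression modelling table
#'
#' Scales age and brain age and binarises ASA (1-2 vs 3) for the
#' burst-suppression model. By default predictors are z-scored within
#' the analysis sample; explicit centres/scales may be supplied instead
#' (e.g. to match a generator's scaling in recovery studies).
#'
#' @param bs_proportion Proportion of the recording in burst suppression
#'   per patient, in `[0, 1]`.
#' @param age_yr,brain_age_yr Chronological and predicted (or latent)
#'   brain age in years.
#' @param asa ASA physical status (1, 2 or 3).
#' @param patient_id Optional identifiers.
#' @param scaling `"sample"` for in-sample z-scoring, or a list with
#'   `age_center`, `age_scale`, `brainage_center`, `brainage_scale`.
#' @return Data frame: patient_id, bs_proportion, age_scaled,
#'   brain_age_scaled, asa_binary; the brain-age SD used is stored in
#'   `attr(, "brain_age_sd")`.
#' @export
build_bs_table <- function(bs_proportion, age_yr, brain_age_yr, asa,
                           patient_id = NULL, scaling = "sample") {
  if (any(bs_proportion < 0 | bs_proportion > 1))
    stop_arg("bs_proportion must lie in [0, 1]")
  if (identical(scaling, "sample")) {
    scaling <- list(age_center = mean(age_yr), age_scale = sd(age_yr),
                    brainage_center = mean(brain_age_yr),
                    brainage_scale = sd(brain_age_yr))
  }
  tab <- data.frame(
    patient_id = patient_id %||% paste0("P", seq_along(age_yr)),
    bs_proportion = bs_proportion,
    age_scaled = (age_yr - scaling$age_center) / scaling$age_scale,
    brain_age_scaled =
      (brain_age_yr - scaling$brainage_center) / scaling$brainage_scale,
    asa_binary = as.integer(asa >= 3),
    stringsAsFactors = FALSE)
  attr(tab, "brain_age_sd") <- scaling$brainage_scale
  tab
}

#' Burst-suppression model: logit of the suppressed proportion
#'
#' Models the logit of the burst-suppression proportion as a weighted
#' sum of scaled age, scaled brain age, binarised ASA, and the
#' interactions of age and brain age with ASA. Because age is in the
#' model, the brain-age coefficient is conditional on age: it captures
#' the age-prediction error of the machine-learning model. The default
#' estimator is a quasi-binomial GLM with logit link; because patient
#' variability of suppression acts multiplicatively on the odds rather
#' than binomially, inference uses heteroscedasticity-robust (HC1)
#' standard errors by default. An ordinary-least-squares fit on
#' empirical logits `log((p + eps) / (1 - p + eps))` is available via
#' `method`; note that its epsilon adjustment compresses the logit for
#' proportions near zero and attenuates coefficients when many
#' proportions are small.
#'
#' @param table A [build_bs_table()] result.
#' @param method `"quasibinomial"` (default) or `"empirical_logit"`.
#' @param robust Use HC1 sandwich standard errors (quasi-binomial
#'   method only).
#' @param eps Adjustment constant for the empirical logit.
#' @param weights Optional observation weights (e.g. recording
#'   durations).
#' @param conf_level Confidence level.
#' @return Object of class `bs_fit`: `coefficients` data frame (term,
#'   estimate, se, stat, df, p, ci_low, ci_high, odds_ratio), `method`,
#'   `fit`.
#' @export
fit_bs_model <- function(table, method = c("quasibinomial",
                                           "empirical_logit"),
                         robust = TRUE, eps = 0.01, weights = NULL,
                         conf_level = 0.95) {
  method <- match.arg(method)
  form <- ~ age_scaled * asa_binary + brain_age_scaled * asa_binary
  if (is.null(weights)) weights <- rep(1, nrow(table))
  tab <- table
  if (method == "empirical_logit") {
    tab$y <- log((tab$bs_proportion + eps) / (1 - tab$bs_proportion + eps))
    fit <- lm(update(form, y ~ .), data = tab, weights = weights)
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    df <- fit$df.residual
  } else {
    if (all(tab$bs_proportion %in% c(0, 1))) {
      warning("degenerate all-0/1 proportions; epsilon-adjusted",
              call. = FALSE)
      tab$bs_proportion <- pmin(pmax(tab$bs_proportion, eps), 1 - eps)
    }
    fit <- glm(update(form, bs_proportion ~ .), data = tab,
               family = quasibinomial("logit"), weights = weights)
    est <- coef(fit)
    se <- sqrt(diag(if (robust) sandwich::vcovHC(fit, type = "HC1")
                    else vcov(fit)))
    df <- fit$df.residual
  }
  tc <- qt(1 - (1 - conf_level) / 2, df)
  stat <- est / se
  coefs <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    stat = unname(stat), df = df,
    p = unname(2 * (1 - stats::pt(abs(stat), df))),
    ci_low = unname(est - tc * se), ci_high = unname(est + tc * se),
    odds_ratio = exp(unname(est)), stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, method = method, fit = fit,
                 brain_age_sd = attr(table, "brain_age_sd"),
                 conf_level = conf_level),
            class = "bs_fit")
}

#' @export
print.bs_fit <- function(x, digits = 3, ...) {
  cat("<bs_fit> logit(burst-suppression proportion), method:",
      x$method, "\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Odds-ratio transform of a logistic coefficient
#'
#' `exp(beta)` is the multiplicative change in the odds of burst
#' suppression per unit of the (scaled) predictor; the percent form is
#' `100 * (exp(beta) - 1)`.
#'
#' @param beta Coefficient on the logit scale.
#' @return List with `odds_ratio` and `percent_change`.
#' @export
#' @examples
#' odds_ratio(0.85)   # 2.34, +134%
#' odds_ratio(-0.99)  # 0.37, -63%
odds_ratio <- function(beta) {
  if (!all(is.finite(beta))) stop_arg("beta must be finite")
  list(odds_ratio = exp(beta), percent_change = 100 * (exp(beta) - 1))
}
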
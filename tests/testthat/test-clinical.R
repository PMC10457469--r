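## feature stub with a known channel-mean PSD
psd_stub <- function(n_pat, psd_value = 1) {
  f <- seq(0, 30, by = 0.25)
  structure(list(
    meta = data.frame(patient_id = sprintf("P%02d", seq_len(n_pat)),
                      age_yr = seq(20, 80, length.out = n_pat),
                      drug = "propofol", asa = 1,
                      stringsAsFactors = FALSE),
    psd_mean = matrix(psd_value, n_pat, length(f)),
    freqs_hz = f), class = "cohort_features")
}

test_that("long power table has one row per patient and frequency bin", {
  tab <- build_long_power_table(psd_stub(170))
  expect_equal(nrow(tab), 170 * 117)        # 1-30 Hz on a 0.25 Hz grid
  expect_equal(length(unique(tab$freq_hz)), 117)
  ## dB reference: power 1 uV^2/Hz -> 0 dB; doubling -> +3.0103 dB
  expect_true(all(tab$log_power_db == 0))
  tab2 <- build_long_power_table(psd_stub(3, psd_value = 2))
  expect_equal(unique(tab2$log_power_db), 10 * log10(2), tolerance = 1e-12)
})

test_that("dB conversion round-trips", {
  x <- c(1e-3, 0.5, 1, 7.3, 1e4)
  expect_equal(db_to_power(power_to_db(x)), x, tolerance = 1e-12)
})

## simulate a long table directly from the mixed model
simulate_power_table <- function(n_pat, beta_age = -0.10, beta_lf = -9,
                                 beta_int = 0.01, sd_pat = 1.5,
                                 sd_res = 0.8, seed = 1) {
  set.seed(seed)
  f <- seq(1, 30, by = 0.25)
  lf <- log(f); lfc <- lf - mean(lf)
  age <- runif(n_pat, 18, 90)
  u <- rnorm(n_pat, 0, sd_pat)
  do.call(rbind, lapply(seq_len(n_pat), function(i) {
    data.frame(patient_id = paste0("P", i), freq_hz = f,
               log_power_db = 10 + u[i] + beta_age * (age[i] - 54) +
                 beta_lf * lfc + beta_int * (age[i] - 54) * lfc +
                 rnorm(length(f), 0, sd_res),
               age_yr = age[i], drug = "propofol",
               log_freq = lf, log_freq_c = lfc,
               stringsAsFactors = FALSE)
  }))
}

test_that("the mixed model recovers simulated fixed effects", {
  tab <- simulate_power_table(120, seed = 2)
  fit <- fit_power_lmm(tab)
  cf <- fit$coefficients
  age_row <- cf[cf$term == "age_c", ]
  expect_lt(age_row$ci_low, -0.10)
  expect_gt(age_row$ci_high, -0.10)
  lf_row <- cf[cf$term == "log_freq_c", ]
  expect_equal(lf_row$estimate, -9, tolerance = 0.05)
  expect_equal(fit$ranef_sd, 1.5, tolerance = 0.35)
})

test_that("with no patient heterogeneity the LMM equals OLS", {
  tab <- simulate_power_table(40, sd_pat = 0, seed = 3)
  fit <- suppressMessages(fit_power_lmm(tab))
  ols <- lm(log_power_db ~ I(age_yr - mean(age_yr)) * log_freq_c, data = tab)
  expect_equal(unname(fit$coefficients$estimate),
               unname(coef(ols)), tolerance = 1e-6)
})

test_that("degenerate input errors are informative", {
  tab <- simulate_power_table(1)
  expect_error(fit_power_lmm(tab), "at least 2")
})

test_that("burst-suppression model recovers a simulated logistic truth", {
  set.seed(4)
  n <- 204
  age <- runif(n, 18, 90)
  ba <- age + rnorm(n, 0, 8)
  asa <- rbinom(n, 1, 0.33) * 2 + 1        # 1 vs 3
  age_s <- (age - 54) / 20.78
  ba_s <- (ba - 54) / 16
  asa_b <- as.integer(asa >= 3)
  p <- plogis(-3.2 + 0.4 * age_s + 0.85 * ba_s + 0.5 * asa_b -
                0.99 * ba_s * asa_b + rnorm(n, 0, 0.3))
  tab <- build_bs_table(p, age, ba, asa,
                        scaling = list(age_center = 54, age_scale = 20.78,
                                       brainage_center = 54,
                                       brainage_scale = 16))
  fit <- fit_bs_model(tab)
  cf <- fit$coefficients
  ba_row <- cf[cf$term == "brain_age_scaled", ]
  int_row <- cf[cf$term == "asa_binary:brain_age_scaled", ]
  expect_lt(abs(ba_row$estimate - 0.85), 2 * ba_row$se)
  expect_lt(abs(int_row$estimate + 0.99), 2 * int_row$se)
  expect_equal(ba_row$odds_ratio, exp(ba_row$estimate))
})

test_that("quasi-binomial estimator gives consistent point estimates", {
  set.seed(5)
  n <- 300
  age <- runif(n, 18, 90)
  ba <- age + rnorm(n, 0, 8)
  asa <- rep(c(1, 3), length.out = n)
  tab <- build_bs_table(
    plogis(-2 + 0.8 * (ba - 54) / 16), age, ba, asa,
    scaling = list(age_center = 54, age_scale = 20.78,
                   brainage_center = 54, brainage_scale = 16))
  fit <- fit_bs_model(tab, method = "quasibinomial")
  ba_row <- fit$coefficients[fit$coefficients$term == "brain_age_scaled", ]
  expect_equal(ba_row$estimate, 0.8, tolerance = 0.1)
})

test_that("rescaling a predictor rescales its coefficient and nothing else", {
  set.seed(6)
  n <- 80
  age <- runif(n, 18, 90); ba <- age + rnorm(n, 0, 8)
  asa <- rep(c(1, 3), length.out = n)
  p <- plogis(-2 + 0.03 * (ba - 54))
  base <- list(age_center = 54, age_scale = 20.78,
               brainage_center = 54, brainage_scale = 16)
  tab1 <- build_bs_table(p, age, ba, asa, scaling = base)
  sc2 <- base; sc2$brainage_scale <- 16 * 3
  tab2 <- build_bs_table(p, age, ba, asa, scaling = sc2)
  f1 <- fit_bs_model(tab1); f2 <- fit_bs_model(tab2)
  b1 <- f1$coefficients[f1$coefficients$term == "brain_age_scaled",
                        "estimate"]
  b2 <- f2$coefficients[f2$coefficients$term == "brain_age_scaled",
                        "estimate"]
  expect_equal(b2, 3 * b1, tolerance = 1e-6)
  expect_equal(fitted(f1$fit), fitted(f2$fit), tolerance = 1e-6)
})

test_that("odds-ratio transforms match the printed derivations", {
  expect_equal(odds_ratio(0.85)$odds_ratio, 2.34, tolerance = 0.005)
  expect_equal(odds_ratio(0.85)$percent_change, 134, tolerance = 0.005)
  expect_equal(odds_ratio(-0.99)$odds_ratio, 0.37, tolerance = 0.005)
  expect_equal(odds_ratio(-0.99)$percent_change, -63, tolerance = 0.01)
  expect_equal(odds_ratio(0)$odds_ratio, 1)
  expect_error(odds_ratio(Inf), "finite")
})
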
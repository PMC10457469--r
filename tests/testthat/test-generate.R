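test_that("the same seed regenerates a patient bit-identically", {
  spec <- tiny_spec(120)
  tr <- generator_truth()
  a <- generate_patient(spec, tr, 99)
  b <- generate_patient(spec, tr, 99)
  expect_identical(a$record$signal, b$record$signal)
  expect_identical(a$truth, b$truth)
  c_ <- generate_patient(spec, tr, 100)
  expect_false(identical(a$record$signal, c_$record$signal))
})

test_that("injected suppression time matches the target proportion", {
  spec <- tiny_spec(300)
  ## force the proportion to exactly 0.10 via a degenerate logistic model
  tr <- generator_truth(bs_logit_coefs = c(intercept = qlogis(0.10), age = 0,
                                           brainage = 0, asa = 0,
                                           brainage_asa = 0),
                        bs_logit_noise_sd = 0)
  pt <- generate_patient(spec, tr, 5, with_artifacts = FALSE)
  expect_equal(pt$truth$true_bs_proportion, 0.10, tolerance = 1e-12)
  injected <- sum(pt$bs_intervals[, 2] - pt$bs_intervals[, 1])
  expect_equal(injected, 30, tolerance = 1e-6)
  expect_equal(burst_suppression_ratio(pt$record), 0.10, tolerance = 0.01)
})

test_that("welch spectrum of a clean record tracks the analytic target", {
  ## spectral-fidelity invariant: <= 1 dB at every 1-30 Hz grid frequency
  spec <- tiny_spec(600)
  tr <- generator_truth()
  for (s in 1:5) {
    pt <- generate_patient(spec, tr, 200 + s, with_bs = FALSE,
                           with_artifacts = FALSE)
    w <- welch_psd(pt$record$signal, spec$fs_hz)
    sel <- w$freqs_hz >= 1 & w$freqs_hz <= 30
    emp <- power_to_db(colMeans(w$psd)[sel])
    tgt <- patient_target_spectrum(w$freqs_hz[sel], pt$truth, tr)
    expect_lt(max(abs(emp - tgt)), 1)
  }
})

test_that("cohort-averaged spectra converge on the per-patient targets", {
  spec <- tiny_spec(600)
  tr <- generator_truth()
  devs <- vapply(1:10, function(i) {
    pt <- generate_patient(spec, tr, 300 + i, with_bs = FALSE,
                           with_artifacts = FALSE)
    w <- welch_psd(pt$record$signal, spec$fs_hz)
    sel <- w$freqs_hz >= 1 & w$freqs_hz <= 30
    power_to_db(colMeans(w$psd)[sel]) -
      patient_target_spectrum(w$freqs_hz[sel], pt$truth, tr)
  }, numeric(117))
  expect_lt(mean(abs(rowMeans(devs))), 0.5)
})

test_that("band covariances of generated records are symmetric positive definite", {
  ft <- clean_features()
  for (b in 1:5) {
    C <- ft$cov_set$cov[b, , ]
    expect_equal(C, t(C))
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("generate_cohort returns matching records, metadata and truth", {
  spec <- cohort_spec(n_patients = 3, seed = 21, duration_s = 60)
  out <- generate_cohort(spec, generator_truth())
  expect_length(out$records, 3)
  expect_equal(nrow(out$metadata), 3)
  expect_equal(nrow(out$truth), 3)
  expect_identical(out$metadata$patient_id, out$truth$patient_id)
  ## regeneration is deterministic
  out2 <- generate_cohort(spec, generator_truth())
  expect_identical(out$records[[2]]$signal, out2$records[[2]]$signal)
})

test_that("null logistic model yields the intercept proportion on average", {
  spec <- cohort_spec(n_patients = 200, seed = 31, duration_s = 60)
  tr <- generator_truth(bs_logit_coefs = c(intercept = qlogis(0.2), age = 0,
                                           brainage = 0, asa = 0,
                                           brainage_asa = 0),
                        bs_logit_noise_sd = 0)
  out <- generate_cohort(spec, tr, keep_signals = FALSE)
  expect_equal(mean(out$truth$true_bs_proportion), 0.2, tolerance = 0.05)
})

test_that("generator encodes the burst-suppression logistic model exactly", {
  ## qlogis(true proportion) must equal the linear predictor built from
  ## the ground-truth row, so one SD (16 yr) of brain age multiplies the
  ## odds by exp(0.85) = 2.34 by construction
  spec <- cohort_spec(n_patients = 50, seed = 13, duration_s = 60)
  tr <- generator_truth(bs_logit_noise_sd = 0)
  out <- generate_cohort(spec, tr, keep_signals = FALSE)
  cf <- tr$bs_logit_coefs
  tt <- out$truth
  age_s <- (tt$age_yr - tr$bs_age_center) / tr$bs_age_scale
  ba_s <- (tt$age_yr + tt$latent_brainage_offset_yr - tr$bs_brainage_center) /
    tr$bs_brainage_scale
  asa_b <- as.integer(tt$asa >= 3)
  lin <- cf[["intercept"]] + cf[["age"]] * age_s + cf[["brainage"]] * ba_s +
    cf[["asa"]] * asa_b + cf[["brainage_asa"]] * ba_s * asa_b
  expect_equal(qlogis(tt$true_bs_proportion), lin, tolerance = 1e-10)
  expect_equal(exp(cf[["brainage"]]), 2.34, tolerance = 0.005)
})

test_that("artifact transients exceed the high-amplitude rejection bound", {
  spec <- tiny_spec(300)
  tr <- generator_truth(artifact_rate_per_min = 2)
  pt <- generate_patient(spec, tr, 77, with_bs = FALSE)
  expect_gt(length(pt$artifact_s), 0)
  es <- epoch_record(pt$record)
  hit <- vapply(pt$artifact_s, function(t0)
    which(es$onsets_s <= t0 & es$onsets_s + es$win_s > t0)[1], 1L)
  expect_true(all(apply(es$ptp[unique(hit), , drop = FALSE], 1, max) > 250))
})
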
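test_that("feature bundle dimensions are 1/1/16/50", {
  ft <- clean_features()
  fb <- make_feature_bundle(ft$psd_grid, ft$cov_set)
  expect_length(fb$total_power, 1)
  expect_length(fb$alpha_power, 1)
  expect_length(fb$spectrum, 16)
  expect_length(fb$spatial, 50)
  expect_true(all(is.finite(unlist(fb[c("total_power", "alpha_power",
                                        "spectrum", "spatial")]))))
})

test_that("identical channels give rank-one band covariances", {
  set.seed(9)
  v <- rnorm(200 * 63, sd = 10)
  rec <- eeg_record(matrix(rep(v, 4), 4, byrow = TRUE), 63)
  es <- compute_sef95(reject_epochs(epoch_record(rec), exclude_bs = FALSE))
  seg <- select_stable_segment(es, band = c(0, 31))
  cs <- band_covariances(es, seg)
  for (b in 1:5) {
    C <- cs$cov[b, , ]
    expect_equal(max(C), min(C), tolerance = 1e-8 * max(C))
  }
})

test_that("independent channels have near-zero band correlations", {
  rec <- noise_record(600, sd = 10, seed = 10)
  es <- compute_sef95(reject_epochs(epoch_record(rec), exclude_bs = FALSE))
  seg <- select_stable_segment(es, band = c(0, 31))
  cs <- band_covariances(es, seg)
  for (b in 2:5) {                       # skip tiny low band (few bins)
    C <- cs$cov[b, , ]
    r <- C[upper.tri(C)] / sqrt(outer(diag(C), diag(C))[upper.tri(C)])
    expect_lt(max(abs(r)), 0.05)
  }
})

test_that("a 10-Hz line loads on the alpha band only", {
  tt <- seq_len(300 * 63) / 63
  set.seed(11)
  sig <- matrix(rep(20 * sin(2 * pi * 10 * tt), 4), 4, byrow = TRUE) +
    matrix(rnorm(4 * length(tt), sd = 0.5), 4)
  rec <- eeg_record(sig, 63)
  es <- compute_sef95(reject_epochs(epoch_record(rec), exclude_bs = FALSE))
  seg <- select_stable_segment(es, band = c(0, 31))
  cs <- band_covariances(es, seg)
  alpha_p <- mean(diag(cs$cov["alpha", , ]))
  for (b in c("low", "delta", "theta", "beta"))
    expect_gt(alpha_p / mean(diag(cs$cov[b, , ])), 10)
})

test_that("band-covariance diagonals integrate the PSD over the band", {
  ft <- clean_features()
  f <- ft$psd_grid$freqs_hz
  df <- f[2] - f[1]
  bands <- eeg_bands()
  for (b in seq_len(nrow(bands))) {
    sel <- f > bands$fmin[b] & f <= bands$fmax[b]
    for (ch in 1:4)
      expect_equal(unname(ft$cov_set$cov[b, ch, ch]),
                   sum(ft$psd_grid$psd[ch, sel]) * df, tolerance = 1e-10)
  }
})

test_that("tangent features vanish at their own reference", {
  ft <- clean_features()
  refs <- lapply(1:5, function(b)
    oas_shrinkage(ft$cov_set$cov[b, , ], ft$cov_set$n_obs))
  fb <- make_feature_bundle(ft$psd_grid, ft$cov_set, tangent_reference = refs)
  expect_lt(max(abs(fb$spatial)), 1e-8)
})

test_that("doubling the amplitude shifts log features by log(4)", {
  pt <- clean_patient()
  rec2 <- pt$record
  rec2$signal <- rec2$signal * 2
  ft1 <- clean_features()
  ft2 <- extract_features(rec2)
  fb1 <- make_feature_bundle(ft1$psd_grid, ft1$cov_set)
  fb2 <- make_feature_bundle(ft2$psd_grid, ft2$cov_set)
  expect_equal(fb2$total_power - fb1$total_power, log(4), tolerance = 1e-6)
  expect_equal(fb2$alpha_power - fb1$alpha_power, log(4), tolerance = 1e-6)
  expect_equal(unname(fb2$spectrum - fb1$spectrum), rep(log(4), 16),
               tolerance = 1e-6)
  ## at the identity reference, logm(4C) = logm(C) + log(4) I: diagonal
  ## tangent entries shift, off-diagonals stay
  d_spatial <- fb2$spatial - fb1$spatial
  diag_idx <- as.vector(outer(1:4, (0:4)[1:5] * 10, `+`))
  expect_equal(unname(d_spatial[diag_idx]), rep(log(4), 20),
               tolerance = 1e-4)
  expect_lt(max(abs(d_spatial[-diag_idx])), 1e-4)
})

test_that("channel permutation preserves channel-averaged features", {
  pt <- clean_patient()
  perm <- c(3, 1, 4, 2)
  rec_p <- pt$record
  rec_p$signal <- rec_p$signal[perm, ]
  ft1 <- clean_features()
  ft2 <- extract_features(rec_p)
  fb1 <- make_feature_bundle(ft1$psd_grid, ft1$cov_set)
  fb2 <- make_feature_bundle(ft2$psd_grid, ft2$cov_set)
  expect_equal(fb1$total_power, fb2$total_power, tolerance = 1e-9)
  expect_equal(fb1$spectrum, fb2$spectrum, tolerance = 1e-9)
  ## spatial features are permuted consistently: same multiset of values
  expect_equal(sort(fb1$spatial), sort(fb2$spatial), tolerance = 1e-6)
})

test_that("mean of per-epoch covariances matches the whole-segment covariance", {
  rec <- noise_record(300, sd = 10, seed = 12)
  es <- compute_sef95(reject_epochs(epoch_record(rec), exclude_bs = FALSE))
  seg <- select_stable_segment(es, band = c(0, 31))
  cs <- band_covariances(es, seg)
  whole <- welch_cross(rec$signal, 63)
  f <- whole$freqs_hz; df <- f[2] - f[1]
  bands <- eeg_bands()
  for (b in c(2, 4)) {
    sel <- f > bands$fmin[b] & f <= bands$fmax[b]
    Cw <- apply(whole$csd[, , sel], c(1, 2), sum) * df
    expect_equal(diag(cs$cov[b, , ]), diag(Cw), tolerance = 0.1)
  }
})

test_that("the sixteen spectrum frequencies are unique and span 1-30 Hz", {
  f <- seq(0, 31.5, by = 0.25)
  sf <- eegbrainage:::spectrum_feature_freqs(f)
  expect_length(unique(sf), 16)
  expect_equal(sf[1], 1)
  expect_equal(sf[16], 30)
})

test_that("zero power raises an informative error", {
  ft <- clean_features()
  bad <- ft$psd_grid
  bad$channel_mean[] <- 0
  expect_error(make_feature_bundle(bad, ft$cov_set), "zero power")
})
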
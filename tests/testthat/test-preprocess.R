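test_that("epoch counts follow the sliding-window formula", {
  expect_equal(epoch_record(noise_record(600))$n_epochs, 55)
  expect_equal(epoch_record(noise_record(60))$n_epochs, 1)
  expect_warning(es <- epoch_record(noise_record(59)), "shorter")
  expect_equal(es$n_epochs, 0)
  ## property: floor((T - 60)/10) + 1 over random durations
  set.seed(4)
  for (dur in sample(60:900, 25)) {
    rec <- eeg_record(matrix(rnorm(4 * dur * 63), 4), 63)
    expect_equal(epoch_record(rec)$n_epochs, floor((dur - 60) / 10) + 1)
  }
})

test_that("epoching does not mutate the raw signal", {
  rec <- noise_record(120)
  orig <- rec$signal
  es <- epoch_record(rec)
  es <- reject_epochs(es)
  es <- compute_sef95(es)
  invisible(select_stable_segment(es))
  expect_identical(rec$signal, orig)
})

test_that("amplitude-based rejection catches flat and artifactual epochs", {
  rec <- noise_record(200, sd = 10)
  rec$signal[2, 1:(63 * 70)] <- 0                 # one flat channel early
  rec$signal[3, 63 * 120 + 1:40] <-
    rec$signal[3, 63 * 120 + 1:40] + 400          # artifact at 120 s
  es <- reject_epochs(epoch_record(rec), exclude_bs = FALSE)
  ## epochs lying entirely inside the flat span have ptp = 0 on channel 2
  flat_epochs <- which(es$onsets_s + 60 <= 70)
  expect_true(all(!es$retained[flat_epochs]))
  art_epochs <- which(es$onsets_s <= 120 & es$onsets_s + 60 > 120)
  expect_true(all(!es$retained[art_epochs]))
  others <- setdiff(seq_len(es$n_epochs), c(flat_epochs, art_epochs))
  expect_true(all(es$retained[others]))
})

test_that("clean generated epochs are fully retained", {
  pre <- preprocess_record(clean_patient()$record)
  expect_true(all(pre$epochs$retained))
  expect_equal(pre$segment$n_epochs, pre$epochs$n_epochs)
})

test_that("SEF95 matches analytic oracles for known spectra", {
  tt <- seq_len(3780) / 63
  x10 <- matrix(rep(sin(2 * pi * 10 * tt), 4), 4, byrow = TRUE)
  expect_lt(abs(sef95(x10, 63)$mean - 10), 0.25 + 1e-9)

  ## flat spectrum: SEF95 = fmin + 0.95 (fmax - fmin) = 28.5 Hz on the grid
  set.seed(8)
  xw <- matrix(rnorm(4 * 600 * 63), 4)
  expect_lt(abs(sef95(xw, 63)$mean - 28.5), 0.25 + 1e-9)

  ## 90% power at 5 Hz, 10% at 20 Hz: the 95% threshold is crossed only
  ## at the upper line
  xm <- matrix(rep(3 * sin(2 * pi * 5 * tt) + sin(2 * pi * 20 * tt), 4),
               4, byrow = TRUE)
  expect_lt(abs(sef95(xm, 63)$mean - 20), 0.25 + 1e-9)
})

test_that("SEF95 is monotone under upward shifts of spectral mass", {
  tt <- seq_len(3780) / 63
  vals <- vapply(seq(3, 27, by = 2), function(f0)
    sef95(matrix(rep(sin(2 * pi * f0 * tt), 4), 4, byrow = TRUE), 63)$mean,
    numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("zero-power epochs are marked invalid and rejected", {
  rec <- noise_record(80)
  rec$signal[] <- 0
  es <- reject_epochs(epoch_record(rec), exclude_bs = FALSE)
  es <- compute_sef95(es)
  expect_true(all(is.na(es$sef95_mean)))
  expect_true(all(!es$retained))
})

test_that("stable-segment selection returns the longest in-band run", {
  seg <- select_stable_segment(fake_eset(c(7, 9, 10, 12, 14, 9, 9)))
  expect_equal(c(seg$first_epoch, seg$last_epoch, seg$n_epochs), c(2, 4, 3))

  all_in <- select_stable_segment(fake_eset(rep(10, 6)))
  expect_equal(all_in$n_epochs, 6)

  ## equal-length runs: the earlier one wins
  tie <- select_stable_segment(fake_eset(c(9, 9, 9, 20, 10, 10, 10)))
  expect_equal(c(tie$first_epoch, tie$last_epoch), c(1, 3))

  expect_null(select_stable_segment(fake_eset(c(5, 6, 20))))
})

test_that("a rejected epoch breaks a stable run", {
  es <- fake_eset(rep(10, 7), retained = c(TRUE, TRUE, FALSE, rep(TRUE, 4)))
  seg <- select_stable_segment(es)
  expect_equal(c(seg$first_epoch, seg$last_epoch), c(4, 7))
})

test_that("stable-segment choice ignores epochs outside the selected run", {
  base <- fake_eset(c(7, 9, 10, 12, 14, 9, 9))
  seg1 <- select_stable_segment(base)
  pert <- base
  pert$sef95_mean[c(1, 5)] <- c(3, 25)            # out-of-band stays out
  seg2 <- select_stable_segment(pert)
  expect_equal(seg1[c("first_epoch", "last_epoch")],
               seg2[c("first_epoch", "last_epoch")])
})

test_that("burst-suppression ratio spans its range", {
  rec <- noise_record(120, sd = 10)
  expect_equal(burst_suppression_ratio(rec), 0)
  flat <- rec; flat$signal <- flat$signal * 0.01
  expect_equal(burst_suppression_ratio(flat), 1)
})

test_that("epochs overlapping detected suppression are excluded", {
  pt <- noisy_patient()
  es <- reject_epochs(epoch_record(pt$record), exclude_bs = TRUE)
  expect_gt(sum(es$bs_overlap), 0)
  expect_true(all(!es$retained[es$bs_overlap]))
  ## overlap flags agree with the injected intervals
  inj <- pt$bs_intervals
  truth_ov <- vapply(seq_len(es$n_epochs), function(i)
    any(es$onsets_s[i] < inj[, 2] & es$onsets_s[i] + 60 > inj[, 1]),
    logical(1))
  expect_equal(es$bs_overlap, truth_ov)
})
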
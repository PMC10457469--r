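test_that("monte carlo splits are reproducible and sized correctly", {
  s1 <- mc_splits(170, n_splits = 100, seed = 3)
  s2 <- mc_splits(170, n_splits = 100, seed = 3)
  expect_length(s1, 100)
  expect_identical(s1, s2)
  expect_true(all(vapply(s1, length, 1L) == 17))
  expect_false(identical(s1, mc_splits(170, n_splits = 100, seed = 4)))
})

test_that("crossval_scores returns one row per split", {
  feats <- toy_features(80)
  splits <- mc_splits(80, n_splits = 100, seed = 5)
  sc <- crossval_scores(feats, model = "total_power", splits = splits)
  expect_equal(nrow(sc), 100)
  expect_equal(sc$split, 1:100)
  expect_true(all(sc$mae >= 0))
})

test_that("dummy scores match the analytic mean-absolute-deviation oracle", {
  ## ages uniform on [18, 90]: E|X - mean| = range/4 = 18 yr; averaged
  ## over several age draws (one n=170 sample has SE ~0.8 yr)
  set.seed(20)
  age_draws <- replicate(5, runif(170, 18, 90), simplify = FALSE)
  maes <- vapply(1:5, function(r) {
    ages <- age_draws[[r]]
    feats <- structure(list(meta = data.frame(age_yr = ages)),
                       class = "cohort_features")
    sc <- crossval_scores(feats, model = "dummy",
                          splits = mc_splits(170, 20, seed = r))
    ## per-cohort CV mean tracks that sample mean absolute deviation
    expect_equal(mean(sc$mae), mean(abs(ages - mean(ages))),
                 tolerance = 0.1)
    mean(sc$mae)
  }, numeric(1))
  expect_equal(mean(maes), 18, tolerance = 1 / 18)
})

test_that("pairwise comparison counts and percentiles follow the oracles", {
  mk <- function(mae, model) {
    out <- data.frame(model = model, split = seq_along(mae), mae = mae,
                      r2 = NA_real_)
    class(out) <- c("cv_scores", "data.frame")
    out
  }
  cmp <- compare_models(mk(c(1, 2, 3), "a"), mk(c(2, 3, 4), "b"))
  expect_equal(cmp$superiority, 3)
  expect_equal(cmp$delta_median, -1)

  same <- compare_models(mk(c(5, 5, 5), "a"), mk(c(5, 5, 5), "b"))
  expect_equal(same$superiority, 0)     # ties are "not better"
  expect_true(all(same$delta_percentiles == 0))

  ## linear-interpolation percentile convention on deltas 1..100
  cmp2 <- compare_models(mk(1:100 + 10, "a"), mk(rep(10, 100), "b"))
  expect_equal(unname(cmp2$delta_percentiles[["25%"]]), 25.75)
  expect_equal(unname(cmp2$delta_percentiles[["75%"]]), 75.25)

  expect_error(compare_models(mk(1:3, "a"), mk(1:4, "b")), "split")
})

test_that("paired splits give identical test sets across models", {
  feats <- toy_features(60)
  splits <- mc_splits(60, n_splits = 10, seed = 7)
  a <- crossval_scores(feats, model = "total_power", splits = splits)
  b <- crossval_scores(feats, model = "alpha_power", splits = splits)
  expect_identical(a$split, b$split)
  cmp <- compare_models(b, a)
  expect_equal(cmp$n_splits, 10)
})

test_that("brain-age table separates out-of-fold and extrapolated sources", {
  feats <- toy_features(90)
  tab <- predict_brain_age(feats, train_idx = 1:60, apply_idx = 61:90,
                           model = "total_power")
  expect_equal(nrow(tab), 90)
  expect_equal(sum(tab$source == "cross_validated"), 60)
  expect_equal(sum(tab$source == "extrapolated"), 30)
  tab0 <- predict_brain_age(feats, train_idx = 1:60,
                            model = "total_power")
  expect_true(all(tab0$source == "cross_validated"))
  expect_error(predict_brain_age(feats, train_idx = 1:60,
                                 apply_idx = 60:70), "overlap")
})

test_that("pooled per-drug sub-scores partition the pooled test fold", {
  feats <- toy_features(80)
  splits <- mc_splits(80, n_splits = 5, seed = 8)
  sc <- drug_generalization(feats, splits = splits, model = "total_power")
  for (i in 1:5) {
    rows <- sc[sc$split == i, ]
    pooled <- rows[rows$model == "pooled", ]
    subp <- rows[rows$model == "pooled_on_propofol", ]
    subs <- rows[rows$model == "pooled_on_sevoflurane", ]
    expect_equal(
      (subp$mae * subp$n_test + subs$mae * subs$n_test) /
        (subp$n_test + subs$n_test),
      pooled$mae, tolerance = 1e-9)
  }
})

test_that("identical drug spectra generalise across drugs", {
  ## drug labels carry no information in the toy features: within- and
  ## cross-drug scores agree up to CV noise
  feats <- toy_features(120, seed = 23)
  splits <- mc_splits(120, n_splits = 20, seed = 9)
  sc <- drug_generalization(feats, splits = splits, model = "total_power")
  med <- function(m) median(sc$mae[sc$model == m], na.rm = TRUE)
  expect_lt(abs(med("propofol_to_sevoflurane") - med("within_sevoflurane")), 2)
  expect_lt(abs(med("sevoflurane_to_propofol") - med("within_propofol")), 2)
})
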
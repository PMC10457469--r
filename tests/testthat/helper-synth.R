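# shared fixtures, generated once per test session

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

tiny_spec <- function(duration_s = 300, n = 2, seed = 7) {
  cohort_spec(n_patients = n, seed = seed, duration_s = duration_s)
}

## one clean (no artifacts, no BS) propofol patient, 600 s
clean_patient <- function() {
  fixture("clean_patient", function() {
    generate_patient(tiny_spec(600), generator_truth(), 42,
                     age_yr = 55, drug = "propofol", asa = 2,
                     with_bs = FALSE, with_artifacts = FALSE)
  })
}

## same patient with defaults (BS + artifacts on)
noisy_patient <- function() {
  fixture("noisy_patient", function() {
    generate_patient(tiny_spec(600), generator_truth(), 42,
                     age_yr = 60, drug = "propofol", asa = 2)
  })
}

## fully processed features of the clean patient
clean_features <- function() {
  fixture("clean_features", function() extract_features(clean_patient()$record))
}

## white-noise record helper
noise_record <- function(duration_s, fs = 63, sd = 10, seed = 1,
                         nchan = 4) {
  set.seed(seed)
  eeg_record(matrix(rnorm(nchan * duration_s * fs, sd = sd), nchan),
             fs_hz = fs, meta = list(patient_id = "noise"))
}

## epoch set stub for stable-segment logic tests
fake_eset <- function(sef_mean, retained = rep(TRUE, length(sef_mean))) {
  n <- length(sef_mean)
  structure(list(record = NULL, onsets_s = (seq_len(n) - 1) * 10,
                 win_s = 60, shift_s = 10, n_epochs = n,
                 ptp = matrix(1, n, 4), retained = retained,
                 bs_overlap = rep(FALSE, n),
                 sef95 = matrix(sef_mean, n, 4),
                 sef95_mean = sef_mean),
            class = "epoch_set")
}

## small synthetic feature table (no EEG): age is linearly encoded in
## every set, with independent noise per set
toy_features <- function(n = 120, seed = 3, spatial = FALSE) {
  set.seed(seed)
  age <- runif(n, 18, 90)
  feats <- list(
    meta = data.frame(patient_id = paste0("T", seq_len(n)), age_yr = age,
                      drug = rep(c("propofol", "sevoflurane"),
                                 length.out = n),
                      asa = rep(1:3, length.out = n),
                      stringsAsFactors = FALSE),
    total = age * 0.05 + rnorm(n, 0, 1),
    alpha = age * -0.03 + rnorm(n, 0, 1),
    spectrum = matrix(age * 0.02, n, 16) + matrix(rnorm(n * 16), n, 16))
  if (spatial) {
    covs <- array(0, c(n, 5, 4, 4))
    for (i in seq_len(n)) for (b in 1:5) {
      a <- (age[i] - 54) / 72
      R <- diag(4) + a * outer(c(1, -1, 1, -1), c(1, -1, 1, -1)) * 0.3
      covs[i, b, , ] <- R + diag(4) * 0.5
    }
    feats$covs <- covs
    feats$cov_n_obs <- rep(1000, n)
  }
  structure(feats, class = "cohort_features")
}
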
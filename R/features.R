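#' Frequency bands for the spatial-pattern features
#'
#' @return Data frame with band name and edges (Hz): low 0.1-1.5, delta
#'   1.5-4, theta 4-8, alpha 8-15, beta 15-30.
#' @export
eeg_bands <- function() {
  data.frame(band = c("low", "delta", "theta", "alpha", "beta"),
             fmin = c(0.1, 1.5, 4, 8, 15),
             fmax = c(1.5, 4, 8, 15, 30),
             stringsAsFactors = FALSE)
}

## PSD and band covariances of the stable segment in one pass: per-epoch
## Welch spectra / co-spectra, arithmetically averaged across epochs.
segment_spectra <- function(eset, segment, control = welch_control()) {
  if (is.null(segment) || segment$n_epochs < 1)
    stop_arg("empty stable segment: patient excluded")
  idx <- segment$first_epoch:segment$last_epoch
  fs <- eset$record$fs_hz
  cache <- eset$cache
  csd_acc <- NULL; freqs <- NULL
  for (i in idx) {
    cr <- if (!is.null(cache))
      cache_csd(cache, eset$onsets_s[i], eset$win_s)
    else
      welch_cross(epoch_slice(eset$record, eset$onsets_s[i], eset$win_s),
                  fs, control)
    if (is.null(csd_acc)) {
      freqs <- cr$freqs_hz
      csd_acc <- cr$csd
    } else csd_acc <- csd_acc + cr$csd
  }
  csd <- csd_acc / length(idx)
  psd <- t(vapply(1:4, function(c_) csd[c_, c_, ], numeric(length(freqs))))
  bands <- eeg_bands()
  df <- freqs[2] - freqs[1]
  covs <- array(NA_real_, c(nrow(bands), 4, 4),
                dimnames = list(bands$band, NULL, NULL))
  for (b in seq_len(nrow(bands))) {
    sel <- freqs > bands$fmin[b] & freqs <= bands$fmax[b]
    covs[b, , ] <- apply(csd[, , sel, drop = FALSE], c(1, 2), sum) * df
  }
  n_obs <- ((length(idx) - 1) * eset$shift_s + eset$win_s) * fs
  list(psd_grid = structure(list(freqs_hz = freqs, psd = psd,
                                 channel_mean = colMeans(psd)),
                            class = "psd_grid"),
       cov_set = structure(list(bands = bands, cov = covs, n_obs = n_obs),
                           class = "band_cov_set"))
}

#' Welch PSD averaged over the stable segment
#'
#' @param eset An epoch set ([epoch_record()] result with QC computed).
#' @param segment A [select_stable_segment()] result.
#' @param control A [welch_control()].
#' @return A `psd_grid`: `freqs_hz` (0-30 Hz), `psd` (4 x n_freqs,
#'   uV^2/Hz) and `channel_mean`.
#' @export
segment_psd <- function(eset, segment, control = welch_control()) {
  segment_spectra(eset, segment, control)$psd_grid
}

#' Band-limited channel covariances of the stable segment
#'
#' For each of the five frequency bands, the 4 x 4 channel covariance of
#' the ideally band-filtered signal, obtained by integrating the Welch
#' co-spectra over the band and averaging across the segment's epochs.
#' The diagonal of each matrix is the per-channel band power.
#'
#' @inheritParams segment_psd
#' @return A `band_cov_set`: band table, `cov` (5 x 4 x 4 array, uV^2)
#'   and the effective observation count.
#' @export
band_covariances <- function(eset, segment, control = welch_control()) {
  segment_spectra(eset, segment, control)$cov_set
}

## snap 16 uniformly spaced frequencies in [1, 30] to the Welch grid
spectrum_feature_freqs <- function(freqs) {
  targets <- seq(1, 30, length.out = 16)
  freqs[vapply(targets, function(t) which.min(abs(freqs - t)), 1L)]
}

#' Assemble the four nested feature vectors of one patient
#'
#' * `total_power` (1): log of channel-mean power summed over 1-30 Hz;
#' * `alpha_power` (1): log of channel-mean power integrated over 8-13 Hz;
#' * `spectrum` (16): log channel-mean PSD at 16 uniformly spaced
#'   frequencies in 1-30 Hz (snapped to the Welch grid);
#' * `spatial` (50): per band, the OAS-shrunk covariance mapped to the
#'   tangent space at `tangent_reference` and vectorised to 10 entries.
#'
#' @param psd_grid A `psd_grid` from [segment_psd()].
#' @param cov_set A `band_cov_set` from [band_covariances()].
#' @param tangent_reference Optional list of 5 reference SPD matrices
#'   (the per-band geometric mean of a training set); identity when
#'   `NULL`.
#' @return List of class `feature_bundle` with elements `total_power`,
#'   `alpha_power`, `spectrum`, `spatial` of lengths 1/1/16/50.
#' @export
make_feature_bundle <- function(psd_grid, cov_set, tangent_reference = NULL) {
  f <- psd_grid$freqs_hz
  df <- f[2] - f[1]
  cm <- psd_grid$channel_mean
  tot <- sum(cm[f >= 1 & f <= 30]) * df
  alp <- sum(cm[f >= 8 & f <= 13]) * df
  if (tot <= 0 || alp <= 0)
    stop_arg("zero power in total/alpha range; cannot log-transform")
  sf <- spectrum_feature_freqs(f)
  sp <- cm[match(sf, f)]
  if (any(sp <= 0)) stop_arg("zero power at spectrum feature frequencies")
  spatial <- numeric(0)
  for (b in seq_len(dim(cov_set$cov)[1])) {
    C <- oas_shrinkage(cov_set$cov[b, , ], cov_set$n_obs)
    ref <- if (is.null(tangent_reference)) NULL else tangent_reference[[b]]
    v <- tangent_vector(C, ref)
    if (any(!is.finite(v)))
      stop_arg("non-finite spatial features in band ",
               cov_set$bands$band[b])
    spatial <- c(spatial, v)
  }
  structure(list(total_power = log(tot), alpha_power = log(alp),
                 spectrum = log(sp), spatial = spatial),
            class = "feature_bundle")
}

#' Preprocess a recording and extract its spectral features
#'
#' Runs [preprocess_record()] and, when a stable segment exists, the
#' segment-averaged PSD and band covariances.
#'
#' @param record An [eeg_record()].
#' @param ... Passed to [preprocess_record()].
#' @return List with `qc`, `bs_ratio`, and (when usable) `psd_grid` and
#'   `cov_set`.
#' @export
extract_features <- function(record, ...) {
  pre <- preprocess_record(record, ...)
  out <- list(qc = pre$qc, bs_ratio = pre$bs_ratio,
              psd_grid = NULL, cov_set = NULL)
  if (!is.null(pre$segment)) {
    sp <- segment_spectra(pre$epochs, pre$segment)
    out$psd_grid <- sp$psd_grid
    out$cov_set <- sp$cov_set
  }
  out
}

#' Feature table for a whole cohort
#'
#' Streams patients through generation (or takes pre-generated records),
#' preprocesses each recording and collects the per-patient features.
#' Patients without a stable segment are kept in the QC table but
#' excluded from the feature arrays.
#'
#' @param cohort A [generate_cohort()] result with `records` kept, or
#'   `NULL` to generate patients on the fly from `spec`/`truth` (memory
#'   friendly for large cohorts).
#' @param spec,truth Used when `cohort` is `NULL`.
#' @param with_bs,with_artifacts Passed to the generator when streaming.
#' @param ... Passed to [extract_features()].
#' @return Object of class `cohort_features`: `meta` (usable patients),
#'   `total`, `alpha` (n-vectors), `spectrum` (n x 16), `covs`
#'   (n x 5 x 4 x 4), `cov_n_obs`, `psd_mean` (n x n_freqs), `freqs_hz`,
#'   `bs_ratio`, `qc` (all patients) and `truth` when available.
#' @export
cohort_features <- function(cohort = NULL, spec = NULL,
                            truth = generator_truth(),
                            with_bs = TRUE, with_artifacts = TRUE, ...) {
  if (is.null(cohort) && is.null(spec))
    stop_arg("supply either a generated cohort or a cohort_spec")
  if (is.null(cohort)) {
    n <- spec$n_patients
    demo <- cohort_demographics(spec)
    get_patient <- function(i)
      generate_patient(spec, truth, derive_seed(spec$seed, i),
                       patient_id = sprintf("P%03d", i),
                       drug = demo$drug[i], asa = demo$asa[i],
                       with_bs = with_bs, with_artifacts = with_artifacts)
    truth_rows <- vector("list", n)
  } else {
    n <- nrow(cohort$metadata)
    get_patient <- function(i) list(record = cohort$records[[i]],
                                    truth = cohort$truth[i, ])
    truth_rows <- NULL
  }
  qc <- vector("list", n)
  feats <- vector("list", n)
  meta_rows <- vector("list", n)
  for (i in seq_len(n)) {
    pt <- get_patient(i)
    fx <- extract_features(pt$record, ...)
    qc[[i]] <- fx$qc
    feats[[i]] <- fx
    meta_rows[[i]] <- data.frame(
      patient_id = pt$record$meta$patient_id,
      age_yr = pt$record$meta$age_yr, sex = pt$record$meta$sex,
      drug = pt$record$meta$drug, asa = pt$record$meta$asa,
      bs_ratio = fx$bs_ratio, usable = fx$qc$usable,
      stringsAsFactors = FALSE)
    if (!is.null(truth_rows)) truth_rows[[i]] <- pt$truth
  }
  meta_all <- do.call(rbind, meta_rows)
  ok <- which(meta_all$usable)
  freqs <- feats[[ok[1]]]$psd_grid$freqs_hz
  nf <- length(freqs)
  out <- list(
    meta = meta_all[ok, , drop = FALSE],
    total = vapply(ok, function(i) {
      fb <- feats[[i]]
      f <- fb$psd_grid$freqs_hz; df <- f[2] - f[1]
      log(sum(fb$psd_grid$channel_mean[f >= 1 & f <= 30]) * df)
    }, numeric(1)),
    alpha = vapply(ok, function(i) {
      fb <- feats[[i]]
      f <- fb$psd_grid$freqs_hz; df <- f[2] - f[1]
      log(sum(fb$psd_grid$channel_mean[f >= 8 & f <= 13]) * df)
    }, numeric(1)),
    spectrum = t(vapply(ok, function(i) {
      fb <- feats[[i]]
      f <- fb$psd_grid$freqs_hz
      log(fb$psd_grid$channel_mean[match(spectrum_feature_freqs(f), f)])
    }, numeric(16))),
    covs = aperm(vapply(ok, function(i) feats[[i]]$cov_set$cov,
                        array(0, c(5, 4, 4))), c(4, 1, 2, 3)),
    cov_n_obs = vapply(ok, function(i) feats[[i]]$cov_set$n_obs, numeric(1)),
    psd_mean = t(vapply(ok, function(i) feats[[i]]$psd_grid$channel_mean,
                        numeric(nf))),
    freqs_hz = freqs,
    qc = do.call(rbind, qc))
  if (!is.null(truth_rows)) {
    tr <- do.call(rbind, truth_rows)
    out$truth <- tr[ok, , drop = FALSE]
    out$truth_all <- tr
  } else if (!is.null(cohort$truth)) {
    out$truth <- cohort$truth[ok, , drop = FALSE]
    out$truth_all <- cohort$truth
  }
  rownames(out$meta) <- NULL
  structure(out, class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
  cat("<cohort_features>", nrow(x$meta), "usable patients of",
      nrow(x$qc), "processed\n")
  invisible(x)
}

#' Export the per-patient feature matrix
#'
#' Writes one row per usable patient with columns named
#' `<feature_set>_<index>` (spatial columns carry the band name), plus a
#' JSON sidecar describing each column (feature set, index, band or
#' frequency).
#'
#' @param features A [cohort_features()] object.
#' @param path Output CSV path; the schema is written next to it as
#'   `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
export_features <- function(features, path) {
  sf <- spectrum_feature_freqs(features$freqs_hz)
  bands <- eeg_bands()$band
  tangent_names <- c(paste0("var_", 1:4),
                     paste0("cov_", c("12", "13", "23", "14", "24", "34")))
  spat_cols <- as.vector(t(outer(bands, tangent_names, paste, sep = "_")))
  sets <- model_feature_sets(features, "spatial_patterns")
  trans <- set_fit(sets$spatial, seq_len(nrow(features$meta)))
  spatial <- set_apply(trans, sets$spatial, seq_len(nrow(features$meta)))
  tab <- data.frame(patient_id = features$meta$patient_id,
                    total_power_1 = features$total,
                    alpha_power_1 = features$alpha,
                    stringsAsFactors = FALSE)
  spec_cols <- paste0("spectrum_", seq_len(16))
  tab[spec_cols] <- features$spectrum
  tab[paste0("spatial_", spat_cols)] <- spatial
  write.csv(tab, path, row.names = FALSE)
  schema <- c(
    list(list(column = "patient_id", feature_set = "id", index = 0)),
    list(list(column = "total_power_1", feature_set = "total_power",
              index = 1, range_hz = c(1, 30))),
    list(list(column = "alpha_power_1", feature_set = "alpha_power",
              index = 1, range_hz = c(8, 13))),
    lapply(seq_len(16), function(i)
      list(column = spec_cols[i], feature_set = "power_spectrum",
           index = i, freq_hz = sf[i])),
    lapply(seq_along(spat_cols), function(i)
      list(column = paste0("spatial_", spat_cols[i]),
           feature_set = "spatial_patterns", index = i,
           band = rep(bands, each = 10)[i])))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(schema, paste0(path, ".schema.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Subset usable patients of a cohort feature table
#'
#' @param x A `cohort_features` object.
#' @param i Integer or logical index over usable patients.
#' @param ... Unused.
#' @export
`[.cohort_features` <- function(x, i, ...) {
  out <- x
  out$meta <- x$meta[i, , drop = FALSE]
  out$total <- x$total[i]
  out$alpha <- x$alpha[i]
  out$spectrum <- x$spectrum[i, , drop = FALSE]
  out$covs <- x$covs[i, , , , drop = FALSE]
  out$cov_n_obs <- x$cov_n_obs[i]
  out$psd_mean <- x$psd_mean[i, , drop = FALSE]
  if (!is.null(x$truth)) out$truth <- x$truth[i, , drop = FALSE]
  out
}
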
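#' Assign patients to the analysis subsets
#'
#' Mirrors the selection flowchart: DS1 (propofol, ASA 1-2; model
#' building), DS2 (sevoflurane, ASA 1-2), DS3 (DS1 with burst
#' suppression annotated), DS4 (ASA 3 with burst suppression annotated),
#' DS5 = DS3 plus DS4 (disjoint). Rows with unknown drug or ASA values
#' are excluded with a reason.
#'
#' @param metadata Data frame with columns drug, asa, and optionally
#'   bs_annotated (assumed `TRUE` when absent).
#' @return List of class `dataset_split` with integer index vectors
#'   `ds1` .. `ds5`, plus `excluded` (indices) and `exclusion_reason`.
#' @export
assign_subsets <- function(metadata) {
  drug <- metadata$drug
  asa <- metadata$asa
  bs_ann <- metadata$bs_annotated %||% rep(TRUE, nrow(metadata))
  valid <- drug %in% c("propofol", "sevoflurane") & asa %in% 1:3
  ds1 <- which(valid & drug == "propofol" & asa <= 2)
  ds2 <- which(valid & drug == "sevoflurane" & asa <= 2)
  ds3 <- intersect(ds1, which(bs_ann))
  ds4 <- which(valid & asa == 3 & bs_ann)
  structure(list(ds1 = ds1, ds2 = ds2, ds3 = ds3, ds4 = ds4,
                 ds5 = c(ds3, ds4), excluded = which(!valid),
                 exclusion_reason = ifelse(valid[!valid], NA,
                                           "unknown drug or ASA value")),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> DS1:", length(x$ds1), " DS2:", length(x$ds2),
      " DS3:", length(x$ds3), " DS4:", length(x$ds4),
      " DS5:", length(x$ds5), " excluded:", length(x$excluded), "\n")
  invisible(x)
}

#' Configuration of an end-to-end experiment
#'
#' @param spec A [cohort_spec()].
#' @param truth A [generator_truth()].
#' @param n_splits,test_fraction Monte Carlo CV settings.
#' @param seed Base seed for splits and model fitting.
#' @param models Models to compare (default: all, dummy first).
#' @param run_drug_generalization,run_clinical Stage toggles.
#' @param out_dir Optional output directory for CSV/JSON results.
#' @return List of class `run_config`.
#' @export
run_config <- function(spec = cohort_spec(), truth = generator_truth(),
                       n_splits = 100, test_fraction = 0.1, seed = 1L,
                       models = brainage_model_names(),
                       run_drug_generalization = TRUE,
                       run_clinical = TRUE, out_dir = NULL) {
  structure(list(spec = spec, truth = truth, n_splits = n_splits,
                 test_fraction = test_fraction, seed = as.integer(seed),
                 models = models,
                 run_drug_generalization = run_drug_generalization,
                 run_clinical = run_clinical, out_dir = out_dir),
            class = "run_config")
}

#' Run the full synthetic-cohort experiment
#'
#' Generates (streaming) and preprocesses the cohort, extracts features,
#' compares the nested age-prediction models on the reference subset
#' (propofol, ASA 1-2) under Monte Carlo CV, produces the concatenated
#' brain-age table (cross-validated on the reference group, extrapolated
#' to ASA 3), fits the burst-suppression model on it, evaluates drug
#' generalisation on the two-drug ASA 1-2 cohort, and fits the
#' single-drug and two-drug log-power mixed models.
#'
#' @param config A [run_config()].
#' @return List of class `experiment_result` with `features`, `subsets`,
#'   `scores` (per-model CV scores), `comparisons` (successive-model
#'   comparisons), `brain_age` table, `bs_fit`, `drug_scores`,
#'   `lmm_single`, `lmm_two_drug`, `qc`.
#' @export
run_experiment <- function(config = run_config()) {
  feats <- cohort_features(spec = config$spec, truth = config$truth)
  subs <- assign_subsets(feats$meta)
  ages <- feats$meta$age_yr

  splits <- mc_splits(length(subs$ds1), n_splits = config$n_splits,
                      test_fraction = config$test_fraction,
                      seed = config$seed)
  feats_ds1 <- feats[subs$ds1]
  scores <- lapply(config$models, function(m)
    crossval_scores(feats_ds1, model = m, splits = splits,
                    seed = config$seed))
  names(scores) <- config$models
  ord <- intersect(brainage_model_names(), config$models)
  comparisons <- list()
  if (length(ord) > 1)
    for (k in 2:length(ord))
      comparisons[[paste(ord[k], "vs", ord[k - 1])]] <-
        compare_models(scores[[ord[k]]], scores[[ord[k - 1]]])

  brain_age <- predict_brain_age(feats, train_idx = subs$ds3,
                                 apply_idx = subs$ds4,
                                 seed = config$seed)
  bs_fit_res <- NULL
  lmm1 <- lmm2 <- NULL
  if (config$run_clinical) {
    ds5 <- c(subs$ds3, subs$ds4)
    bs_tab <- build_bs_table(feats$meta$bs_ratio[ds5],
                             brain_age$age_yr, brain_age$brain_age_yr,
                             brain_age$asa, brain_age$patient_id)
    bs_fit_res <- fit_bs_model(bs_tab)
    lmm1 <- fit_power_lmm(build_long_power_table(feats[subs$ds1]))
    lmm2 <- fit_power_lmm(
      build_long_power_table(feats[c(subs$ds1, subs$ds2)]),
      with_drug_terms = TRUE)
  }
  drug_scores <- NULL
  if (config$run_drug_generalization) {
    ds12 <- c(subs$ds1, subs$ds2)
    splits12 <- mc_splits(length(ds12), n_splits = config$n_splits,
                          test_fraction = config$test_fraction,
                          seed = config$seed + 1L)
    drug_scores <- drug_generalization(feats[ds12], splits = splits12,
                                       seed = config$seed)
  }
  res <- structure(list(features = feats, subsets = subs,
                        scores = scores, comparisons = comparisons,
                        brain_age = brain_age, bs_fit = bs_fit_res,
                        drug_scores = drug_scores, lmm_single = lmm1,
                        lmm_two_drug = lmm2, qc = feats$qc,
                        config = config),
                   class = "experiment_result")
  if (!is.null(config$out_dir)) write_experiment(res, config$out_dir)
  res
}

write_experiment <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sc <- do.call(rbind, res$scores)
  write.csv(sc, file.path(out_dir, "cv_scores.csv"), row.names = FALSE)
  write.csv(res$brain_age, file.path(out_dir, "brain_age.csv"),
            row.names = FALSE)
  write.csv(res$qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
  if (!is.null(res$drug_scores))
    write.csv(res$drug_scores, file.path(out_dir, "drug_scores.csv"),
              row.names = FALSE)
  if (!is.null(res$bs_fit))
    write.csv(res$bs_fit$coefficients,
              file.path(out_dir, "bs_model.csv"), row.names = FALSE)
  if (!is.null(res$lmm_single))
    write.csv(res$lmm_single$coefficients,
              file.path(out_dir, "lmm_single_drug.csv"), row.names = FALSE)
  if (!is.null(res$lmm_two_drug))
    write.csv(res$lmm_two_drug$coefficients,
              file.path(out_dir, "lmm_two_drug.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$subsets)
  for (nm in names(x$scores))
    cat(sprintf("  %-18s median MAE %.2f yr\n", nm,
                median(x$scores[[nm]]$mae)))
  invisible(x)
}
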
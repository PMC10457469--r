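#' Monte Carlo cross-validation splits
#'
#' Repeated random shuffle-splits. All models being compared must score
#' on the same splits, so generate the splits once and pass them to every
#' [crossval_scores()] call.
#'
#' @param n Number of patients.
#' @param n_splits Number of splits (default 100).
#' @param test_fraction Fraction held out per split (default 0.1).
#' @param seed Integer seed.
#' @return List of class `mc_splits`; each element is a sorted vector of
#'   test indices.
#' @export
mc_splits <- function(n, n_splits = 100, test_fraction = 0.1, seed = 1L) {
  set.seed(seed)
  n_test <- max(1L, round(test_fraction * n))
  structure(lapply(seq_len(n_splits), function(i) sort(sample(n, n_test))),
            class = "mc_splits", n = n, seed = seed)
}

score_predictions <- function(pred, truth) {
  c(mae = mean(abs(pred - truth)),
    r2 = 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2))
}

#' Cross-validated scores of one age-prediction model
#'
#' For every Monte Carlo split, the model (a stacked ridge over the
#' model's feature sets, or the dummy mean predictor) is fitted on the
#' training fold — including tangent referencing, feature
#' standardisation and penalty selection — and scored on the held-out
#' fold with MAE (years) and the test-fold R-squared.
#'
#' @param features A [cohort_features()] object (or subset).
#' @param ages Chronological ages; defaults to `features$meta$age_yr`.
#' @param model One of [brainage_model_names()].
#' @param splits An [mc_splits()] list shared across models.
#' @param seed Base seed for the internal stacking folds.
#' @param extra_sets Optional named list of additional feature sets
#'   appended after the model's own sets (used e.g. to probe stacking
#'   robustness with pure-noise features).
#' @return Data frame of class `cv_scores`: model, split, mae, r2.
#' @export
crossval_scores <- function(features, ages = features$meta$age_yr,
                            model = "spatial_patterns", splits,
                            seed = 1L, extra_sets = NULL) {
  n <- length(ages)
  sets <- if (model != "dummy") model_feature_sets(features, model,
                                                   extra_sets)
  res <- lapply(seq_along(splits), function(i) {
    te <- splits[[i]]
    tr <- setdiff(seq_len(n), te)
    set.seed(derive_seed(seed, i, 2L))
    if (model == "dummy") {
      pred <- rep(mean(ages[tr]), length(te))
    } else {
      fit <- fit_stacking(subset_sets(sets, tr), ages[tr])
      pred <- predict(fit, subset_sets(sets, te))
    }
    sc <- score_predictions(pred, ages[te])
    data.frame(model = model, split = i, mae = sc[["mae"]],
               r2 = sc[["r2"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("cv_scores", "data.frame")
  out
}

#' Pairwise model comparison across shared CV splits
#'
#' Summarises the paired per-split MAE difference (a minus b) with
#' percentiles P2.5/P25/P75/P97.5 and a superiority count: on how many
#' splits model a scored strictly better (lower MAE) than model b.
#'
#' @param scores_a,scores_b `cv_scores` for two models evaluated on the
#'   identical split sequence.
#' @return List of class `model_comparison`.
#' @export
compare_models <- function(scores_a, scores_b) {
  if (nrow(scores_a) != nrow(scores_b) ||
      any(scores_a$split != scores_b$split))
    stop_arg("scores were not computed on the same split sequence")
  delta <- scores_a$mae - scores_b$mae
  structure(list(
    model_a = scores_a$model[1], model_b = scores_b$model[1],
    n_splits = nrow(scores_a),
    delta_mae = delta,
    delta_percentiles = cv_percentiles(delta),
    delta_median = median(delta),
    superiority = sum(scores_a$mae < scores_b$mae),
    percentiles_a = cv_percentiles(scores_a$mae),
    percentiles_b = cv_percentiles(scores_b$mae),
    median_a = median(scores_a$mae), median_b = median(scores_b$mae)),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s vs %s over %d splits\n",
              x$model_a, x$model_b, x$n_splits))
  cat(sprintf("  median MAE: %.2f vs %.2f yr; median delta %+.2f yr\n",
              x$median_a, x$median_b, x$delta_median))
  cat(sprintf("  delta P25=%.2f P75=%.2f; superior on %d/%d splits\n",
              x$delta_percentiles[["25%"]], x$delta_percentiles[["75%"]],
              x$superiority, x$n_splits))
  invisible(x)
}

#' Cross-validated and extrapolated brain-age predictions
#'
#' Reference patients receive out-of-fold predictions (no patient is
#' predicted by a model trained on itself); held-out patients (e.g. a
#' higher-ASA population never used for model building) are predicted by
#' a model refitted on all reference patients. The concatenated table is
#' the brain-age variable used by the clinical models.
#'
#' @param features A [cohort_features()] object covering both groups.
#' @param train_idx Indices (into usable patients) of the reference
#'   group.
#' @param apply_idx Indices of the extrapolation group (may be empty);
#'   must not overlap `train_idx`.
#' @param model Model name (default `"spatial_patterns"`).
#' @param n_folds Folds for the out-of-fold predictions.
#' @param seed Integer seed.
#' @return Data frame: patient_id, age_yr, brain_age_yr, source
#'   (`"cross_validated"` / `"extrapolated"`), drug, asa.
#' @export
predict_brain_age <- function(features, train_idx,
                              apply_idx = integer(0),
                              model = "spatial_patterns",
                              n_folds = 10, seed = 1L) {
  if (length(intersect(train_idx, apply_idx)))
    stop_arg("train and apply groups overlap")
  ages <- features$meta$age_yr
  sets <- model_feature_sets(features, model)
  set.seed(derive_seed(seed, 0L, 3L))
  folds <- sample(rep(seq_len(n_folds), length.out = length(train_idx)))
  oof <- numeric(length(train_idx))
  for (k in seq_len(n_folds)) {
    tr <- train_idx[folds != k]; te <- train_idx[folds == k]
    fit <- fit_stacking(subset_sets(sets, tr), ages[tr])
    oof[folds == k] <- predict(fit, subset_sets(sets, te))
  }
  tab <- data.frame(patient_id = features$meta$patient_id[train_idx],
                    age_yr = ages[train_idx], brain_age_yr = oof,
                    source = "cross_validated",
                    drug = features$meta$drug[train_idx],
                    asa = features$meta$asa[train_idx],
                    stringsAsFactors = FALSE)
  if (length(apply_idx)) {
    fit <- fit_stacking(subset_sets(sets, train_idx), ages[train_idx])
    pred <- predict(fit, subset_sets(sets, apply_idx))
    tab <- rbind(tab, data.frame(
      patient_id = features$meta$patient_id[apply_idx],
      age_yr = ages[apply_idx], brain_age_yr = pred,
      source = "extrapolated",
      drug = features$meta$drug[apply_idx],
      asa = features$meta$asa[apply_idx],
      stringsAsFactors = FALSE))
  }
  rownames(tab) <- NULL
  tab
}

#' Within-, between- and pooled-drug generalisation
#'
#' For every Monte Carlo split of the pooled two-drug cohort, the model
#' is (i) fitted and scored within each drug, (ii) fitted on the
#' training patients of one drug and scored on the test patients of the
#' other, and (iii) fitted on the pooled training fold and scored on the
#' pooled test fold plus its per-drug subsets. The per-drug pooled
#' sub-scores partition the pooled test fold, so their size-weighted
#' mean MAE equals the overall pooled MAE.
#'
#' @param features A [cohort_features()] object containing both drugs.
#' @param ages Ages; defaults to the metadata.
#' @param drug Drug labels; defaults to the metadata.
#' @param splits An [mc_splits()] list on the pooled cohort; splits whose
#'   training fold lacks one of the drugs are regenerated with a
#'   warning.
#' @param model Model name.
#' @param seed Base seed.
#' @param inner_folds Internal stacking folds; a training cell smaller
#'   than this is marked unavailable (`NA` scores).
#' @return `cv_scores` data frame with models `within_propofol`,
#'   `within_sevoflurane`, `propofol_to_sevoflurane`,
#'   `sevoflurane_to_propofol`, `pooled`, `pooled_on_propofol`,
#'   `pooled_on_sevoflurane`, plus an `n_test` column.
#' @export
drug_generalization <- function(features, ages = features$meta$age_yr,
                                drug = features$meta$drug, splits,
                                model = "spatial_patterns", seed = 1L,
                                inner_folds = 10) {
  n <- length(ages)
  is_prop <- drug == "propofol"
  if (!any(is_prop) || !all(is_prop %in% c(TRUE, FALSE)) || all(is_prop))
    stop_arg("both drug groups must be non-empty")
  sets <- model_feature_sets(features, model)
  fit_cell <- function(tr, te) {
    if (length(tr) < max(inner_folds, 20) || !length(te))
      return(c(mae = NA_real_, r2 = NA_real_))
    fit <- fit_stacking(subset_sets(sets, tr), ages[tr],
                        inner_folds = inner_folds)
    score_predictions(predict(fit, subset_sets(sets, te)), ages[te])
  }
  res <- vector("list", length(splits))
  warned <- FALSE
  for (i in seq_along(splits)) {
    te <- splits[[i]]
    tr <- setdiff(seq_len(n), te)
    tries <- 0
    while ((!any(is_prop[tr]) || !any(!is_prop[tr])) && tries < 100) {
      if (!warned) {
        warning("regenerating split with single-drug training fold",
                call. = FALSE)
        warned <- TRUE
      }
      set.seed(derive_seed(seed, i, 4L) + tries)
      te <- sort(sample(n, length(te)))
      tr <- setdiff(seq_len(n), te)
      tries <- tries + 1
    }
    set.seed(derive_seed(seed, i, 5L))
    trP <- tr[is_prop[tr]]; trS <- tr[!is_prop[tr]]
    teP <- te[is_prop[te]]; teS <- te[!is_prop[te]]
    cells <- list(
      within_propofol = fit_cell(trP, teP),
      within_sevoflurane = fit_cell(trS, teS),
      propofol_to_sevoflurane = fit_cell(trP, teS),
      sevoflurane_to_propofol = fit_cell(trS, teP))
    ## pooled cell and its per-drug sub-scores share one fit, so the
    ## size-weighted mean of the sub-MAEs equals the pooled MAE exactly
    na_cell <- c(mae = NA_real_, r2 = NA_real_)
    if (length(tr) >= max(inner_folds, 20)) {
      fitp <- fit_stacking(subset_sets(sets, tr), ages[tr],
                           inner_folds = inner_folds)
      subcell <- function(idx) if (length(idx))
        score_predictions(predict(fitp, subset_sets(sets, idx)), ages[idx])
      else na_cell
      cells$pooled <- subcell(te)
      cells$pooled_on_propofol <- subcell(teP)
      cells$pooled_on_sevoflurane <- subcell(teS)
    } else {
      cells$pooled <- na_cell
      cells$pooled_on_propofol <- na_cell
      cells$pooled_on_sevoflurane <- na_cell
    }
    n_test <- c(length(teP), length(teS), length(teS), length(teP),
                length(te), length(teP), length(teS))
    res[[i]] <- data.frame(model = names(cells), split = i,
                           mae = vapply(cells, `[[`, 0, "mae"),
                           r2 = vapply(cells, `[[`, 0, "r2"),
                           n_test = n_test,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("cv_scores", "data.frame")
  out
}
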
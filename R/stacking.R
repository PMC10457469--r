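## Feature-set abstraction for stacking. A "set" is either a plain
## numeric design matrix (rows = patients) or a covariance set that must
## be referenced to the training data (per-band geometric mean) before
## tangent-space vectorisation. Transforms are always fitted on training
## rows only, so no test-fold statistics leak into the model.

cov_feature_set <- function(covs, n_obs) {
  ## shrinkage depends only on each patient's own matrix, so the shrunk
  ## covariances and their matrix logarithms are precomputed once; the
  ## log-Euclidean geometric mean of any training subset is then a
  ## simple average of stored logs
  n <- dim(covs)[1]; nb <- dim(covs)[2]
  shrunk <- covs
  logs <- covs
  for (i in seq_len(n)) for (b in seq_len(nb)) {
    C <- oas_shrinkage(covs[i, b, , ], n_obs[i])
    shrunk[i, b, , ] <- C
    logs[i, b, , ] <- spd_logm(C)
  }
  structure(list(covs = covs, n_obs = n_obs, shrunk = shrunk,
                 logs = logs), class = "cov_feature_set")
}

set_fit <- function(set, idx) {
  if (!inherits(set, "cov_feature_set")) return(NULL)
  nb <- dim(set$covs)[2]
  refs <- vector("list", nb)
  rinv <- vector("list", nb)
  for (b in seq_len(nb)) {
    refs[[b]] <- spd_expm(apply(set$logs[idx, b, , , drop = FALSE],
                                c(3, 4), mean))
    rinv[[b]] <- spd_invsqrtm(refs[[b]])
  }
  list(refs = refs, rinv = rinv)
}

set_apply <- function(trans, set, idx) {
  if (!inherits(set, "cov_feature_set"))
    return(as.matrix(set)[idx, , drop = FALSE])
  nb <- dim(set$covs)[2]
  p <- dim(set$covs)[3]
  out <- matrix(0, length(idx), nb * p * (p + 1) / 2)
  ut <- upper.tri(matrix(0, p, p))
  for (k in seq_along(idx)) {
    col <- 1L
    for (b in seq_len(nb)) {
      R <- trans$rinv[[b]]
      W <- spd_logm(R %*% set$shrunk[idx[k], b, , ] %*% R)
      out[k, col:(col + p + sum(ut) - 1L)] <-
        c(diag(W), sqrt(2) * W[ut])
      col <- col + p + sum(ut)
    }
  }
  out
}

## named list of feature sets for a model, in nesting order
model_feature_sets <- function(features, model, extra_sets = NULL) {
  sets <- switch(model,
    total_power = list(total = matrix(features$total, ncol = 1)),
    alpha_power = list(total = matrix(features$total, ncol = 1),
                       alpha = matrix(features$alpha, ncol = 1)),
    power_spectrum = list(total = matrix(features$total, ncol = 1),
                          alpha = matrix(features$alpha, ncol = 1),
                          spectrum = features$spectrum),
    spatial_patterns = list(total = matrix(features$total, ncol = 1),
                            alpha = matrix(features$alpha, ncol = 1),
                            spectrum = features$spectrum,
                            spatial = cov_feature_set(features$covs,
                                                      features$cov_n_obs)),
    stop_arg("unknown model: ", model))
  c(sets, extra_sets)
}

#' Brain-age model names in nesting order
#'
#' Each model adds one feature set to the previous one: total power,
#' alpha power, the 16-point power spectrum, and the tangent-space
#' spatial patterns in five bands. `"dummy"` predicts the training mean.
#'
#' @return Character vector of model names.
#' @export
brainage_model_names <- function() {
  c("dummy", "total_power", "alpha_power", "power_spectrum",
    "spatial_patterns")
}

#' Fit a stacked ridge age-prediction model
#'
#' Level-1 ridge regressions (one per feature set, penalty chosen by
#' generalised cross-validation) produce internal out-of-fold
#' predictions; a level-2 ridge combines them, one input per feature
#' set. Stacking balances comparisons between feature sets of very
#' different dimension: the combined model can only improve on a simpler
#' one through genuinely complementary information, because each set is
#' summarised by a single input. Covariance sets are referenced to the
#' per-band geometric mean of the training patients (refitted inside
#' every internal fold).
#'
#' @param sets Named list of feature sets, e.g. from the internal
#'   constructor used by [crossval_scores()]; each is a numeric matrix
#'   or a covariance set.
#' @param ages Numeric training ages (years).
#' @param inner_folds Internal folds for the out-of-fold level-1
#'   predictions (default 10).
#' @param lambdas Penalty grid for both levels.
#' @return Object of class `brainage_stack`.
#' @export
fit_stacking <- function(sets, ages, inner_folds = 10,
                         lambdas = default_lambdas()) {
  n <- length(ages)
  if (n < inner_folds)
    stop_arg("fewer training patients (", n, ") than internal folds (",
             inner_folds, ")")
  folds <- sample(rep(seq_len(inner_folds), length.out = n))
  S <- length(sets)
  z <- matrix(NA_real_, n, S, dimnames = list(NULL, names(sets)))
  full <- vector("list", S)
  for (s in seq_len(S)) {
    ## the tangent reference (for covariance sets) is fitted on this
    ## training set once and shared by the internal folds; the outer CV
    ## refits it for every split, so test folds never inform it
    trans <- set_fit(sets[[s]], seq_len(n))
    X <- set_apply(trans, sets[[s]], seq_len(n))
    for (k in seq_len(inner_folds)) {
      tr <- which(folds != k); te <- which(folds == k)
      fit <- ridge_fit(X[tr, , drop = FALSE], ages[tr], lambdas)
      z[te, s] <- predict(fit, X[te, , drop = FALSE])
    }
    full[[s]] <- list(trans = trans, fit = ridge_fit(X, ages, lambdas))
  }
  structure(list(level1 = full, level2 = ridge_fit(z, ages, lambdas),
                 set_names = names(sets), oof = z, n_train = n),
            class = "brainage_stack")
}

#' Predict ages with a fitted stacked model
#'
#' @param object A [fit_stacking()] result.
#' @param newsets Named list of feature sets with the same structure as
#'   used at fit time.
#' @param ... Unused.
#' @return Numeric vector of predicted ages (years).
#' @export
predict.brainage_stack <- function(object, newsets, ...) {
  z <- vapply(seq_along(object$level1), function(s) {
    m <- object$level1[[s]]
    X <- set_apply(m$trans, newsets[[s]],
                   seq_len(set_size(newsets[[s]])))
    predict(m$fit, X)
  }, numeric(set_size(newsets[[1]])))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  predict(object$level2, z)
}

set_size <- function(set) {
  if (inherits(set, "cov_feature_set")) dim(set$covs)[1] else nrow(as.matrix(set))
}

subset_sets <- function(sets, idx) {
  lapply(sets, function(s) {
    if (inherits(s, "cov_feature_set"))
      structure(list(covs = s$covs[idx, , , , drop = FALSE],
                     n_obs = s$n_obs[idx],
                     shrunk = s$shrunk[idx, , , , drop = FALSE],
                     logs = s$logs[idx, , , , drop = FALSE]),
                class = "cov_feature_set")
    else as.matrix(s)[idx, , drop = FALSE]
  })
}
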
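## Symmetric positive-definite matrix utilities for the tangent-space
## treatment of band covariances.

sym_fun <- function(M, f) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

spd_logm <- function(M) {
  sym_fun(M, function(v) {
    if (any(v <= 0)) stop_arg("matrix is not positive definite")
    log(v)
  })
}

spd_expm <- function(M) sym_fun(M, exp)

spd_invsqrtm <- function(M) sym_fun(M, function(v) {
  if (any(v <= 0)) stop_arg("matrix is not positive definite")
  1 / sqrt(v)
})

#' Oracle-approximating shrinkage of a covariance matrix
#'
#' Shrinks a sample covariance toward a scaled identity with the OAS
#' intensity, guaranteeing a well-conditioned positive-definite matrix.
#'
#' @param C Symmetric sample covariance (p x p).
#' @param n_obs Number of observations behind `C`.
#' @return Shrunk covariance matrix.
#' @export
oas_shrinkage <- function(C, n_obs) {
  p <- nrow(C)
  mu <- sum(diag(C)) / p
  tr2 <- sum(C^2)
  num <- (1 - 2 / p) * tr2 + (sum(diag(C)))^2
  den <- (n_obs + 1 - 2 / p) * (tr2 - (sum(diag(C)))^2 / p)
  rho <- if (den <= 0) 1 else min(1, num / den)
  (1 - rho) * C + rho * mu * diag(p)
}

#' Log-Euclidean geometric mean of SPD matrices
#'
#' @param covs Array (n x p x p) or list of SPD matrices.
#' @return The p x p geometric mean.
#' @export
spd_geometric_mean <- function(covs) {
  if (is.array(covs) && length(dim(covs)) == 3)
    covs <- lapply(seq_len(dim(covs)[1]), function(i) covs[i, , ])
  logs <- lapply(covs, spd_logm)
  spd_expm(Reduce(`+`, logs) / length(logs))
}

#' Tangent-space vectorisation of an SPD matrix
#'
#' Maps `C` to the tangent space at `ref` via
#' `logm(ref^{-1/2} C ref^{-1/2})` and returns the p diagonal entries
#' followed by the sqrt(2)-weighted upper off-diagonal entries, so the
#' Euclidean norm of the vector equals the affine-invariant distance.
#' With `ref = NULL` (identity) this reduces to the matrix logarithm.
#'
#' @param C SPD matrix.
#' @param ref Reference SPD matrix, or `NULL` for the identity.
#' @return Numeric vector of length p(p+1)/2.
#' @export
tangent_vector <- function(C, ref = NULL) {
  W <- if (is.null(ref)) spd_logm(C) else {
    R <- spd_invsqrtm(ref)
    spd_logm(R %*% C %*% R)
  }
  c(diag(W), sqrt(2) * W[upper.tri(W)])
}
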
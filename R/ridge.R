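## Ridge regression with generalised cross-validation over a log-spaced
## penalty grid, via the SVD of the standardised design. This is the
## level-1 and level-2 learner of the stacked age-prediction models.

default_lambdas <- function() 10^seq(-3, 5, length.out = 30)

ridge_fit <- function(X, y, lambdas = default_lambdas()) {
  X <- as.matrix(X)
  n <- nrow(X)
  my <- mean(y)
  mx <- colMeans(X)
  sx <- apply(X, 2, sd)
  keep <- which(sx > 0)
  if (!length(keep) || n < 3) {
    return(structure(list(intercept = my, beta = rep(0, ncol(X)),
                          lambda = NA_real_, keep = integer(0),
                          mx = mx, sx = sx),
                     class = "ridge_gcv"))
  }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mx[keep]), 2, sx[keep], "/")
  yc <- y - my
  sv <- svd(Xs)
  d <- sv$d
  uty <- crossprod(sv$u, yc)
  gcv <- vapply(lambdas, function(l) {
    shr <- d^2 / (d^2 + l)
    fit <- sv$u %*% (shr * uty)
    rss <- sum((yc - fit)^2)
    df <- sum(shr) + 1
    n * rss / (n - df)^2
  }, numeric(1))
  l <- lambdas[which.min(gcv)]
  beta_s <- sv$v %*% ((d / (d^2 + l)) * uty)
  beta <- rep(0, ncol(X))
  beta[keep] <- beta_s / sx[keep]
  structure(list(intercept = my - sum(beta[keep] * mx[keep]), beta = beta,
                 lambda = l, keep = keep, mx = mx, sx = sx),
            class = "ridge_gcv")
}

#' @export
predict.ridge_gcv <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$beta) + object$intercept
}
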
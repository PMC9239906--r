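`%||%` <- function(x, y) if (is.null(x)) y else x

## Symmetric-eigendecomposition square root so that singular (including zero)
## covariance matrices are valid inputs; chol() would reject them.
mvn_sqrt <- function(sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  }
  vals <- pmax(ev$values, 0)
  ev$vectors %*% (sqrt(vals) * t(ev$vectors))
}

## n draws from N(0, sigma); rows are draws. Uses the current RNG state.
mvn_draw <- function(n, sigma, sqrt_sigma = NULL) {
  d <- ncol(sigma)
  rt <- sqrt_sigma %||% mvn_sqrt(sigma)
  matrix(stats::rnorm(n * d), n, d) %*% rt
}

is_psd <- function(mat, tol = 1e-8) {
  if (!isSymmetric(unname(mat), tol = 1e-8)) return(FALSE)
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev), 1)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 1

is_prob <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 0 && x <= 1
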
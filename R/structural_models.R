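## Shared design: intercept, exposure-category indicators (level 1 reference),
## confounder main effects. Used by the mediator and total-association models.
te_design <- function(cat, C) {
  n <- length(cat)
  D <- matrix(0, n, 4L, dimnames = list(NULL, paste0("cat", 2:5)))
  for (j in 2:5) D[, j - 1L] <- as.numeric(cat == j)
  cbind("(Intercept)" = rep(1, n), D, C)
}

## Outcome design: te_design columns plus mediator main effects and all
## mediator-by-confounder products.
outcome_design <- function(cat, M, C) {
  inter <- matrix(0, nrow(M), 3L * ncol(C))
  nm <- character(3L * ncol(C))
  idx <- 0L
  for (q in 1:3) {
    for (k in seq_len(ncol(C))) {
      idx <- idx + 1L
      inter[, idx] <- M[, q] * C[, k]
      nm[idx] <- paste0(colnames(M)[q], ":", colnames(C)[k])
    }
  }
  colnames(inter) <- nm
  cbind(te_design(cat, C), M, inter)
}

check_categories <- function(cat) {
  present <- tabulate(cat, nbins = 5L)
  if (any(present == 0L)) {
    stop("empty exposure category: ",
         paste(which(present == 0L), collapse = ", "), call. = FALSE)
  }
  invisible(present)
}

## Least-squares fit on an explicit design; errors on rank deficiency naming
## the collinear columns. y may be a matrix (one column per response).
ls_fit <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p) {
    stop(sprintf("need more rows (%d) than design columns (%d)", n, p),
         call. = FALSE)
  }
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qrx, y)
  res <- y - X %*% coef
  ri <- chol2inv(qr.R(qrx))
  o <- order(qrx$pivot)
  xtx_inv <- ri[o, o, drop = FALSE]
  list(coef = coef, residuals = res, n = n, p = p, rank = qrx$rank,
       xtx_inv = xtx_inv)
}

## Split a coefficient vector laid out by outcome_design()/te_design() into
## named parts for fast linear-predictor evaluation.
coef_parts <- function(coef, k, with_mediators) {
  cat <- c(0, coef[2:5])
  pos <- 5L
  conf <- coef[pos + seq_len(k)]; pos <- pos + k
  if (with_mediators) {
    med <- coef[pos + (1:3)]; pos <- pos + 3L
    inter <- matrix(coef[pos + seq_len(3L * k)], nrow = 3L, byrow = TRUE)
  } else {
    med <- NULL; inter <- NULL
  }
  list(intercept = unname(coef[1]), cat = unname(cat), med = unname(med),
       conf = unname(conf), inter = inter)
}

#' Fit the joint mediator model
#'
#' Three seemingly-unrelated least-squares regressions of the mediators on a
#' shared design: exposure-category indicators with the lowest category as
#' reference, plus confounder main effects (mediator-by-confounder
#' interactions belong to the outcome model only). The joint law of the
#' mediators given (X, C) is captured by the coefficient matrix together with
#' the residual covariance
#' (cross-product of residuals divided by n - p); residual rows are retained
#' for the empirical draw dialect.
#'
#' @param table a `cohort_table` with assigned exposure categories and no
#'   missing analysis values.
#' @return a `mediator_model` object.
#' @export
fit_mediator_model <- function(table) {
  fit_mediator_core(analysis_arrays(table))
}

## Plain-array view of the analysis columns; the bootstrap loop works on
## these directly to avoid per-replicate data.frame overhead.
analysis_arrays <- function(table) {
  list(cat = category_vector(table), C = conf_matrix(table),
       M = med_matrix(table), y = outcome_vector(table))
}

fit_mediator_core <- function(arr) {
  cat <- arr$cat
  check_categories(cat)
  C <- arr$C
  M <- arr$M
  X <- te_design(cat, C)
  fit <- ls_fit(X, M)
  sigma <- crossprod(fit$residuals) / (fit$n - fit$p)
  structure(list(coef = fit$coef, sigma = sigma, residuals = fit$residuals,
                 n = fit$n, p = fit$p, rank = fit$rank,
                 xtx_inv = fit$xtx_inv,
                 se = matrix(sqrt(outer(diag(fit$xtx_inv), diag(sigma))),
                             fit$p, 3L,
                             dimnames = list(colnames(X), colnames(M))),
                 confounders = colnames(C), mediators = colnames(M)),
            class = "mediator_model")
}

#' Fit the outcome model
#'
#' Linear model for the outcome on exposure-category indicators, mediator
#' main effects, confounder main effects, and all mediator-by-confounder
#' product terms. Its prediction with mediators set to supplied values is the
#' plug-in for the potential outcome under a mediator intervention.
#'
#' @inheritParams fit_mediator_model
#' @return an `outcome_model` object.
#' @export
fit_outcome_model <- function(table) {
  fit_outcome_core(analysis_arrays(table))
}

fit_outcome_core <- function(arr) {
  cat <- arr$cat
  check_categories(cat)
  C <- arr$C
  M <- arr$M
  y <- arr$y
  X <- outcome_design(cat, M, C)
  fit <- ls_fit(X, y)
  sigma2 <- sum(fit$residuals^2) / (fit$n - fit$p)
  se <- stats::setNames(sqrt(diag(fit$xtx_inv) * sigma2), colnames(X))
  structure(list(coef = drop(fit$coef), sigma2 = sigma2, n = fit$n,
                 p = fit$p, rank = fit$rank, se = se,
                 parts = coef_parts(drop(fit$coef), ncol(C), TRUE),
                 confounders = colnames(C), mediators = colnames(M)),
            class = "outcome_model")
}

#' Fit the total-association model
#'
#' Linear model for the outcome on exposure-category indicators and
#' confounder main effects only (no mediators): the component behind the
#' adjusted total association.
#'
#' @inheritParams fit_mediator_model
#' @return a `total_model` object.
#' @export
fit_total_model <- function(table) {
  fit_total_core(analysis_arrays(table))
}

fit_total_core <- function(arr) {
  cat <- arr$cat
  check_categories(cat)
  C <- arr$C
  y <- arr$y
  X <- te_design(cat, C)
  fit <- ls_fit(X, y)
  sigma2 <- sum(fit$residuals^2) / (fit$n - fit$p)
  se <- stats::setNames(sqrt(diag(fit$xtx_inv) * sigma2), colnames(X))
  structure(list(coef = drop(fit$coef), sigma2 = sigma2, n = fit$n,
                 p = fit$p, rank = fit$rank, se = se,
                 parts = coef_parts(drop(fit$coef), ncol(C), FALSE),
                 confounders = colnames(C)),
            class = "total_model")
}

#' Fit all three regression components
#'
#' @inheritParams fit_mediator_model
#' @return a list of class `structural_models` with elements `mediator`,
#'   `outcome`, `total`.
#' @export
fit_models <- function(table) {
  fit_models_core(analysis_arrays(table))
}

fit_models_core <- function(arr) {
  structure(list(mediator = fit_mediator_core(arr),
                 outcome = fit_outcome_core(arr),
                 total = fit_total_core(arr)),
            class = "structural_models")
}

#' @export
print.mediator_model <- function(x, ...) {
  cat("mediator_model: 3 responses,", x$p, "design columns, n =", x$n, "\n")
  invisible(x)
}

#' @export
print.outcome_model <- function(x, ...) {
  cat("outcome_model:", x$p, "design columns (incl. mediator x confounder",
      "interactions), n =", x$n, "\n")
  invisible(x)
}

#' @export
print.total_model <- function(x, ...) {
  cat("total_model:", x$p, "design columns, n =", x$n, "\n")
  invisible(x)
}

## Model-predicted mediator means at a set exposure level for given
## confounder rows (n x 3).
med_mu <- function(model, level, C) {
  coef <- model$coef
  mu <- matrix(coef[1, ], nrow(C), 3L, byrow = TRUE)
  if (level > 1L) mu <- mu + matrix(coef[level, ], nrow(C), 3L, byrow = TRUE)
  mu + C %*% coef[5L + seq_len(ncol(C)), , drop = FALSE]
}

## One set of n residual draws under the requested dialect.
med_noise <- function(model, n, dialect, sqrt_sigma = NULL) {
  switch(dialect,
         gaussian = mvn_draw(n, model$sigma, sqrt_sigma),
         empirical = model$residuals[sample.int(model$n, n, replace = TRUE), ,
                                     drop = FALSE],
         stop("unknown draw dialect: ", dialect, call. = FALSE))
}

#' Draw counterfactual mediator vectors
#'
#' Random draws from the fitted joint mediator distribution with the exposure
#' set to `level`, conditional on each supplied confounder row. The
#' `gaussian` dialect adds trivariate Gaussian noise with the fitted residual
#' covariance; the `empirical` dialect resamples whole residual rows, which
#' preserves the cross-mediator dependence without assuming normality. Uses
#' the current RNG state (call `set.seed()` for reproducibility).
#'
#' @param model a fitted `mediator_model`.
#' @param level exposure category in 1..5 under which to draw.
#' @param confounders numeric matrix of confounder rows (n x k) in the order
#'   used at fit time.
#' @param K number of draws per row (>= 1).
#' @param dialect `"gaussian"` or `"empirical"`.
#' @return an n x K x 3 array of draws.
#' @export
draw_mediators <- function(model, level, confounders, K = 1L,
                           dialect = c("gaussian", "empirical")) {
  dialect <- match.arg(dialect)
  if (!is_count(K)) stop("K must be a positive integer", call. = FALSE)
  if (!(level %in% 1:5)) stop("level must be in 1..5", call. = FALSE)
  C <- as.matrix(confounders)
  n <- nrow(C)
  mu <- med_mu(model, as.integer(level), C)
  sqrt_sigma <- if (dialect == "gaussian") mvn_sqrt(model$sigma) else NULL
  noise <- med_noise(model, n * K, dialect, sqrt_sigma)
  out <- array(NA_real_, dim = c(n, K, 3L),
               dimnames = list(NULL, NULL, model$mediators))
  for (q in 1:3) out[, , q] <- mu[, q] + matrix(noise[, q], n, K)
  out
}

## Fast linear predictors (no model-matrix allocation); M is n x 3, C n x k.
outcome_lp <- function(model, level, M, C) {
  b <- model$parts
  lp <- b$intercept + b$cat[level] + drop(M %*% b$med) + drop(C %*% b$conf)
  lp + rowSums((M %*% b$inter) * C)
}

total_lp <- function(model, level, C) {
  b <- model$parts
  b$intercept + b$cat[level] + drop(C %*% b$conf)
}

#' Predict the expected outcome at set exposure level and mediator values
#'
#' Evaluates the fitted outcome model's linear predictor with the exposure
#' indicators set to `level` and the mediators set to the supplied values:
#' the plug-in for the potential outcome under a mediator intervention.
#'
#' @param model a fitted `outcome_model`.
#' @param level exposure category in 1..5.
#' @param mediators a 3-vector or an n x 3 matrix of mediator values.
#' @param confounders a k-vector or an n x k matrix of confounder values.
#' @return expected outcome(s) (kg/m^2).
#' @export
predict_outcome <- function(model, level, mediators, confounders) {
  if (!(level %in% 1:5)) stop("level must be in 1..5", call. = FALSE)
  M <- if (is.matrix(mediators)) mediators else matrix(mediators, nrow = 1)
  C <- if (is.matrix(confounders)) confounders else matrix(confounders, nrow = 1)
  if (ncol(M) != 3L) stop("mediators must have 3 columns", call. = FALSE)
  if (nrow(M) != nrow(C)) stop("mediators and confounders must align",
                               call. = FALSE)
  if (!all(is.finite(M)) || !all(is.finite(C))) {
    stop("non-finite mediator or confounder values", call. = FALSE)
  }
  drop(outcome_lp(model, as.integer(level), M, C))
}
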
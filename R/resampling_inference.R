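#' Bootstrap settings
#'
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer master seed; per-replicate substreams are derived from
#'   it deterministically.
#' @param ci_level confidence level in (0, 1); default 0.95.
#' @param method interval type; only `"percentile"` is implemented.
#' @return a `bootstrap_settings` object.
#' @export
bootstrap_settings <- function(B = 1000L, seed = 1L, ci_level = 0.95,
                               method = "percentile") {
  if (!is_count(B) || B < 2) stop("B must be an integer >= 2", call. = FALSE)
  if (!(is.numeric(ci_level) && ci_level > 0 && ci_level < 1)) {
    stop("ci_level must lie strictly between 0 and 1", call. = FALSE)
  }
  method <- match.arg(method, "percentile")
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 ci_level = ci_level, method = method),
            class = "bootstrap_settings")
}

#' Nonparametric bootstrap confidence intervals for all effect estimates
#'
#' For each replicate, resamples the rows of the analysis table with
#' replacement, refits the mediator, outcome and total models, and recomputes
#' every requested contrast (Differences are computed within each replicate,
#' so their intervals reflect the joint sampling law). Intervals are
#' percentile bootstrap: quantiles of the replicate values with linear
#' interpolation between order statistics at plotting positions k/(B+1)
#' (`stats::quantile` type 6), so with B = 2 the interval is the range of the
#' two replicate values. Replicates in which a resample empties an exposure
#' category or makes the design rank deficient are recorded as failures and
#' redrawn, up to 2B total attempts.
#'
#' @param table a complete-case `cohort_table` with assigned categories.
#' @param est_settings an [estimation_settings()]; bootstrap replicates reuse
#'   its K and dialect with per-replicate seeds.
#' @param boot_settings a [bootstrap_settings()].
#' @param contrasts list of [contrast_spec()]s; defaults to all eight.
#' @return an `interval_estimates` data frame with one row per contrast and
#'   quantity (`adj_ta`, `idm_de`, `difference`): columns `scheme`, `label`,
#'   `quantity`, `estimate`, `lower`, `upper`. Attributes: `B`, `ci_level`,
#'   `failures` (failed replicates), and `replicates` (B x rows matrix of
#'   replicate values).
#' @export
bootstrap_effects <- function(table, est_settings = estimation_settings(),
                              boot_settings = bootstrap_settings(),
                              contrasts = all_contrasts()) {
  arr <- analysis_arrays(table)
  models <- fit_models_core(arr)
  point <- estimate_all_core(arr$C, models, est_settings, contrasts)
  n <- nrow(table)
  B <- boot_settings$B

  set.seed(boot_settings$seed)
  seed_pool <- sample.int(2147483646L, 2L * B)
  n_quant <- nrow(point)
  reps <- matrix(NA_real_, B, 3L * n_quant)
  b <- 0L; attempt <- 0L; failures <- 0L
  while (b < B) {
    attempt <- attempt + 1L
    if (attempt > 2L * B) {
      stop(sprintf(
        "bootstrap failure cap exceeded: %d failed replicates in %d attempts",
        failures, attempt - 1L), call. = FALSE)
    }
    s <- seed_pool[attempt]
    set.seed(s)
    idx <- sample.int(n, n, replace = TRUE)
    arr_b <- list(cat = arr$cat[idx], C = arr$C[idx, , drop = FALSE],
                  M = arr$M[idx, , drop = FALSE], y = arr$y[idx])
    models_b <- tryCatch(fit_models_core(arr_b), error = function(e) e)
    if (inherits(models_b, "error")) {
      failures <- failures + 1L
      next
    }
    st <- est_settings
    st$seed <- s
    est_b <- estimate_all_core(arr_b$C, models_b, st, contrasts)
    b <- b + 1L
    reps[b, ] <- c(est_b$adj_ta, est_b$idm_de, est_b$difference)
  }

  probs <- c((1 - boot_settings$ci_level) / 2,
             1 - (1 - boot_settings$ci_level) / 2)
  qs <- apply(reps, 2L, stats::quantile, probs = probs, type = 6,
              names = FALSE)
  quantity <- rep(c("adj_ta", "idm_de", "difference"), each = n_quant)
  out <- data.frame(scheme = rep(point$scheme, 3L),
                    label = rep(point$label, 3L),
                    quantity = quantity,
                    estimate = c(point$adj_ta, point$idm_de, point$difference),
                    lower = qs[1L, ], upper = qs[2L, ],
                    stringsAsFactors = FALSE)
  structure(out, B = B, ci_level = boot_settings$ci_level,
            failures = failures, replicates = reps, n = n,
            K = est_settings$K,
            class = c("interval_estimates", "data.frame"))
}
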
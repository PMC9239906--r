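#' Monte Carlo estimation settings
#'
#' @param K Monte Carlo expansion factor: counterfactual mediator draws per
#'   individual (the "K-fold expanded dataset"); default 1000.
#' @param dialect mediator draw dialect, `"gaussian"` or `"empirical"`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param common_draws reuse the same mediator draws in both arms of each
#'   contrast (variance reduction; with the default model forms the Monte
#'   Carlo noise then cancels exactly).
#' @return an `estimation_settings` object.
#' @export
estimation_settings <- function(K = 1000L,
                                dialect = c("gaussian", "empirical"),
                                seed = 1L, common_draws = TRUE) {
  dialect <- match.arg(dialect)
  if (!is_count(K)) stop("K must be a positive integer", call. = FALSE)
  structure(list(K = as.integer(K), dialect = dialect, seed = seed,
                 common_draws = isTRUE(common_draws)),
            class = "estimation_settings")
}

#' Specify an exposure contrast and its mediator reference level
#'
#' Scheme `"shift_to_reference"` contrasts category `a` against the lowest
#' category with the mediators drawn under the lowest category
#' (`b = 1`, `m_level = 1`). Scheme `"shift_down_one"` contrasts adjacent
#' categories `a` versus `a - 1` with the mediators drawn under the lower of
#' the two (`m_level = a - 1`), i.e. parental behaviour shifted down one
#' liability category. The degenerate identity contrast `a = b = 1` is
#' permitted and estimates zero by construction.
#'
#' @param scheme `"shift_to_reference"` or `"shift_down_one"`.
#' @param a the higher exposure category of the contrast.
#' @return a `contrast_spec` with fields `scheme`, `a`, `b`, `m_level`,
#'   `label`.
#' @export
contrast_spec <- function(scheme = c("shift_to_reference", "shift_down_one"),
                          a) {
  scheme <- match.arg(scheme)
  if (!(a %in% 1:5)) stop("a must be in 1..5", call. = FALSE)
  a <- as.integer(a)
  if (scheme == "shift_to_reference") {
    b <- 1L; m_level <- 1L
    label <- as.character(a)
  } else {
    if (a < 2L) stop("shift_down_one requires a in 2..5", call. = FALSE)
    b <- a - 1L; m_level <- b
    label <- paste0(a, b)
  }
  structure(list(scheme = scheme, a = a, b = b, m_level = m_level,
                 label = label), class = "contrast_spec")
}

#' All eight reported contrasts
#'
#' The four shift-to-reference contrasts (2..5 vs 1) and the four
#' shift-down-one contrasts (2 vs 1, ..., 5 vs 4).
#'
#' @return a list of [contrast_spec()] objects.
#' @export
all_contrasts <- function() {
  c(lapply(2:5, function(a) contrast_spec("shift_to_reference", a)),
    lapply(2:5, function(a) contrast_spec("shift_down_one", a)))
}

#' Estimate the interventional disparity measure direct effect (IDM-DE)
#'
#' Monte Carlo g-computation: for each row i of the table and each of K
#' draws, a counterfactual mediator vector is drawn from the fitted joint
#' mediator law at the contrast's reference level given the row's
#' confounders; the fitted outcome model is evaluated at both exposure
#' levels with the mediators set to the draw, and the differences are
#' averaged over draws and rows. Averaging over all rows standardizes over
#' the empirical confounder distribution (the sample analogue of weighting
#' by Pr(C = c)).
#'
#' @param table a `cohort_table` (supplies the confounder rows).
#' @param mediator_model a fitted [fit_mediator_model()].
#' @param outcome_model a fitted [fit_outcome_model()].
#' @param contrast a [contrast_spec()].
#' @param settings an [estimation_settings()].
#' @return the IDM-DE estimate (kg/m^2), with attribute `mc_se`, the Monte
#'   Carlo standard error across the K draw means (0 when common draws make
#'   the per-draw values identical).
#' @export
estimate_idm_de <- function(table, mediator_model, outcome_model, contrast,
                            settings = estimation_settings()) {
  estimate_idm_de_core(conf_matrix(table), mediator_model, outcome_model,
                       contrast, settings)
}

estimate_idm_de_core <- function(C, mediator_model, outcome_model, contrast,
                                 settings) {
  stopifnot(inherits(contrast, "contrast_spec"))
  if (!is.null(settings$seed)) set.seed(settings$seed)
  n <- nrow(C)
  K <- settings$K
  b <- outcome_model$parts
  mu <- med_mu(mediator_model, contrast$m_level, C)
  base <- b$intercept + drop(C %*% b$conf)   # mediator-free part, both arms
  sqrt_sigma <- if (settings$dialect == "gaussian") {
    mvn_sqrt(mediator_model$sigma)
  } else NULL
  ## Mediator-dependent part of the outcome linear predictor. For row i with
  ## mediator vector m: m' betaM + m' W c_i = sum_q m_q * Q_iq with
  ## Q = C W' + 1 betaM' fixed across draws, so it is precomputed once.
  q_mat <- C %*% t(b$inter) + matrix(b$med, n, 3L, byrow = TRUE)
  ## The K draws are processed in draw-major blocks of stacked rows, so the
  ## expanded dataset is never materialized: the per-row vectors (mu, Q,
  ## confounder part) recycle exactly into each block of n * nb draws.
  m_part <- function(noise) {
    part <- (noise[, 1L] + mu[, 1L]) * q_mat[, 1L]
    part <- part + (noise[, 2L] + mu[, 2L]) * q_mat[, 2L]
    part + (noise[, 3L] + mu[, 3L]) * q_mat[, 3L]
  }
  block <- max(1L, min(K, as.integer(5e5 %/% n)))
  per_draw <- numeric(K)
  done <- 0L
  while (done < K) {
    nb <- min(block, K - done)
    part_a <- m_part(med_noise(mediator_model, n * nb, settings$dialect,
                               sqrt_sigma))
    part_b <- if (settings$common_draws) part_a else {
      m_part(med_noise(mediator_model, n * nb, settings$dialect, sqrt_sigma))
    }
    d <- (base + b$cat[contrast$a] + part_a) -
      (base + b$cat[contrast$b] + part_b)
    per_draw[done + seq_len(nb)] <- colMeans(matrix(d, n, nb))
    done <- done + nb
  }
  est <- mean(per_draw)
  attr(est, "mc_se") <- if (K > 1) stats::sd(per_draw) / sqrt(K) else NA_real_
  est
}

#' Estimate the adjusted total association (Adj-TA)
#'
#' Standardized contrast of the fitted total-association model between the
#' two exposure levels, averaged over the empirical confounder rows. With
#' the default main-effects model this equals the difference of the two
#' category coefficients; the standardization loop is kept so that
#' extensions with exposure-confounder terms remain correct.
#'
#' @param table a `cohort_table`.
#' @param total_model a fitted [fit_total_model()].
#' @param contrast a [contrast_spec()].
#' @return the Adj-TA estimate (kg/m^2).
#' @export
estimate_adj_ta <- function(table, total_model, contrast) {
  estimate_adj_ta_core(conf_matrix(table), total_model, contrast)
}

estimate_adj_ta_core <- function(C, total_model, contrast) {
  stopifnot(inherits(contrast, "contrast_spec"))
  mean(total_lp(total_model, contrast$a, C) -
         total_lp(total_model, contrast$b, C))
}

#' Estimate all reported contrasts
#'
#' Computes Adj-TA, IDM-DE and their Difference (Adj-TA minus IDM-DE, the
#' portion of the disparity removable by the mediator intervention) for the
#' four shift-to-reference and four shift-down-one contrasts. Mediator draws
#' are seeded per reference level, so contrasts sharing a mediator reference
#' level (in particular the first contrast of each scheme) use identical
#' draws, and the whole table is deterministic given `settings$seed`.
#'
#' @param table a `cohort_table`.
#' @param models a [fit_models()] list (or one assembled from the individual
#'   fits).
#' @param settings an [estimation_settings()].
#' @param contrasts list of [contrast_spec()]s; defaults to all eight.
#' @return an `effect_estimates` data frame with columns `scheme`, `label`,
#'   `adj_ta`, `idm_de`, `difference`, and attributes `n`, `K`, `seed`.
#' @export
estimate_all <- function(table, models, settings = estimation_settings(),
                         contrasts = all_contrasts()) {
  estimate_all_core(conf_matrix(table), models, settings, contrasts)
}

estimate_all_core <- function(C, models, settings, contrasts) {
  stopifnot(inherits(models, "structural_models") || is.list(models))
  if (!is.null(settings$seed)) {
    set.seed(settings$seed)
    level_seeds <- sample.int(.Machine$integer.max, 5L)
  } else {
    level_seeds <- NULL
  }
  rows <- lapply(contrasts, function(ct) {
    st <- settings
    st$seed <- if (is.null(level_seeds)) NULL else level_seeds[ct$m_level]
    idm <- estimate_idm_de_core(C, models$mediator, models$outcome, ct, st)
    adj <- estimate_adj_ta_core(C, models$total, ct)
    data.frame(scheme = ct$scheme, label = ct$label,
               adj_ta = adj, idm_de = as.numeric(idm),
               difference = adj - as.numeric(idm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n = models$outcome$n, K = settings$K, seed = settings$seed,
            class = c("effect_estimates", "data.frame"))
}
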
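#' Quintile-conditional means of a standard normal
#'
#' The expected value of a standard normal variable given that it falls in
#' its j-th quintile: `lambda_j = (phi(z_{j-1}) - phi(z_j)) / 0.2` with
#' `z = (-Inf, qnorm(.2), qnorm(.4), qnorm(.6), qnorm(.8), Inf)`. These map a
#' continuous standardized score to its category-conditional mean; their
#' variance `0.2 * sum(lambda^2)` (about 0.897) is the attenuation factor the
#' categorical-pathway calibration corrects by.
#'
#' @return a numeric 5-vector, symmetric about zero.
#' @export
quintile_conditional_means <- function() {
  z <- c(-Inf, stats::qnorm(c(0.2, 0.4, 0.6, 0.8)), Inf)
  (stats::dnorm(z[1:5]) - stats::dnorm(z[2:6])) / 0.2
}

## Category-level effective exposure values under a generator config.
category_exposure_values <- function(config) {
  config$pgs_mean + config$pgs_sd * quintile_conditional_means()
}

true_effects_frame <- function(contrasts, adj, idm, valid) {
  out <- data.frame(scheme = vapply(contrasts, `[[`, "", "scheme"),
                    label = vapply(contrasts, `[[`, "", "label"),
                    adj_ta = adj, idm_de = idm, difference = adj - idm,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("true_effects", "data.frame"),
            closed_form_valid = valid$closed_form,
            assumption_compliant = valid$compliant)
}

closed_form_validity <- function(config) {
  no_inter <- is.null(config$interactionMC) || all(config$interactionMC == 0)
  pgs_indep_c <- config$pgs_on_maternal_bmi == 0
  list(closed_form = no_inter &&
         (config$pathway == "categorical" || pgs_indep_c),
       compliant = config$pathway == "categorical")
}

#' Closed-form true effects under a generator configuration
#'
#' Analytic values of the estimands under the linear-Gaussian structural law.
#' With `g_j` the category-level exposure value (the score mean plus the
#' score SD times the quintile-conditional mean), the direct effect of
#' contrast (a vs b) is `betaX * (g_a - g_b)` and the total association is
#' `(betaX + sum(betaM * alphaX)) * (g_a - g_b)`. Valid for categorical-
#' pathway configs, and for continuous-pathway configs with the score
#' independent of the confounders; interaction coefficients must be zero.
#' Only categorical-pathway configs are assumption-compliant for the
#' estimator (attribute `assumption_compliant`): under a continuous pathway
#' the residual within-quintile score confounds the mediator-outcome
#' relation, so the identified functional differs from this structural truth.
#'
#' @param config a [generator_config()].
#' @param contrasts list of [contrast_spec()]s; defaults to all eight.
#' @return a `true_effects` data frame (`scheme`, `label`, `adj_ta`,
#'   `idm_de`, `difference`) with validity attributes `closed_form_valid` and
#'   `assumption_compliant`.
#' @export
closed_form_effects <- function(config, contrasts = all_contrasts()) {
  stopifnot(inherits(config, "generator_config"))
  valid <- closed_form_validity(config)
  if (!valid$closed_form) {
    stop(paste0("closed form not applicable (interactions present, or ",
                "continuous pathway with score-confounder dependence); ",
                "use brute_force_effects()"), call. = FALSE)
  }
  g <- category_exposure_values(config)
  slope_ta <- config$betaX + sum(config$betaM * config$alphaX)
  dg <- vapply(contrasts, function(ct) g[ct$a] - g[ct$b], 0)
  true_effects_frame(contrasts, adj = slope_ta * dg,
                     idm = config$betaX * dg, valid = valid)
}

#' Brute-force true effects by simulation from the structural equations
#'
#' Simulates a large population from the configuration, draws counterfactual
#' mediator vectors from the true mediator law at each contrast's reference
#' level given each individual's confounders, evaluates the true outcome
#' equation at both exposure levels, and averages. For the total association
#' the mediators are drawn at each arm's own level (with shared residual
#' noise across arms for variance reduction). Monte Carlo standard errors of
#' both quantities are reported per contrast.
#'
#' @param config a categorical-pathway [generator_config()] (the
#'   assumption-compliant regime in which structural truth is the estimand).
#' @param n_large population size; below 1e5 a warning is issued because the
#'   Monte Carlo error is too large for oracle use.
#' @param seed integer seed.
#' @param contrasts list of [contrast_spec()]s; defaults to all eight.
#' @return a `true_effects` data frame with additional columns `mc_se_adj`
#'   and `mc_se_idm`.
#' @export
brute_force_effects <- function(config, n_large = 1e6, seed = 1L,
                                contrasts = all_contrasts()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$pathway != "categorical") {
    stop(paste0("brute-force truth is only defined for categorical-pathway ",
                "configs (the assumption-compliant regime)"), call. = FALSE)
  }
  if (n_large < 1e5) {
    warning("n_large < 1e5: Monte Carlo error may be too large for oracle use")
  }
  set.seed(seed)
  n <- as.integer(n_large)
  sex <- stats::rbinom(n, 1, config$p_boy)
  edu <- stats::rbinom(n, 1, config$p_high_edu)
  mbmi <- stats::rnorm(n, config$maternal_bmi_mean, config$maternal_bmi_sd)
  C <- cbind(sex, edu, mbmi)
  g <- category_exposure_values(config)
  W <- config$interactionMC

  true_y <- function(g_level, M) {
    y <- config$beta0 + config$betaX * g_level + drop(M %*% config$betaM) +
      drop(C %*% config$betaC)
    if (!is.null(W)) y <- y + rowSums((M %*% W) * C)
    y
  }
  true_med <- function(g_level, U) {
    matrix(config$alpha0, n, 3, byrow = TRUE) + outer(rep(g_level, n),
                                                      config$alphaX) +
      C %*% t(config$alphaC) + U
  }

  adj <- idm <- se_adj <- se_idm <- numeric(length(contrasts))
  for (i in seq_along(contrasts)) {
    ct <- contrasts[[i]]
    U <- mvn_draw(n, config$sigma_u)
    m_ref <- true_med(g[ct$m_level], U)
    d_idm <- true_y(g[ct$a], m_ref) - true_y(g[ct$b], m_ref)
    d_adj <- true_y(g[ct$a], true_med(g[ct$a], U)) -
      true_y(g[ct$b], true_med(g[ct$b], U))
    idm[i] <- mean(d_idm); se_idm[i] <- stats::sd(d_idm) / sqrt(n)
    adj[i] <- mean(d_adj); se_adj[i] <- stats::sd(d_adj) / sqrt(n)
  }
  out <- true_effects_frame(contrasts, adj, idm,
                            closed_form_validity(config))
  out$mc_se_adj <- se_adj
  out$mc_se_idm <- se_idm
  out
}
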
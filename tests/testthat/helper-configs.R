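# Shared fixtures: structural configurations with known coefficients used to
# validate the estimator against the oracles, plus a small cohort data frame
# builder for I/O tests.

# Assumption-compliant regime: exposure effects act only through the quintile
# category, so the categorical regression models are correctly specified and
# closed-form structural truth is the estimand. Residual noise is kept modest
# so finite-sample estimates sit close to truth.
validation_config <- function(...) {
  args <- list(
    pathway = "categorical",
    alpha0 = c(0.1, -0.1, 0.05),
    alphaX = c(0.25, 0.45, -0.35),
    alphaC = matrix(c(-0.02, -0.05,  0.01,
                       0.00,  0.03,  0.01,
                       0.06, -0.04, -0.02), 3, byrow = TRUE),
    sigma_u = matrix(c(0.05,  0.010, -0.010,
                       0.010, 0.06,  -0.015,
                      -0.010, -0.015, 0.08), 3),
    beta0 = 14, betaX = 3.5,
    betaM = c(0.5, 0.8, -0.4),
    betaC = c(-0.15, -0.25, 0.28),
    sigma_e = 0.35)
  do.call(generator_config, utils::modifyList(args, list(...)))
}

# All mediator and exposure effects non-negative (monotone regime).
monotone_config <- function() {
  validation_config(alphaX = c(0.2, 0.45, 0.3), betaM = c(0.5, 0.8, 0.4))
}

small_cohort_df <- function(n = 5) {
  data.frame(id = seq_len(n),
             pgs = seq(-1, 1, length.out = n),
             med_emotional = rep(0.1, n),
             med_restriction = rep(-0.1, n),
             med_pressure = rep(0.2, n),
             outcome_bmi = seq(18, 21, length.out = n),
             sex = rep_len(c(0, 1), n),
             maternal_education = rep_len(c(1, 0), n),
             maternal_bmi = rep(23, n))
}

# Conservative standard error for the contrast (a vs b) of a fitted
# category-coefficient model: exact for b = 1 (reference), an upper bound
# otherwise.
catdiff_se <- function(model, a, b) {
  se <- model$se
  sa <- if (a == 1) 0 else se[[paste0("cat", a)]]
  sb <- if (b == 1) 0 else se[[paste0("cat", b)]]
  sa + sb
}
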
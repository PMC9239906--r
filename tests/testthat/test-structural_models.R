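# Expected design-scale coefficients implied by a categorical-pathway config:
# the models regress on category indicators (reference = 1) and confounders.
true_mediator_coef <- function(cfg) {
  g <- cfg$pgs_mean + cfg$pgs_sd * quintile_conditional_means()
  rbind("(Intercept)" = cfg$alpha0 + cfg$alphaX * g[1],
        t(vapply(2:5, function(j) cfg$alphaX * (g[j] - g[1]), numeric(3))),
        t(cfg$alphaC))
}

true_total_coef <- function(cfg) {
  g <- cfg$pgs_mean + cfg$pgs_sd * quintile_conditional_means()
  slope <- cfg$betaX + sum(cfg$betaM * cfg$alphaX)
  mean_med_ref <- cfg$alpha0 + cfg$alphaX * g[1]
  c(cfg$beta0 + cfg$betaX * g[1] + sum(cfg$betaM * mean_med_ref),
    slope * (g[2:5] - g[1]),
    cfg$betaC + drop(cfg$betaM %*% cfg$alphaC))
}

test_that("zero-noise mediator data are recovered exactly", {
  cfg <- validation_config(sigma_u = matrix(0, 3, 3))
  tab <- generate_cohort(cfg, n = 800, seed = 31)
  fit <- fit_mediator_model(tab)
  expect_equal(unname(fit$coef), unname(true_mediator_coef(cfg)),
               tolerance = 1e-8)
  expect_lt(max(abs(fit$sigma)), 1e-16)
})

test_that("zero-noise outcome data recover interaction coefficients exactly", {
  W <- matrix(c(0.3, -0.2, 0.05,
                0.1,  0.4, -0.03,
               -0.2,  0.1, 0.02), 3, byrow = TRUE)
  cfg <- validation_config(sigma_e = 0, interactionMC = W)
  tab <- generate_cohort(cfg, n = 1500, seed = 37)
  fit <- fit_outcome_model(tab)
  b <- fit$parts
  expect_equal(b$med, cfg$betaM, tolerance = 1e-8)
  expect_equal(b$conf, cfg$betaC, tolerance = 1e-8)
  expect_equal(unname(b$inter), unname(W), tolerance = 1e-8)
  g <- cfg$pgs_mean + cfg$pgs_sd * quintile_conditional_means()
  expect_equal(unname(b$cat[2:5]), cfg$betaX * (g[2:5] - g[1]),
               tolerance = 1e-8)
})

test_that("all three models recover known coefficients within 3 SE at n = 50,000", {
  cfg <- validation_config()
  tab <- generate_cohort(cfg, n = 50000, seed = 43)
  models <- fit_models(tab)

  zm <- abs(models$mediator$coef - true_mediator_coef(cfg)) / models$mediator$se
  expect_lt(max(zm), 3)

  bo <- models$outcome$parts
  g <- cfg$pgs_mean + cfg$pgs_sd * quintile_conditional_means()
  truth_out <- c(cfg$beta0 + cfg$betaX * g[1], cfg$betaX * (g[2:5] - g[1]),
                 cfg$betaC, cfg$betaM, rep(0, 9))
  zo <- abs(models$outcome$coef - truth_out) / models$outcome$se
  expect_lt(max(zo), 3)

  zt <- abs(models$total$coef - true_total_coef(cfg)) / models$total$se
  expect_lt(max(zt), 3)
})

test_that("interaction estimates stay near zero when none were generated", {
  cfg <- validation_config()
  tab <- generate_cohort(cfg, n = 50000, seed = 47)
  fit <- fit_outcome_model(tab)
  inter_idx <- grepl(":", names(fit$coef))
  z <- abs(fit$coef[inter_idx]) / fit$se[inter_idx]
  expect_lt(max(z), 3)
})

test_that("degenerate designs raise informative fitting errors", {
  tab <- generate_cohort(validation_config(), n = 400, seed = 51)
  # empty exposure category
  sub <- cohort_table(as.data.frame(tab)[tab$exposure_category != 3, ])
  expect_error(fit_mediator_model(sub), "empty exposure category: 3")
  expect_error(fit_outcome_model(sub), "empty exposure category")

  # collinear confounder
  df <- as.data.frame(tab)
  df$maternal_bmi2 <- df$maternal_bmi
  roles <- variable_roles(confounders = c("sex", "maternal_education",
                                          "maternal_bmi", "maternal_bmi2"))
  err <- expect_error(fit_total_model(cohort_table(df, roles)))
  expect_match(conditionMessage(err), "rank deficient")
  expect_match(conditionMessage(err), "maternal_bmi2")
})

test_that("fits are invariant to row permutation", {
  tab <- generate_cohort(validation_config(), n = 1000, seed = 53)
  set.seed(1)
  perm <- sample.int(1000)
  df <- as.data.frame(tab)[perm, ]
  df$id <- seq_len(1000)
  tab_p <- cohort_table(df)
  m1 <- fit_models(tab)
  m2 <- fit_models(tab_p)
  expect_equal(m1$mediator$coef, m2$mediator$coef, tolerance = 1e-10)
  expect_equal(m1$outcome$coef, m2$outcome$coef, tolerance = 1e-10)
  expect_equal(m1$total$coef, m2$total$coef, tolerance = 1e-10)
})

test_that("counterfactual mediator draws match the fitted law", {
  tab <- generate_cohort(validation_config(), n = 5000, seed = 59)
  fit <- fit_mediator_model(tab)
  c_row <- matrix(c(1, 0, 23), 1,
                  dimnames = list(NULL, fit$confounders))

  set.seed(7)
  dr <- draw_mediators(fit, level = 4, c_row, K = 10000)
  mu <- drop(intdisp:::med_mu(fit, 4L, c_row))
  for (q in 1:3) {
    expect_lt(abs(mean(dr[1, , q]) - mu[q]),
              4 * sqrt(fit$sigma[q, q]) / sqrt(10000))
  }

  set.seed(8)
  big <- draw_mediators(fit, level = 2, c_row, K = 100000)
  emp_cov <- cov(big[1, , ])
  expect_lt(max(abs(emp_cov - fit$sigma) / (abs(fit$sigma) + 1e-12)), 0.05)

  set.seed(9)
  emp <- draw_mediators(fit, level = 2, c_row, K = 100000,
                        dialect = "empirical")
  emp_cov2 <- cov(emp[1, , ])
  expect_lt(max(abs(emp_cov2 - fit$sigma) / (abs(fit$sigma) + 1e-12)), 0.05)

  expect_error(draw_mediators(fit, 2, c_row, K = 0), "positive integer")
  expect_error(draw_mediators(fit, 7, c_row, K = 1), "1..5")
  expect_error(draw_mediators(fit, 2, c_row, K = 1, dialect = "magic"))
})

test_that("zero residual covariance makes every draw the predicted mean", {
  cfg <- validation_config(sigma_u = matrix(0, 3, 3))
  tab <- generate_cohort(cfg, n = 800, seed = 61)
  fit <- fit_mediator_model(tab)
  C <- intdisp:::conf_matrix(tab)[1:10, , drop = FALSE]
  dr <- draw_mediators(fit, level = 3, C, K = 5)
  mu <- intdisp:::med_mu(fit, 3L, C)
  for (k in 1:5) expect_equal(unname(dr[, k, ]), unname(mu), tolerance = 1e-7)
})

test_that("predict_outcome matches manual arithmetic and is linear in level", {
  W <- matrix(c(0.3, -0.2, 0.05, 0.1, 0.4, -0.03, -0.2, 0.1, 0.02),
              3, byrow = TRUE)
  tab <- generate_cohort(validation_config(interactionMC = W),
                         n = 2000, seed = 67)
  fit <- fit_outcome_model(tab)

  m <- c(0.3, -0.2, 0.5)
  cv <- c(1, 0, 23)
  co <- fit$coef
  manual <- co[["(Intercept)"]] + co[["cat3"]] +
    sum(co[c("med_emotional", "med_restriction", "med_pressure")] * m) +
    sum(co[c("sex", "maternal_education", "maternal_bmi")] * cv) +
    sum(outer(m, cv) * matrix(co[grepl(":", names(co))], 3, byrow = TRUE))
  expect_equal(predict_outcome(fit, 3, m, cv), unname(manual),
               tolerance = 1e-12)

  expect_error(predict_outcome(fit, 3, c(m[1:2], NA), cv), "non-finite")

  # no exposure interactions: level contrasts are constant in (m, c)
  set.seed(11)
  diffs <- replicate(20, {
    mm <- rnorm(3); cc <- c(rbinom(1, 1, 0.5), rbinom(1, 1, 0.5), rnorm(1, 23, 3))
    predict_outcome(fit, 4, mm, cc) - predict_outcome(fit, 1, mm, cc)
  })
  expect_equal(max(diffs) - min(diffs), 0, tolerance = 1e-12)
  expect_equal(diffs[1], unname(co[["cat4"]]), tolerance = 1e-12)
})

test_that("fitted mediator residual covariance is positive semi-definite", {
  for (seed in 1:4) {
    tab <- generate_cohort(validation_config(), n = 300, seed = seed)
    fit <- fit_mediator_model(tab)
    ev <- eigen(fit$sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})
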
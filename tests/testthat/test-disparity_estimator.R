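test_that("contrast_spec encodes both intervention schemes", {
  c5 <- contrast_spec("shift_to_reference", 5)
  expect_equal(c5[c("a", "b", "m_level", "label")],
               list(a = 5L, b = 1L, m_level = 1L, label = "5"))
  c54 <- contrast_spec("shift_down_one", 5)
  expect_equal(c54[c("a", "b", "m_level", "label")],
               list(a = 5L, b = 4L, m_level = 4L, label = "54"))
  expect_error(contrast_spec("shift_to_reference", 6), "1..5")
  expect_error(contrast_spec("shift_down_one", 1), "2..5")
  labs <- vapply(all_contrasts(), `[[`, "", "label")
  expect_equal(labs, c("2", "3", "4", "5", "21", "32", "43", "54"))
})

test_that("the identity contrast estimates exactly zero", {
  tab <- generate_cohort(validation_config(), n = 500, seed = 71)
  models <- fit_models(tab)
  ct <- contrast_spec("shift_to_reference", 1)
  expect_identical(
    as.numeric(estimate_idm_de(tab, models$mediator, models$outcome, ct,
                               estimation_settings(K = 5, seed = 2))), 0)
  expect_identical(estimate_adj_ta(tab, models$total, ct), 0)
})

test_that("Monte Carlo IDM-DE collapses to the outcome category coefficient", {
  tab <- generate_cohort(validation_config(), n = 2000, seed = 73)
  models <- fit_models(tab)
  for (K in c(1, 7)) {
    for (j in 2:5) {
      ct <- contrast_spec("shift_to_reference", j)
      est <- estimate_idm_de(tab, models$mediator, models$outcome, ct,
                             estimation_settings(K = K, seed = 5))
      expect_equal(as.numeric(est),
                   unname(models$outcome$coef[[paste0("cat", j)]]),
                   tolerance = 1e-10)
    }
  }
  # the empirical draw dialect collapses identically under common draws
  ct <- contrast_spec("shift_down_one", 4)
  est <- estimate_idm_de(tab, models$mediator, models$outcome, ct,
                         estimation_settings(K = 3, seed = 5,
                                             dialect = "empirical"))
  expect_equal(as.numeric(est),
               unname(models$outcome$coef[["cat4"]] -
                        models$outcome$coef[["cat3"]]),
               tolerance = 1e-10)
})

test_that("standardized Adj-TA equals the category-coefficient difference", {
  tab <- generate_cohort(validation_config(), n = 2000, seed = 79)
  models <- fit_models(tab)
  for (j in 2:5) {
    ct <- contrast_spec("shift_to_reference", j)
    expect_equal(estimate_adj_ta(tab, models$total, ct),
                 unname(models$total$coef[[paste0("cat", j)]]),
                 tolerance = 1e-10)
  }
})

test_that("shift-down-one Adj-TA contrasts telescope to the top contrast", {
  tab <- generate_cohort(validation_config(), n = 3000, seed = 83)
  models <- fit_models(tab)
  est <- estimate_all(tab, models, estimation_settings(K = 4, seed = 3))
  s2 <- est[est$scheme == "shift_down_one", ]
  expect_equal(sum(s2$adj_ta), est$adj_ta[est$label == "5"],
               tolerance = 1e-10)
})

test_that("the first contrast of both schemes coincides under shared draws", {
  tab <- generate_cohort(validation_config(), n = 3000, seed = 89)
  models <- fit_models(tab)
  est <- estimate_all(tab, models, estimation_settings(K = 6, seed = 7))
  expect_identical(est$idm_de[est$label == "21"],
                   est$idm_de[est$label == "2"])
  expect_identical(est$adj_ta[est$label == "21"],
                   est$adj_ta[est$label == "2"])
})

test_that("difference column is exactly Adj-TA minus IDM-DE", {
  tab <- generate_cohort(validation_config(), n = 1500, seed = 97)
  est <- estimate_all(tab, fit_models(tab), estimation_settings(K = 3, seed = 1))
  expect_identical(est$difference, est$adj_ta - est$idm_de)
})

test_that("estimates track the oracle and tighten with sample size", {
  cfg <- validation_config()
  truth <- closed_form_effects(cfg)
  err <- vapply(c(2000, 20000), function(n) {
    tab <- generate_cohort(cfg, n = n, seed = 101)
    est <- estimate_all(tab, fit_models(tab), estimation_settings(K = 20, seed = 5))
    mean(abs(est$adj_ta - truth$adj_ta) + abs(est$idm_de - truth$idm_de))
  }, 0)
  expect_lt(err[2], err[1])
  # at n = 20,000 the per-contrast sampling SEs are ~0.01-0.02 kg/m^2, so a
  # mean absolute error beyond 0.05 would indicate systematic bias
  expect_lt(err[2], 0.05)
})

test_that("monotone configurations give IDM-DE below Adj-TA", {
  cfg <- monotone_config()
  tab <- generate_cohort(cfg, n = 20000, seed = 103)
  models <- fit_models(tab)
  est <- estimate_all(tab, models, estimation_settings(K = 10, seed = 5))
  for (i in seq_len(nrow(est))) {
    a <- as.integer(substr(est$label[i], 1, 1))
    b <- if (nchar(est$label[i]) == 2) a - 1L else 1L
    bound <- 2 * (catdiff_se(models$outcome, a, b) +
                    catdiff_se(models$total, a, b))
    expect_lt(est$idm_de[i], est$adj_ta[i] + bound)
  }
})
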
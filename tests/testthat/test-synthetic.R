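test_that("synthetic cohorts are deterministic given the configuration", {
  cfg <- synthetic_config(n = 200, tau = "linear", seed = 13)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- synthetic_config(n = 200, tau = "linear", seed = 14)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("noise-free potential outcomes obey the effect contracts exactly", {
  z <- generate_cohort(synthetic_config(n = 50, tau = "zero", noise_sd = 0,
                                        seed = 2))
  expect_equal(z$.truth_y1, z$.truth_y0)
  k <- generate_cohort(synthetic_config(n = 50, tau = "constant",
                                        tau_value = 2.5, noise_sd = 0,
                                        seed = 2))
  expect_equal(k$.truth_y1 - k$.truth_y0, rep(2.5, 50))
  # observed outcome is consistent with the latent potential outcomes
  expect_equal(k$BMI, ifelse(k$T == 1, k$.truth_y1, k$.truth_y0))
})

test_that("realized effects match their design expectation at large n", {
  coh <- generate_cohort(synthetic_config(n = 5000, tau = "linear", seed = 31))
  d <- coh$.truth_y1 - coh$.truth_y0
  # linear tau has design mean 0 on standardized covariates
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
  # nonlinear form switches sign smoothly
  nl <- generate_cohort(synthetic_config(n = 2000, tau = "nonlinear", seed = 8))
  expect_true(any(nl$.truth_tau > 0) && any(nl$.truth_tau < 0))
  expect_true(all(abs(nl$.truth_tau) <= 3))
})

test_that("treatment assignment is calibrated and overlap enforced", {
  coh <- generate_cohort(synthetic_config(n = 4000, seed = 5,
                                          assignment = list(type = "constant",
                                                            p = 0.3)))
  bounds <- qbinom(c(0.005, 0.995), 4000, 0.3) / 4000
  expect_gte(mean(coh$T), bounds[1])
  expect_lte(mean(coh$T), bounds[2])

  lg <- synthetic_config(n = 3000, seed = 5,
                         assignment = list(type = "logistic", intercept = 0.2,
                                           coef = c(Age = 0.8, FCVC = -0.5)))
  coh2 <- generate_cohort(lg)
  expect_true(all(coh2$.truth_p1 > 0 & coh2$.truth_p1 < 1))
  expect_gt(cor(coh2$Age, coh2$.truth_p1), 0.5)

  expect_error(synthetic_config(n = 100, assignment = list(type = "constant",
                                                           p = 1)), "overlap")
  expect_error(synthetic_config(n = 2), "n >= 4")
  expect_error(synthetic_config(n = 100, noise_sd = -1), "noise_sd")
})

test_that("true optimal decision follows the sign of tau, and truths strip", {
  expect_equal(true_optimal(c(2, 0, -1)), c("0", "tie", "1"))
  coh <- generate_cohort(synthetic_config(n = 20, tau = "linear", seed = 3))
  expect_equal(true_optimal(coh), decide_optimal(coh$.truth_tau))
  bare <- strip_truths(coh)
  expect_false(any(grepl("^\\.truth_", names(bare))))
  expect_error(true_optimal(bare), "truth_tau")
})
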
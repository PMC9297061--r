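test_that("covariate encoding one-hots categoricals drop-first and excludes the treatment", {
  coh <- validate_cohort(make_cohort_df(40, seed = 2))
  enc <- encode_covariates(coh, treatment = "CALC")
  cn <- colnames(enc$x)
  expect_false(any(grepl("^CALC", cn)))
  expect_false(any(cn %in% c("Height", "Weight", "BMI")))
  # 2-level Gender -> one indicator, reference level dropped
  expect_equal(sum(grepl("^Gender\\.", cn)), 1L)
  expect_equal(cn[grepl("^Gender", cn)], "Gender.Male")
  # k-level categoricals -> k-1 indicators for the levels present
  expect_equal(sum(grepl("^MTRANS\\.", cn)),
               length(unique(coh$MTRANS)) - 1L)
  expect_true(is.numeric(enc$x))
})

test_that("five-level transport feature yields four indicator columns", {
  coh <- make_cohort_df(40, seed = 2)
  coh$MTRANS <- rep(c("Automobile", "Bike", "Motorbike",
                      "Public_Transportation", "Walking"), 8)
  enc <- encode_covariates(validate_cohort(coh), treatment = "CALC")
  expect_equal(sum(grepl("^MTRANS\\.", colnames(enc$x))), 4L)
})

test_that("encoder reuse gives identical layout and rejects unseen levels", {
  coh <- validate_cohort(make_cohort_df(30, seed = 4))
  enc <- encode_covariates(coh, treatment = "CALC")
  new <- validate_cohort(make_cohort_df(10, seed = 5))
  enc2 <- encode_covariates(new, treatment = "CALC", encoder = enc$encoder)
  expect_equal(colnames(enc2$x), colnames(enc$x))
  new$MTRANS <- "Motorbike"   # level absent from the training data
  expect_error(encode_covariates(new, treatment = "CALC",
                                 encoder = enc$encoder), "unseen")
})

test_that("constant columns are dropped with a warning, truth columns never encoded", {
  coh <- validate_cohort(make_cohort_df(20, seed = 6))
  coh$SMOKE <- "No"
  coh$.truth_tau <- rnorm(20)
  expect_warning(enc <- encode_covariates(coh, treatment = "CALC"), "constant")
  expect_false(any(grepl("SMOKE|truth", colnames(enc$x))))
})

test_that("interaction design is [x, t, x*t] with the zero structure", {
  x <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  t <- c(0, 1, 0, 1, 1)
  d <- build_interactions(x, t)
  expect_equal(ncol(d), 2 * 3 + 1)
  expect_equal(unname(d[t == 0, 5:7]), matrix(0, 2, 3))
  expect_equal(unname(d[t == 1, 5:7]), unname(x[t == 1, ]))
  expect_equal(d[, "t"], t)
  expect_error(build_interactions(x, c(0, 1, 2, 0, 1)), "binary")
})
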
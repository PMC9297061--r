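test_that("KS distance matches the exhaustive ECDF oracle", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:5, 1:5)$p, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11, 12))$D, 1)
  set.seed(10)
  a <- rnorm(7); b <- rnorm(5, 0.5)
  expect_equal(ks_two_sample(a, b)$D, ks_oracle_D(a, b), tolerance = 1e-12)
  # property: random small instances, with and without ties
  for (i in 1:200) {
    m <- sample(2:12, 1); n <- sample(2:12, 1)
    a <- sample(0:6, m, replace = TRUE) + if (i %% 2) 0 else runif(m)
    b <- sample(0:6, n, replace = TRUE) + if (i %% 2) 0 else runif(n)
    expect_equal(ks_two_sample(a, b)$D, ks_oracle_D(a, b), tolerance = 1e-12)
  }
})

test_that("KS p-values agree with the reference implementation", {
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(sample(10:60, 1)); b <- rnorm(sample(10:60, 1), runif(1, 0, 1))
    ours <- ks_two_sample(a, b)
    ref <- stats::ks.test(a, b, exact = FALSE)
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
    # the reference truncates its Kolmogorov series at tol = 1e-6 for
    # small arguments, so agreement is only expected to ~1e-4
    expect_equal(ours$p, ref$p.value, tolerance = 1e-4)
    exact <- ks_two_sample(a, b, exact = TRUE)
    expect_equal(exact$p, stats::ks.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
  expect_error(ks_two_sample(c(1, NA), 1:3), "NA")
})

test_that("the one-for-all rule picks the arm with lower mean outcome", {
  y <- c(30.1, 30.1, 28.4, 28.4); t <- c(1, 1, 0, 0)
  expect_equal(general_rule(y, t), "0")
  expect_equal(general_rule(y, 1 - t), "1")
  expect_warning(g <- general_rule(c(30, 30), c(0, 1)), "tie")
  expect_equal(g, "0")
  expect_error(general_rule(c(1, 2), c(0, 0)), "both treatment arms")
})

test_that("group decomposition follows the definitions and partitions", {
  g <- decompose_groups(c(1, 0, 1), c("1", "1", "0"), "0")
  expect_equal(g$O, 1L)
  expect_equal(g$NO, c(2L, 3L))
  expect_equal(g$G, 2L)
  expect_length(g$ties, 0)

  g2 <- decompose_groups(c(1, 0, 1), rep("tie", 3), "0")
  expect_length(g2$O, 0); expect_length(g2$NO, 0)
  expect_equal(g2$ties, 1:3)

  set.seed(20)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    t <- rbinom(n, 1, 0.5)
    dec <- sample(c("0", "1", "tie"), n, replace = TRUE)
    g <- decompose_groups(t, dec, sample(c("0", "1"), 1))
    idx <- sort(c(g$O, g$NO, g$ties))
    expect_equal(idx, seq_len(n))  # exact partition, every run
  }
  expect_error(decompose_groups(c(1, 0), c("0"), "0"), "lengths differ")
  expect_error(decompose_groups(c(1, 0), c("0", "x"), "0"), "decisions")
})

test_that("treated/untreated ratios and learner overlaps compute directly", {
  expect_equal(treatment_ratio(counts = c(1130, 414)), 2.729)
  expect_equal(treatment_ratio(counts = c(0, 5)), 0)
  expect_true(is.na(treatment_ratio(counts = c(5, 0))))
  expect_equal(treatment_ratio(c(1, 1, 0)), 2)

  expect_equal(learner_overlap(1:4, 1:4), 100)
  expect_equal(learner_overlap(1:4, 5:8), 0)
  expect_equal(learner_overlap(1:4, 2:3), 50)
  expect_true(is.na(learner_overlap(integer(0), 1:3)))
})
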
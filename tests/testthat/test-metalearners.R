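lmb <- base_learner("lm")

test_that("all learners recover a linear effect exactly on noiseless data", {
  d <- make_linear_dgp()  # heterogeneous tau = b2 + x b3
  for (kind in c("T", "S", "X")) {
    f <- metalearner(d$x, d$y, d$t, kind = kind, base = lmb)
    expect_equal(predict(f, d$x), d$tau, tolerance = 1e-10)
  }
  rt <- seq(1, nrow(d$x), by = 2)
  f <- metalearner(d$x, d$y, d$t, kind = "SXwint", base = lmb, retrain = rt)
  expect_equal(predict(f, d$x), d$tau, tolerance = 1e-10)

  # constant effect: the interaction-free SX joint model is well specified
  # too, so all five learners are exact
  dc <- make_linear_dgp(b3 = rep(0, 4), b2 = 1.5)
  for (kind in c("T", "S", "X")) {
    f <- metalearner(dc$x, dc$y, dc$t, kind = kind, base = lmb)
    expect_equal(predict(f, dc$x), dc$tau, tolerance = 1e-10)
  }
  for (kind in c("SX", "SXwint")) {
    f <- metalearner(dc$x, dc$y, dc$t, kind = kind, base = lmb, retrain = rt)
    expect_equal(predict(f, dc$x), dc$tau, tolerance = 1e-10)
  }
})

test_that("forcing the propensity to an endpoint collapses the blend exactly", {
  d <- make_linear_dgp(sigma = 0.5, seed = 7)
  rt <- sample(nrow(d$x), nrow(d$x) / 2)
  for (kind in c("X", "SX", "SXwint")) {
    args <- list(d$x, d$y, d$t, kind = kind, base = lmb)
    if (kind != "X") args$retrain <- rt
    f0 <- do.call(metalearner, c(args, propensity = 0))
    expect_identical(predict(f0, d$x), f0$models$tau1$predict(d$x))
    f1 <- do.call(metalearner, c(args, propensity = 1))
    expect_identical(predict(f1, d$x), f1$models$tau0$predict(d$x))
  }
})

test_that("SX and SXwint agree when g is zero and the true interaction vanishes", {
  dc <- make_linear_dgp(b3 = rep(0, 4), seed = 11)
  rt <- seq(2, nrow(dc$x), by = 2)
  f1 <- metalearner(dc$x, dc$y, dc$t, "SX", base = lmb, retrain = rt,
                    propensity = 0)
  f2 <- metalearner(dc$x, dc$y, dc$t, "SXwint", base = lmb, retrain = rt,
                    propensity = 0)
  expect_equal(predict(f1, dc$x), predict(f2, dc$x), tolerance = 1e-10)
})

test_that("S learner without interactions is rejected as non-personalized", {
  d <- make_linear_dgp()
  expect_error(metalearner(d$x, d$y, d$t, "S", interactions = FALSE),
               "not personalized")
  # the rejected path would indeed be non-personalized: a linear joint fit
  # on [x, t] has mu(x,1) - mu(x,0) constant in x
  joint <- lmb$fit(cbind(d$x, t = d$t), d$y)
  diff <- joint$predict(cbind(d$x, t = 1)) - joint$predict(cbind(d$x, t = 0))
  expect_lt(max(diff) - min(diff), 1e-10)
})

test_that("decisions follow the sign of tau and the argmin of predicted outcomes", {
  expect_equal(decide_optimal(c(0.3, -0.3, 0)), c("0", "1", "tie"))
  expect_equal(decide_optimal(c(2, 5)), c("0", "0"))
  expect_error(decide_optimal(c(1, NaN)), "non-finite")
  # invariance to positive rescaling
  tau <- c(1.2, -0.4, 0, 3)
  for (k in c(0.01, 1, 250)) {
    expect_equal(decide_optimal(k * tau), decide_optimal(tau))
  }
  # brute force: for T and S the decision minimizes the two predicted outcomes
  d <- make_linear_dgp(sigma = 1, seed = 21)
  for (kind in c("T", "S")) {
    f <- metalearner(d$x, d$y, d$t, kind = kind, base = lmb)
    m <- f$models
    mu0 <- if (kind == "T") m$mu0$predict(d$x) else
      m$joint$predict(build_interactions(d$x, rep(0, nrow(d$x))))
    mu1 <- if (kind == "T") m$mu1$predict(d$x) else
      m$joint$predict(build_interactions(d$x, rep(1, nrow(d$x))))
    argmin <- ifelse(mu1 > mu0, "0", ifelse(mu1 < mu0, "1", "tie"))
    expect_equal(predict(f, d$x, type = "decision"), argmin)
  }
})

test_that("predictions are deterministic, permutation-equivariant and refit-stable", {
  cfg <- synthetic_config(n = 300, tau = "linear", seed = 17)
  coh <- generate_cohort(cfg)
  enc <- encode_covariates(coh, treatment = "T")
  f <- metalearner(enc$x, coh$BMI, coh$T, kind = "X", seed = 5)
  xt <- enc$x[1:40, ]
  dup <- rbind(xt, xt)
  p <- predict(f, dup)
  expect_identical(p[1:40], p[41:80])
  perm <- sample(40)
  expect_identical(predict(f, xt[perm, ]), predict(f, xt)[perm])
  f2 <- metalearner(enc$x, coh$BMI, coh$T, kind = "X", seed = 5)
  expect_identical(predict(f2, xt), predict(f, xt))
})

test_that("propensity estimation is calibrated, clipped and guarded", {
  cfg <- synthetic_config(n = 2000, seed = 23)
  coh <- generate_cohort(cfg)
  enc <- encode_covariates(coh, treatment = "T")
  g <- estimate_propensity(enc$x, coh$T, seed = 3)
  ghat <- g$predict(enc$x)
  # fair-coin assignment: mean of P(T=0|x) near 0.5
  expect_lt(abs(mean(ghat) - 0.5), 3 * sqrt(0.25 / 2000))
  expect_true(all(ghat >= 0.01 & ghat <= 0.99))
  expect_error(estimate_propensity(enc$x, rep(0, nrow(enc$x))), "degenerate")
  # a separable problem drives raw probabilities to the clipping bounds
  xs <- matrix(seq(-3, 3, length.out = 60), ncol = 1, dimnames = list(NULL, "x"))
  gs <- estimate_propensity(xs, as.integer(xs[, 1] > 0),
                            base = base_learner("lm"))
  expect_equal(range(gs$predict(xs)), c(0.01, 0.99))
})

test_that("arm and split preconditions produce informative errors", {
  d <- make_linear_dgp(n = 40)
  expect_error(metalearner(d$x, d$y, rep(0L, 40), "T", base = lmb), "T = 1")
  expect_error(metalearner(d$x, d$y, d$t, "SX", base = lmb), "retrain")
  expect_error(metalearner(d$x, d$y, d$t, "SX", base = lmb,
                           retrain = 1:20, train = 15:40), "overlap")
  t_bad <- d$t; t_bad[1:20] <- 0L
  rt <- 1:20
  t_one_arm <- d$t; t_one_arm[rt] <- 0L
  expect_error(metalearner(d$x, d$y, t_one_arm, "SX", base = lmb, retrain = rt),
               "re-training")
  f <- metalearner(d$x, d$y, d$t, "T", base = lmb)
  bad <- d$x[, 1:2]
  expect_error(predict(f, bad), "missing model column")
})

test_that("fitted model surfaces print and summarize", {
  d <- make_linear_dgp(n = 60)
  f <- metalearner(d$x, d$y, d$t, "T", base = lmb)
  expect_output(print(f), "T metalearner")
  s <- summary(f)
  expect_output(print(s), "tau quantiles")
  expect_equal(sum(s$decisions), 60)
  expect_output(print(lmb), "lm")
})
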
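test_that("orthonormal designs reproduce the closed-form knots and statistic", {
  X <- orthonormal_design(60, 5, seed = 2)
  z <- c(3, 2, 1, 0.2, 0.1)
  y <- drop(X %*% z)  # x_j' y = z_j exactly
  pa <- lasso_path(X, y, standardize = FALSE)
  ent <- pa$event == "enter"
  expect_equal(pa$lambda[ent], sort(abs(z), decreasing = TRUE),
               tolerance = 1e-10)
  ct <- covariance_test(pa, sigma2 = 1)
  # T_k = lambda_k (lambda_k - lambda_{k+1}) / sigma^2 on orthonormal designs
  lam <- sort(abs(z), decreasing = TRUE)
  expect_equal(ct$statistic, lam * (lam - c(lam[-1], 0)), tolerance = 1e-10)
  expect_equal(ct$p_value[1], exp(-3), tolerance = 1e-10)
  # doubling sigma^2 halves every statistic
  ct2 <- covariance_test(pa, sigma2 = 2)
  expect_equal(ct2$statistic, ct$statistic / 2, tolerance = 1e-12)
})

test_that("degenerate paths behave: no signal, single predictor, collinearity", {
  X <- orthonormal_design(30, 4, seed = 3)
  pa <- lasso_path(X, rep(0, 30), standardize = FALSE)
  expect_length(pa$lambda, 0)
  expect_equal(nrow(covariance_test(pa, sigma2 = 1)), 0)

  set.seed(4)
  x1 <- matrix(rnorm(25), 25, 1, dimnames = list(NULL, "a"))
  y <- rnorm(25)
  p1 <- lasso_path(x1, y, standardize = FALSE)
  expect_equal(p1$lambda[p1$event == "enter"], abs(sum(x1 * y)),
               tolerance = 1e-10)

  xc <- cbind(a = rnorm(20), b = rnorm(20))
  xc <- cbind(xc, c = xc[, 1] + xc[, 2])
  expect_error(lasso_path(xc, rnorm(20)), "collinear")
})

test_that("the path agrees with glmnet coefficients at interior lambdas", {
  set.seed(9)
  n <- 80; p <- 6
  x <- scale(matrix(rnorm(n * p), n, p) %*% chol(0.6 * diag(p) + 0.4))
  colnames(x) <- paste0("v", 1:p)
  y <- drop(x %*% c(2, -1.5, 1, 0, 0, 0)) + rnorm(n)
  pa <- lasso_path(x, y, standardize = FALSE)
  for (lam in c(mean(pa$lambda[1:2]), mean(pa$lambda[2:3]),
                0.9 * pa$lambda[3])) {
    ours <- metacate:::beta_at(pa, lam)
    ref <- glmnet::glmnet(x, y - mean(y), lambda = lam / n,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-14)
    expect_equal(unname(ours), as.numeric(ref$beta), tolerance = 1e-6)
  }
})

test_that("p-values are Exp(1) tails and screening is monotone in alpha", {
  X <- orthonormal_design(50, 4, seed = 5)
  y <- drop(X %*% c(4, 2.5, 0.4, 0.1))
  ct <- covariance_test(lasso_path(X, y, standardize = FALSE), sigma2 = 1)
  expect_equal(ct$p_value, exp(-ct$statistic), tolerance = 1e-12)
  expect_true(all(ct$statistic >= 0))
  sets <- lapply(c(0.001, 0.01, 0.05, 0.5, 1), function(a)
    screen_features(ct, alpha = a))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
  expect_equal(screen_features(ct, alpha = 1), ct$variable)
  ct0 <- ct; ct0$p_value <- rep(1, nrow(ct0))
  expect_length(screen_features(ct0, alpha = 0.05), 0)
})

test_that("the published screen selects the six reported lifestyle features", {
  scr <- reference_counts()$screen
  fake <- data.frame(variable = scr$feature, entry = seq_len(nrow(scr)),
                     lambda = NA_real_, statistic = scr$statistic,
                     p_value = scr$p_value)
  class(fake) <- c("covtest_result", "data.frame")
  sig <- screen_features(fake, alpha = 0.05)
  expect_setequal(sig, c("FCVC", "FHWO", "FAVC", "SCC", "NCP", "FAF"))
})

test_that("one-hot blocks report the first entering column per feature", {
  coh <- generate_cohort(synthetic_config(n = 400, tau = "zero", seed = 44))
  fs <- feature_screen(strip_truths(coh))
  expect_false(any(duplicated(fs$table$feature)))
  expect_true(all(fs$table$p_value >= 0 & fs$table$p_value <= 1))
  # group mapping sends every design column to a source feature
  expect_true(all(fs$table$feature %in% names(coh)))
})

test_that("sigma^2 defaults to the full least-squares residual variance", {
  set.seed(6)
  n <- 60; p <- 3
  x <- scale(matrix(rnorm(n * p), n, p)); colnames(x) <- letters[1:3]
  y <- drop(x %*% c(1, 0.5, 0)) + rnorm(n)
  pa <- lasso_path(x, y)
  ct <- covariance_test(pa)
  fit <- lm(scale(y, scale = FALSE) ~ x - 1)
  s2 <- sum(resid(fit)^2) / (n - p - 1)
  expect_equal(attr(ct, "sigma2"), s2, tolerance = 1e-8)
  expect_error(covariance_test(pa, sigma2 = -1), "positive")
})
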
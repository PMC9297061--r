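# Shared fixtures and independent oracles.

# Small valid cohort records in the lifestyle schema.
make_cohort_df <- function(n = 6, seed = 1) {
  set.seed(seed)
  data.frame(
    Age = round(runif(n, 18, 50), 1),
    Gender = sample(c("Female", "Male"), n, replace = TRUE),
    Height = round(runif(n, 1.5, 1.95), 2),
    Weight = round(runif(n, 50, 140), 1),
    FHWO = sample(c("Yes", "No"), n, replace = TRUE),
    FAVC = sample(c("Yes", "No"), n, replace = TRUE),
    FCVC = round(runif(n, 1, 3), 2),
    NCP = round(runif(n, 1, 4), 2),
    CAEC = sample(c("No", "Sometimes", "Frequently", "Always"), n, TRUE),
    SMOKE = sample(c("Yes", "No"), n, replace = TRUE),
    CH2O = round(runif(n, 1, 3), 2),
    SCC = sample(c("Yes", "No"), n, replace = TRUE),
    FAF = round(runif(n, 0, 3), 2),
    TUE = round(runif(n, 0, 2), 2),
    CALC = sample(c("No", "Sometimes", "Frequently"), n, replace = TRUE),
    MTRANS = sample(c("Public_Transportation", "Automobile", "Walking"), n, TRUE),
    stringsAsFactors = FALSE
  )
}

# Noiseless linear potential-outcome data: Y = x b1 + t * (b2 + x b3).
make_linear_dgp <- function(n = 400, p = 4, b1 = c(1, -2, 0.5, 1),
                            b2 = 1.5, b3 = c(2, 0, -1, 0), seed = 42,
                            sigma = 0) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("z", 1:p)))
  t <- rbinom(n, 1, 0.5)
  tau <- b2 + drop(x %*% b3)
  y <- drop(x %*% b1) + t * tau + rnorm(n, 0, sigma)
  list(x = x, y = y, t = t, tau = tau)
}

# Exhaustive ECDF-scan oracle for the two-sample KS distance: evaluate the
# gap at every merged sample point by direct counting.
ks_oracle_D <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(v) {
    abs(mean(a <= v) - mean(b <= v))
  }, numeric(1)))
}

# Random orthonormal design (columns of a QR Q factor).
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  colnames(q) <- paste0("q", seq_len(p))
  q
}
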
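# Synthetic cohorts with known potential outcomes.
#
# The generator emulates the statistical structure the metalearners assume:
# mixed continuous/categorical lifestyle covariates, a binary treatment with
# (optionally covariate-dependent) assignment satisfying overlap, and a
# continuous BMI-like outcome Y = T*Y(1) + (1-T)*Y(0) whose treatment effect
# tau(x) is known exactly. Latent truths travel in `.truth_*` columns that
# the encoders never expose to a learner.

# Obesity-like default covariate schema: continuous features uniform over
# their recorded ranges (Age truncated normal), categorical frequencies
# matching the published overweight/obese subset. Documented constants, not
# claims about the real data-generating process.
default_schema <- function() {
  list(
    Age    = list(type = "normal", mean = 25.6, sd = 6.5, range = c(15, 56)),
    FCVC   = list(type = "uniform", range = c(1, 3)),
    NCP    = list(type = "uniform", range = c(1, 4)),
    CH2O   = list(type = "uniform", range = c(1, 3)),
    FAF    = list(type = "uniform", range = c(0, 3)),
    TUE    = list(type = "uniform", range = c(0, 2)),
    Gender = list(type = "categorical",
                  levels = c("Female", "Male"), probs = c(0.466, 0.534)),
    FHWO   = list(type = "categorical",
                  levels = c("No", "Yes"), probs = c(0.066, 0.934)),
    FAVC   = list(type = "categorical",
                  levels = c("No", "Yes"), probs = c(0.074, 0.926)),
    SCC    = list(type = "categorical",
                  levels = c("No", "Yes"), probs = c(0.975, 0.025)),
    SMOKE  = list(type = "categorical",
                  levels = c("No", "Yes"), probs = c(0.981, 0.019)),
    CAEC   = list(type = "categorical",
                  levels = c("Always", "Frequently", "No", "Sometimes"),
                  probs = c(0.011, 0.025, 0.025, 0.939)),
    MTRANS = list(type = "categorical",
                  levels = c("Automobile", "Bike", "Motorbike",
                             "Public_Transportation", "Walking"),
                  probs = c(0.236, 0.002, 0.003, 0.747, 0.012))
  )
}

# Theoretical standardization of a continuous schema entry, so tau/baseline
# coefficients act on comparable scales.
.schema_moments <- function(def) {
  if (def$type == "uniform") {
    c(mean = mean(def$range), sd = diff(def$range) / sqrt(12))
  } else {
    c(mean = def$mean, sd = def$sd)
  }
}

#' Configure a synthetic cohort
#'
#' @param n Sample size (>= 4).
#' @param tau Form of the treatment effect \eqn{\tau(x) = E[Y(1)-Y(0)|x]}:
#'   \code{"zero"}, \code{"constant"} (value \code{tau_value}),
#'   \code{"linear"} (\code{tau_value + sum(tau_coef * z)} on standardized
#'   continuous covariates) or \code{"nonlinear"}
#'   (\code{tau_value * tanh(z_FCVC + z_FAF)}, a smooth sign-switching form).
#' @param tau_value Scalar effect level; default 2 for \code{"constant"},
#'   0 for \code{"linear"} (so both signs occur), 3 for \code{"nonlinear"}.
#' @param tau_coef Named coefficients on standardized continuous covariates
#'   for the linear form; default \code{c(FCVC = 2, FAF = 1.5, Age = 1)}.
#' @param noise_sd Residual standard deviation sigma >= 0; errors are
#'   mean-zero given x.
#' @param assignment Treatment assignment: \code{list(type = "constant",
#'   p = 0.5)} or \code{list(type = "logistic", intercept = 0, coef = c(...))}
#'   with coefficients on standardized continuous covariates, giving
#'   \eqn{P(T=1|x)}. Overlap (probabilities strictly inside (0, 1)) is
#'   enforced.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   full configuration.
#' @param schema Covariate schema; defaults to the obesity-like schema.
#' @return Object of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n = 1000,
                             tau = c("linear", "zero", "constant", "nonlinear"),
                             tau_value = NULL,
                             tau_coef = c(FCVC = 2, FAF = 1.5, Age = 1),
                             noise_sd = 1,
                             assignment = list(type = "constant", p = 0.5),
                             seed = 1,
                             schema = default_schema()) {
  tau <- match.arg(tau)
  if (n < 4) stop("synthetic cohorts need n >= 4", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  tau_value <- tau_value %||% switch(tau, zero = 0, constant = 2,
                                     linear = 0, nonlinear = 3)
  if (identical(assignment$type, "constant") &&
      (assignment$p <= 0 || assignment$p >= 1)) {
    stop("assignment violates overlap: p must lie strictly in (0, 1)",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), tau = tau, tau_value = tau_value,
                 tau_coef = tau_coef, noise_sd = noise_sd,
                 assignment = assignment, seed = as.integer(seed),
                 schema = schema),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  n =", x$n, "| tau form:", x$tau, "(level", x$tau_value, ")",
      "| sigma =", x$noise_sd, "\n")
  cat("  assignment:", x$assignment$type, "| seed:", x$seed, "\n")
  invisible(x)
}

# Standardized continuous covariates under the schema's theoretical moments.
.standardized <- function(data, schema) {
  cont <- names(schema)[vapply(schema, function(d) d$type != "categorical",
                               logical(1))]
  z <- lapply(cont, function(nm) {
    m <- .schema_moments(schema[[nm]])
    (data[[nm]] - m["mean"]) / m["sd"]
  })
  names(z) <- cont
  z
}

# Baseline outcome surface mu0(x): BMI-like level around 29 with fixed
# lifestyle effects. Documented constants (see the methods vignette).
.baseline_mu0 <- function(data, z) {
  29 + 1.0 * z$Age - 1.5 * z$FCVC + 0.7 * z$NCP - 1.0 * z$FAF +
    0.5 * z$TUE +
    1.5 * (data$FHWO == "Yes") + 1.0 * (data$FAVC == "Yes") -
    0.8 * (data$SCC == "Yes") + 0.5 * (data$Gender == "Male")
}

.true_tau <- function(config, data, z) {
  switch(config$tau,
    zero = rep(0, nrow(data)),
    constant = rep(config$tau_value, nrow(data)),
    linear = {
      v <- rep(config$tau_value, nrow(data))
      for (nm in names(config$tau_coef)) {
        if (!nm %in% names(z)) {
          stop("tau_coef names a non-continuous covariate: ", nm, call. = FALSE)
        }
        v <- v + config$tau_coef[[nm]] * z[[nm]]
      }
      v
    },
    nonlinear = config$tau_value * tanh(z$FCVC + z$FAF)
  )
}

.propensity1 <- function(config, z, n) {
  a <- config$assignment
  p1 <- if (identical(a$type, "constant")) {
    rep(a$p, n)
  } else if (identical(a$type, "logistic")) {
    eta <- rep(a$intercept %||% 0, n)
    for (nm in names(a$coef)) {
      if (!nm %in% names(z)) {
        stop("assignment coef names a non-continuous covariate: ", nm,
             call. = FALSE)
      }
      eta <- eta + a$coef[[nm]] * z[[nm]]
    }
    stats::plogis(eta)
  } else {
    stop("unknown assignment type: ", a$type, call. = FALSE)
  }
  if (any(p1 <= 0) || any(p1 >= 1)) {
    stop("assignment violates overlap: P(T=1|x) must lie strictly in (0, 1)",
         call. = FALSE)
  }
  p1
}

#' Generate a synthetic cohort with latent potential outcomes
#'
#' Draws covariates from the configured schema, assigns treatment from the
#' configured propensity, and builds the observed outcome
#' \eqn{Y = T Y(1) + (1-T) Y(0)} with \eqn{Y(1) = Y(0) + \tau(x)} and a
#' shared mean-zero noise draw (so \code{noise_sd = 0} makes Y an exact
#' function of (x, T)). The outcome column is named \code{BMI} and latent
#' truths are stored in \code{.truth_y0}, \code{.truth_y1},
#' \code{.truth_tau} and \code{.truth_p1} columns, which the covariate
#' encoder strips before any learner sees the data.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with covariates, \code{T}, \code{BMI} and
#'   \code{.truth_*} columns; byte-identical across calls with the same
#'   configuration.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n
  with_seed(config$seed, {
    data <- as.data.frame(lapply(config$schema, function(def) {
      if (def$type == "categorical") {
        sample(def$levels, n, replace = TRUE, prob = def$probs)
      } else if (def$type == "uniform") {
        stats::runif(n, def$range[1], def$range[2])
      } else {
        v <- stats::rnorm(n, def$mean, def$sd)
        pmin(pmax(v, def$range[1]), def$range[2])
      }
    }), stringsAsFactors = FALSE)
    z <- .standardized(data, config$schema)
    mu0 <- .baseline_mu0(data, z)
    tau <- .true_tau(config, data, z)
    p1 <- .propensity1(config, z, n)
    eps <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
    y0 <- mu0 + eps
    y1 <- y0 + tau
    t <- stats::rbinom(n, 1L, p1)
    data$T <- t
    data$BMI <- ifelse(t == 1L, y1, y0)
    data$.truth_y0 <- y0
    data$.truth_y1 <- y1
    data$.truth_tau <- tau
    data$.truth_p1 <- p1
    data
  })
}

#' True optimal decision from the latent treatment effect
#'
#' Lower outcome is preferred, so \eqn{\tau(x) > 0} makes T = 0 optimal,
#' \eqn{\tau(x) < 0} makes T = 1 optimal, and \eqn{\tau(x) = 0} is a tie.
#'
#' @param x A synthetic cohort (with \code{.truth_tau}) or a numeric vector
#'   of true effects.
#' @return Character vector in \code{c("0", "1", "tie")}.
#' @export
true_optimal <- function(x) {
  tau <- if (is.data.frame(x)) {
    if (!".truth_tau" %in% names(x)) {
      stop("data frame has no `.truth_tau` column", call. = FALSE)
    }
    x$.truth_tau
  } else {
    as.numeric(x)
  }
  decide_optimal(tau)
}

#' Drop latent truth columns from a synthetic cohort
#'
#' @param cohort Data frame possibly holding \code{.truth_*} columns.
#' @return The data frame with every \code{.truth_*} column removed.
#' @export
strip_truths <- function(cohort) {
  cohort[, !grepl("^\\.truth_", names(cohort)), drop = FALSE]
}
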
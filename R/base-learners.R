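#' Base learner specification for the metalearners
#'
#' A metalearner is agnostic to the supervised procedure it stacks; it only
#' needs a regressor (fit/predict) and a probability classifier
#' (fit/predict_prob). Two engines are provided:
#' \describe{
#'   \item{\code{"ranger"}}{Random forests (the default), configured as in
#'     the BMI prediction study: 100 trees and a minimum of 7 observations
#'     for a node to be split. Forests run single-threaded with a
#'     deterministic seed derived from the pipeline seed.}
#'   \item{\code{"lm"}}{Ordinary least squares / logistic regression.
#'     Deterministic; used for the exact algebraic properties of the
#'     learners in the noiseless linear limit.}
#' }
#'
#' @param engine \code{"ranger"} or \code{"lm"}.
#' @param num.trees,min.node.size Forest hyperparameters (ranger only).
#' @param ... Further arguments passed to [ranger::ranger()].
#' @return Object of class \code{"base_learner"} with \code{$fit(x, y, seed)}
#'   and \code{$fit_classifier(x, t, seed)} factories; fitted objects carry a
#'   \code{$predict(x)} (regressor) or \code{$predict_prob0(x)} (classifier,
#'   returning P(T = 0 | x)).
#' @export
base_learner <- function(engine = c("ranger", "lm"),
                         num.trees = 100, min.node.size = 7, ...) {
  engine <- match.arg(engine)
  extra <- list(...)
  if (engine == "ranger") {
    fit <- function(x, y, seed = 1) {
      args <- c(list(x = as.data.frame(x), y = y, num.trees = num.trees,
                     min.node.size = min.node.size, num.threads = 1L,
                     seed = as.integer(seed) %% .Machine$integer.max), extra)
      m <- do.call(ranger::ranger, args)
      list(predict = function(newx) {
        stats::predict(m, data = as.data.frame(newx),
                       num.threads = 1L)$predictions
      }, model = m)
    }
    fit_classifier <- function(x, t, seed = 1) {
      if (length(unique(t)) < 2L) {
        stop("degenerate treatment labels: both arms are required to ",
             "estimate the propensity score", call. = FALSE)
      }
      args <- c(list(x = as.data.frame(x), y = factor(t, levels = c(0, 1)),
                     num.trees = num.trees, min.node.size = min.node.size,
                     probability = TRUE, num.threads = 1L,
                     seed = as.integer(seed) %% .Machine$integer.max), extra)
      m <- do.call(ranger::ranger, args)
      list(predict_prob0 = function(newx) {
        stats::predict(m, data = as.data.frame(newx),
                       num.threads = 1L)$predictions[, "0"]
      }, model = m)
    }
  } else {
    fit <- function(x, y, seed = 1) {
      xm <- cbind(`(Intercept)` = 1, as.matrix(x))
      cf <- stats::lm.fit(xm, y)$coefficients
      cf[is.na(cf)] <- 0
      list(predict = function(newx) {
        drop(cbind(1, as.matrix(newx)) %*% cf)
      }, coefficients = cf)
    }
    fit_classifier <- function(x, t, seed = 1) {
      if (length(unique(t)) < 2L) {
        stop("degenerate treatment labels: both arms are required to ",
             "estimate the propensity score", call. = FALSE)
      }
      xm <- cbind(`(Intercept)` = 1, as.matrix(x))
      cf <- suppressWarnings(
        stats::glm.fit(xm, t, family = stats::binomial())$coefficients)
      cf[is.na(cf)] <- 0
      list(predict_prob0 = function(newx) {
        1 - stats::plogis(drop(cbind(1, as.matrix(newx)) %*% cf))
      }, coefficients = cf)
    }
  }
  structure(list(engine = engine,
                 params = c(if (engine == "ranger")
                   list(num.trees = num.trees, min.node.size = min.node.size),
                   extra),
                 fit = fit, fit_classifier = fit_classifier),
            class = "base_learner")
}

#' @export
print.base_learner <- function(x, ...) {
  cat("Base learner:", x$engine)
  if (length(x$params)) {
    cat(" (", paste(names(x$params), unlist(x$params), sep = " = ",
                    collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Estimate the propensity score g(x) = P(T = 0 | x)
#'
#' Note the control-probability convention: \code{g(x)} is the probability
#' of \emph{not} being treated, and the learners combine the two imputed
#' effect models as \eqn{\hat\tau = \hat g \hat\tau_0 + (1-\hat g)\hat\tau_1}.
#' Estimated probabilities are clipped to \code{[clip, 1 - clip]} to keep
#' the convex combination away from degenerate weights.
#'
#' @param x Covariate matrix.
#' @param t Binary 0/1 treatment vector; both arms must be present.
#' @param base A [base_learner()] providing the probability classifier.
#' @param clip Clipping bound, default 0.01.
#' @param seed Seed for stochastic classifiers.
#' @return Object with \code{$predict(newx)} returning clipped
#'   \eqn{\hat g(newx)}.
#' @export
estimate_propensity <- function(x, t, base = base_learner(), clip = 0.01,
                                seed = 1) {
  stopifnot(inherits(base, "base_learner"))
  m <- base$fit_classifier(x, t, seed = seed)
  structure(list(
    predict = function(newx) {
      pmin(pmax(m$predict_prob0(newx), clip), 1 - clip)
    },
    clip = clip, model = m
  ), class = "propensity_model")
}
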
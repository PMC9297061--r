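#' Fit a metalearner for the conditional average treatment effect
#'
#' Estimates \eqn{\tau(x) = E[Y(1) - Y(0) | X = x]} for a binary treatment
#' by stacking base learners according to one of five metaalgorithms, and
#' turns \eqn{\hat\tau} into personalized optimal decisions (lower outcome
#' preferred, so \eqn{\hat\tau(x) > 0} recommends T = 0):
#' \describe{
#'   \item{T}{two outcome models: \eqn{\hat\mu_0} on the control arm,
#'     \eqn{\hat\mu_1} on the treated arm;
#'     \eqn{\hat\tau = \hat\mu_1 - \hat\mu_0}.}
#'   \item{S}{one joint model \eqn{\hat\mu(x, t)} on \code{[x, t, x*t]};
#'     the first-order treatment-covariate interactions are mandatory —
#'     without them a linear joint model forces a constant effect and the
#'     decision rule cannot be personalized.}
#'   \item{X}{outcome models as in T, then imputed individual effects
#'     \eqn{D^0 = \hat\mu_1(x) - Y(0)} (controls) and
#'     \eqn{D^1 = Y(1) - \hat\mu_0(x)} (treated), effect models
#'     \eqn{\hat\tau_0, \hat\tau_1} on those, and the propensity-weighted
#'     blend \eqn{\hat\tau = \hat g\hat\tau_0 + (1 - \hat g)\hat\tau_1}
#'     with \eqn{g(x) = P(T = 0 | x)}.}
#'   \item{SX}{hybrid of S and X: a joint model \emph{without} interactions
#'     fit on the training split imputes \eqn{D^0, D^1} on a disjoint
#'     re-training split, where \eqn{\hat\tau_0, \hat\tau_1} are fit; the
#'     propensity model uses the union of the two splits; combination as
#'     in X.}
#'   \item{SXwint}{SX with the joint model fit on \code{[x, t, x*t]}
#'     (interaction columns supplied explicitly, whatever the base
#'     learner).}
#' }
#'
#' @param x Numeric covariate design matrix (see [encode_covariates()]).
#' @param y Numeric outcome vector (BMI; lower is better).
#' @param t Binary 0/1 observed treatment vector.
#' @param kind One of \code{"T"}, \code{"S"}, \code{"X"}, \code{"SX"},
#'   \code{"SXwint"}.
#' @param base A [base_learner()]; random forest by default.
#' @param retrain For SX/SXwint: integer indices (rows of \code{x}) forming
#'   the re-training split. The training split is its complement unless
#'   \code{train} is given.
#' @param train Optional explicit training indices for SX/SXwint; must be
#'   disjoint from \code{retrain}.
#' @param interactions Logical; only consulted by the S learner, where
#'   \code{FALSE} is an error (see above). SX always fits without and
#'   SXwint always with interactions.
#' @param propensity Override for \eqn{\hat g(x) = P(T = 0 | x)}: \code{NULL}
#'   (estimate with the base classifier, clipped), a constant in [0, 1]
#'   (used exactly as given, e.g. to force \eqn{\hat g \equiv 0}), or a
#'   function of the covariate matrix.
#' @param clip Clipping bound for estimated propensities, default 0.01.
#' @param seed Integer pipeline seed; each stochastic component receives a
#'   deterministic child seed derived from it and a stage label.
#' @return Object of class \code{"metalearner"} with [predict.metalearner()],
#'   [print.metalearner()] and [summary.metalearner()] methods.
#' @examples
#' cfg <- synthetic_config(n = 300, tau = "linear", seed = 7)
#' cohort <- generate_cohort(cfg)
#' enc <- encode_covariates(cohort, treatment = "T")
#' fit <- metalearner(enc$x, cohort$BMI, cohort$T, kind = "T",
#'                    base = base_learner("lm"))
#' table(predict(fit, enc$x, type = "decision"))
#' @export
metalearner <- function(x, y, t,
                        kind = c("T", "S", "X", "SX", "SXwint"),
                        base = base_learner(),
                        retrain = NULL, train = NULL,
                        interactions = NULL,
                        propensity = NULL, clip = 0.01, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(base, "base_learner"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  if (length(y) != n || length(t) != n) {
    stop("`x`, `y` and `t` must describe the same records", call. = FALSE)
  }
  if (!all(t %in% c(0, 1))) stop("`t` must be binary 0/1", call. = FALSE)
  t <- as.integer(t)

  if (kind %in% c("SX", "SXwint")) {
    if (is.null(retrain)) {
      stop(kind, " learner needs a `retrain` split disjoint from training",
           call. = FALSE)
    }
    retrain <- as.integer(retrain)
    train <- if (is.null(train)) setdiff(seq_len(n), retrain)
             else as.integer(train)
    if (length(intersect(train, retrain))) {
      stop("training and re-training indices overlap", call. = FALSE)
    }
  } else {
    train <- seq_len(n)
  }

  check_arms <- function(tt, where) {
    for (arm in c(0L, 1L)) {
      if (!any(tt == arm)) {
        stop("no records with T = ", arm, " in the ", where,
             " data; the ", kind, " learner needs both arms", call. = FALSE)
      }
    }
  }

  models <- list()
  fitted_tau <- NULL

  g_model <- function(xg, tg, label) {
    if (is.null(propensity)) {
      estimate_propensity(xg, tg, base = base, clip = clip,
                          seed = stage_seed(seed, label))
    } else if (is.numeric(propensity) && length(propensity) == 1L) {
      if (propensity < 0 || propensity > 1) {
        stop("constant `propensity` must lie in [0, 1]", call. = FALSE)
      }
      structure(list(predict = function(newx) rep(propensity, nrow(newx))),
                class = "propensity_model")
    } else if (is.function(propensity)) {
      structure(list(predict = propensity), class = "propensity_model")
    } else {
      stop("`propensity` must be NULL, a scalar or a function", call. = FALSE)
    }
  }

  if (kind == "T") {
    check_arms(t, "training")
    models$mu0 <- base$fit(x[t == 0L, , drop = FALSE], y[t == 0L],
                           seed = stage_seed(seed, "mu0"))
    models$mu1 <- base$fit(x[t == 1L, , drop = FALSE], y[t == 1L],
                           seed = stage_seed(seed, "mu1"))
  } else if (kind == "S") {
    interactions <- interactions %||% TRUE
    if (!isTRUE(interactions)) {
      stop("the S learner requires treatment-covariate interactions: ",
           "without them the estimated effect is constant in x and the ",
           "decision rule is not personalized", call. = FALSE)
    }
    check_arms(t, "training")
    models$joint <- base$fit(build_interactions(x, t), y,
                             seed = stage_seed(seed, "joint"))
  } else if (kind == "X") {
    check_arms(t, "training")
    i0 <- which(t == 0L); i1 <- which(t == 1L)
    models$mu0 <- base$fit(x[i0, , drop = FALSE], y[i0],
                           seed = stage_seed(seed, "mu0"))
    models$mu1 <- base$fit(x[i1, , drop = FALSE], y[i1],
                           seed = stage_seed(seed, "mu1"))
    d0 <- models$mu1$predict(x[i0, , drop = FALSE]) - y[i0]
    d1 <- y[i1] - models$mu0$predict(x[i1, , drop = FALSE])
    models$tau0 <- base$fit(x[i0, , drop = FALSE], d0,
                            seed = stage_seed(seed, "tau0"))
    models$tau1 <- base$fit(x[i1, , drop = FALSE], d1,
                            seed = stage_seed(seed, "tau1"))
    models$g <- g_model(x, t, "propensity")
    models$imputed <- list(D0 = d0, D1 = d1)
  } else {  # SX / SXwint
    with_int <- kind == "SXwint"
    tr <- train; rt <- retrain
    check_arms(t[rt], "re-training")
    joint_design <- function(xx, tt) {
      if (with_int) build_interactions(xx, tt) else cbind(xx, t = tt)
    }
    models$joint <- base$fit(joint_design(x[tr, , drop = FALSE], t[tr]),
                             y[tr], seed = stage_seed(seed, "joint"))
    r0 <- rt[t[rt] == 0L]; r1 <- rt[t[rt] == 1L]
    mu_at <- function(idx, tt) {
      xx <- x[idx, , drop = FALSE]
      models$joint$predict(joint_design(xx, rep(tt, length(idx))))
    }
    d0 <- mu_at(r0, 1L) - y[r0]
    d1 <- y[r1] - mu_at(r1, 0L)
    models$tau0 <- base$fit(x[r0, , drop = FALSE], d0,
                            seed = stage_seed(seed, "tau0"))
    models$tau1 <- base$fit(x[r1, , drop = FALSE], d1,
                            seed = stage_seed(seed, "tau1"))
    un <- c(tr, rt)
    models$g <- g_model(x[un, , drop = FALSE], t[un], "propensity")
    models$imputed <- list(D0 = d0, D1 = d1)
  }

  obj <- structure(list(
    kind = kind, base = base, models = models,
    interactions = if (kind == "S") TRUE else kind == "SXwint",
    clip = clip, seed = seed,
    feature_names = colnames(x),
    n = n, n_arm = c(`0` = sum(t == 0L), `1` = sum(t == 1L)),
    train = train, retrain = if (kind %in% c("SX", "SXwint")) retrain,
    call = match.call()
  ), class = "metalearner")
  obj$fitted_tau <- predict(obj, x)
  obj
}

#' Predict treatment effects or decisions from a fitted metalearner
#'
#' @param object A fitted [metalearner()].
#' @param newdata Covariate matrix encoded with the same layout as the
#'   training design (same columns, same order).
#' @param type \code{"cate"} returns \eqn{\hat\tau(x)}; \code{"decision"}
#'   returns the personalized optimal decision via [decide_optimal()].
#' @param ... Unused.
#' @return Numeric vector of effects or character decision vector.
#' @export
predict.metalearner <- function(object, newdata, type = c("cate", "decision"),
                                ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$feature_names)) {
      stop("`newdata` has ", ncol(newdata), " columns; the model expects ",
           length(object$feature_names), call. = FALSE)
    }
    colnames(newdata) <- object$feature_names
  } else {
    miss <- setdiff(object$feature_names, colnames(newdata))
    if (length(miss)) {
      stop("`newdata` is missing model column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  m <- object$models
  tau <- switch(object$kind,
    T = m$mu1$predict(newdata) - m$mu0$predict(newdata),
    S = {
      n <- nrow(newdata)
      m$joint$predict(build_interactions(newdata, rep(1, n))) -
        m$joint$predict(build_interactions(newdata, rep(0, n)))
    },
    {
      g <- m$g$predict(newdata)
      g * m$tau0$predict(newdata) + (1 - g) * m$tau1$predict(newdata)
    })
  if (type == "cate") tau else decide_optimal(tau)
}

#' Convert estimated treatment effects into optimal decisions
#'
#' Lower outcome is preferred: \eqn{\hat\tau(x) > 0} means the outcome under
#' T = 1 is higher, so T = 0 is the personalized optimal decision;
#' \eqn{\hat\tau(x) < 0} recommends T = 1; an exact zero is an explicit tie
#' (both options equally favorable) rather than an arbitrary assignment.
#'
#' @param tau Numeric vector of estimated effects; must be finite.
#' @return Character vector in \code{c("0", "1", "tie")}.
#' @examples
#' decide_optimal(c(0.3, -0.3, 0))
#' @export
decide_optimal <- function(tau) {
  if (any(!is.finite(tau))) {
    stop("estimated treatment effects contain non-finite values", call. = FALSE)
  }
  ifelse(tau > 0, "0", ifelse(tau < 0, "1", "tie"))
}

#' @export
print.metalearner <- function(x, ...) {
  cat(x$kind, "metalearner (base:", x$base$engine, ")\n")
  cat("  records:", x$n, " | arms: T=0:", x$n_arm[["0"]],
      " T=1:", x$n_arm[["1"]], "\n")
  if (!is.null(x$retrain)) {
    cat("  splits: train", length(x$train), "/ retrain", length(x$retrain), "\n")
  }
  dec <- decide_optimal(x$fitted_tau)
  cat("  fitted decisions: T=0:", sum(dec == "0"), " T=1:", sum(dec == "1"),
      " ties:", sum(dec == "tie"), "\n")
  invisible(x)
}

#' @export
summary.metalearner <- function(object, ...) {
  dec <- decide_optimal(object$fitted_tau)
  out <- list(kind = object$kind, base = object$base$engine,
              n = object$n, n_arm = object$n_arm,
              tau_quantiles = stats::quantile(object$fitted_tau,
                                              c(0, .25, .5, .75, 1)),
              decisions = c(`T=0` = sum(dec == "0"), `T=1` = sum(dec == "1"),
                            tie = sum(dec == "tie")))
  class(out) <- "summary.metalearner"
  out
}

#' @export
print.summary.metalearner <- function(x, ...) {
  cat(x$kind, "metalearner (base:", x$base, "), n =", x$n, "\n")
  cat("  arm sizes: T=0:", x$n_arm[["0"]], " T=1:", x$n_arm[["1"]], "\n")
  cat("  fitted tau quantiles:\n")
  print(round(x$tau_quantiles, 4))
  cat("  personalized optimal decisions:\n")
  print(x$decisions)
  invisible(x)
}
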
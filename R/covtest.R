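# Lasso solution path (LARS with the lasso modification) and the
# covariance test for variables entering the path.
#
# The path is computed exactly: knots are the penalty values at which a
# variable enters or leaves the active set, and coefficients are piecewise
# linear in lambda between knots. Lambda lives on the inner-product scale
# |x_j' r| of the (standardized) design. The covariance test compares, at
# the next knot, the fitted inner product <y, X beta> of the full lasso
# with that of the lasso restricted to the active set just before the
# variable entered; under the null the statistic is asymptotically Exp(1).

#' Exact lasso solution path
#'
#' Computes the piecewise-linear lasso coefficient path by least-angle
#' regression with the lasso modification (variables drop out when a
#' coefficient crosses zero). Intended for the low-dimensional regime
#' n > p used by the feature screen.
#'
#' @param x Numeric design matrix, n x p; must be full column rank.
#' @param y Numeric outcome vector.
#' @param standardize If \code{TRUE} (default), columns of \code{x} are
#'   centered and scaled to unit standard deviation and \code{y} is
#'   centered before the path is computed; knots are reported on that
#'   standardized inner-product scale. Use \code{FALSE} when \code{x} is
#'   already prepared (e.g. orthonormal designs).
#' @param max_steps Safety cap on path events.
#' @return Object of class \code{"lasso_path"}: \code{lambda} (event knots,
#'   decreasing, ending at 0 when the path is complete), \code{beta}
#'   (coefficients at each knot, events x p), \code{event}
#'   (\code{"enter"}/\code{"drop"}/\code{"end"}), \code{var} (column name per
#'   event), plus the prepared design and outcome.
#' @export
lasso_path <- function(x, y, standardize = TRUE, max_steps = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("`y` length must match rows of `x`", call. = FALSE)
  qrx <- qr(x)
  if (qrx$rank < p) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (standardize) {
    x <- scale(x)
    y <- y - mean(y)
  }
  max_steps <- max_steps %||% (50L + 10L * p)

  tol <- 1e-10
  beta <- numeric(p)
  active <- integer(0)
  r <- as.numeric(y)
  cvec <- drop(crossprod(x, r))
  lam <- max(abs(cvec))
  lam_scale <- max(lam, 1)

  lambdas <- numeric(0); betas <- NULL; events <- character(0); vars <- integer(0)
  push <- function(l, ev, v) {
    lambdas <<- c(lambdas, l); events <<- c(events, ev); vars <<- c(vars, v)
    betas <<- rbind(betas, beta)
  }

  if (lam <= tol * max(1, sqrt(sum(y^2)))) {
    # y (after centering) carries no signal: empty path
    out <- list(lambda = numeric(0), beta = matrix(0, 0, p,
                  dimnames = list(NULL, colnames(x))),
                event = character(0), var = character(0),
                x = x, y = as.numeric(y), n = n, p = p,
                standardize = standardize)
    class(out) <- "lasso_path"
    return(out)
  }

  # first variable enters at lambda_1 = max |x_j' y|
  j1 <- which.max(abs(cvec))
  active <- j1
  push(lam, "enter", j1)

  steps <- 1L
  while (lam > tol * lam_scale && steps < max_steps) {
    sA <- sign(cvec[active])
    xa <- x[, active, drop = FALSE]
    w <- solve(crossprod(xa), sA)           # direction in beta-space
    u <- drop(xa %*% w)                     # |x_j' u| = 1 for j active
    a <- drop(crossprod(x, u))

    inactive <- setdiff(seq_len(p), active)
    gam_enter <- Inf; j_enter <- NA_integer_
    for (j in inactive) {
      for (g in c((lam - cvec[j]) / (1 - a[j]), (lam + cvec[j]) / (1 + a[j]))) {
        if (is.finite(g) && g > tol * lam_scale && g < gam_enter) {
          gam_enter <- g; j_enter <- j
        }
      }
    }
    gam_drop <- Inf; j_drop <- NA_integer_
    gd <- -beta[active] / w
    ok <- is.finite(gd) & gd > tol * lam_scale
    if (any(ok)) {
      k <- which(ok)[which.min(gd[ok])]
      gam_drop <- gd[k]; j_drop <- active[k]
    }

    ev <- if (lam <= min(gam_enter, gam_drop)) "end"
          else if (gam_drop <= gam_enter) "drop" else "enter"
    gam <- switch(ev, end = lam, drop = gam_drop, enter = gam_enter)
    beta[active] <- beta[active] + gam * w
    r <- r - gam * u
    cvec <- drop(crossprod(x, r))
    lam <- lam - gam
    steps <- steps + 1L

    if (ev == "drop") {
      beta[j_drop] <- 0
      active <- setdiff(active, j_drop)
      push(lam, "drop", j_drop)
      if (!length(active)) break
    } else if (ev == "enter") {
      active <- c(active, j_enter)
      push(lam, "enter", j_enter)
    } else {
      lam <- 0
      push(0, "end", NA_integer_)
      break
    }
  }

  colnames(betas) <- colnames(x)
  out <- list(lambda = lambdas, beta = betas, event = events,
              var = ifelse(is.na(vars), NA_character_, colnames(x)[vars]),
              x = x, y = as.numeric(y), n = n, p = p,
              standardize = standardize)
  class(out) <- "lasso_path"
  out
}

#' @export
print.lasso_path <- function(x, ...) {
  cat("Lasso solution path:", x$p, "predictors,", x$n, "observations\n")
  ent <- x$event == "enter"
  if (!any(ent)) {
    cat("  empty path (no signal)\n")
    return(invisible(x))
  }
  cat("  entry knots:\n")
  print(data.frame(variable = x$var[ent],
                   lambda = signif(x$lambda[ent], 6)), row.names = FALSE)
  invisible(x)
}

# Coefficients at an arbitrary lambda by linear interpolation between knots.
beta_at <- function(path, lambda) {
  K <- length(path$lambda)
  if (K == 0L || lambda >= path$lambda[1]) return(numeric(path$p))
  if (lambda <= path$lambda[K]) {
    if (lambda < path$lambda[K] && path$event[K] != "end" &&
        path$lambda[K] > 1e-8 * max(path$lambda[1], 1))
      stop("path was truncated above lambda = ", lambda, call. = FALSE)
    return(path$beta[K, ])
  }
  k <- max(which(path$lambda >= lambda))
  l1 <- path$lambda[k]; l2 <- path$lambda[k + 1L]
  if (l1 == l2) return(path$beta[k + 1L, ])
  f <- (l1 - lambda) / (l1 - l2)
  path$beta[k, ] + f * (path$beta[k + 1L, ] - path$beta[k, ])
}

#' Covariance test along a lasso path
#'
#' For the k-th variable entering the path at knot \eqn{\lambda_k}, the
#' statistic ("drop in variance") measures how much the fitted inner
#' product \eqn{\langle y, X\hat\beta(\lambda_{k+1})\rangle} exceeds that of
#' the lasso restricted to the previously active set, scaled by the error
#' variance:
#' \deqn{T_k = (\langle y, X\hat\beta(\lambda_{k+1})\rangle -
#'   \langle y, X_A\tilde\beta_A(\lambda_{k+1})\rangle) / \sigma^2.}
#' Under the null that the entering variable is irrelevant, \eqn{T_k} is
#' asymptotically standard exponential, so \eqn{p = \exp(-T_k)}. On an
#' orthonormal design \eqn{T_1 = \lambda_1(\lambda_1 - \lambda_2)/\sigma^2}.
#'
#' @param path A [lasso_path()].
#' @param sigma2 Error variance. Defaults to the residual variance of the
#'   full least-squares fit (requires n > p + 1).
#' @param k Number of path entries to test (default: all). Useful with a
#'   truncated path when only the first statistics are needed.
#' @return Object of class \code{"covtest_result"}: a data frame with one
#'   row per path entry — variable, entry order, knot, statistic, p_value.
#' @export
covariance_test <- function(path, sigma2 = NULL, k = NULL) {
  stopifnot(inherits(path, "lasso_path"))
  if (is.null(sigma2)) {
    if (path$n <= path$p + 1L) {
      stop("cannot estimate sigma^2 from the full least-squares fit when ",
           "n <= p + 1; supply `sigma2`", call. = FALSE)
    }
    res <- stats::lm.fit(path$x, path$y)$residuals
    sigma2 <- sum(res^2) / (path$n - path$p - 1L)
  }
  if (sigma2 <= 0) stop("`sigma2` must be positive", call. = FALSE)

  enters <- which(path$event == "enter")
  if (!is.null(k)) enters <- utils::head(enters, k)
  if (!length(enters)) {
    out <- data.frame(variable = character(0), entry = integer(0),
                      lambda = numeric(0), statistic = numeric(0),
                      p_value = numeric(0))
    class(out) <- c("covtest_result", "data.frame")
    attr(out, "sigma2") <- sigma2
    return(out)
  }

  x <- path$x; y <- path$y
  stat <- numeric(length(enters))
  for (i in seq_along(enters)) {
    k <- enters[i]
    lam_next <- if (k < length(path$lambda)) path$lambda[k + 1L] else 0
    full <- sum(y * drop(x %*% beta_at(path, lam_next)))
    # active set just before this entry: all variables entered, minus
    # dropped, strictly before event k
    act <- integer(0)
    if (k > 1L) {
      for (e in seq_len(k - 1L)) {
        v <- match(path$var[e], colnames(x))
        if (path$event[e] == "enter") act <- union(act, v)
        if (path$event[e] == "drop") act <- setdiff(act, v)
      }
    }
    reduced <- if (length(act)) {
      sub <- lasso_path(x[, act, drop = FALSE], y, standardize = FALSE)
      sum(y * drop(x[, act, drop = FALSE] %*% beta_at(sub, lam_next)))
    } else 0
    stat[i] <- (full - reduced) / sigma2
  }
  stat <- pmax(stat, 0)  # exact arithmetic gives >= 0; clamp roundoff
  out <- data.frame(variable = path$var[enters],
                    entry = seq_along(enters),
                    lambda = path$lambda[enters],
                    statistic = stat,
                    p_value = exp(-stat))
  class(out) <- c("covtest_result", "data.frame")
  attr(out, "sigma2") <- sigma2
  out
}

#' @export
print.covtest_result <- function(x, ...) {
  cat("Covariance test along the lasso path (sigma^2 =",
      signif(attr(x, "sigma2"), 5), ")\n")
  df <- as.data.frame(x)
  df$lambda <- signif(df$lambda, 6)
  df$statistic <- signif(df$statistic, 5)
  df$p_value <- signif(df$p_value, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Select significant features from a covariance test
#'
#' Variables whose covariance-test p-value falls below \code{alpha}, in
#' path entry order. When one-hot blocks represent a multi-level feature,
#' supply \code{groups} (named vector mapping design columns to feature
#' names); a feature's p-value is that of its first entering column.
#'
#' @param result A [covariance_test()] result.
#' @param alpha Significance level, default 0.05.
#' @param groups Optional named character vector: design column -> feature.
#' @return Character vector of significant feature names in entry order.
#' @export
screen_features <- function(result, alpha = 0.05, groups = NULL) {
  df <- as.data.frame(result)
  if (!nrow(df)) return(character(0))
  feat <- if (is.null(groups)) df$variable else {
    mapped <- unname(groups[df$variable])
    ifelse(is.na(mapped), df$variable, mapped)
  }
  first <- !duplicated(feat)
  df <- df[first, , drop = FALSE]
  feat <- feat[first]
  feat[df$p_value < alpha]
}

#' Lasso covariance-test screen of cohort features
#'
#' End-to-end feature screen: encodes all lifestyle features (no treatment
#' excluded), regresses BMI on the standardized design along the lasso
#' path, applies the covariance test and reports one row per feature
#' (multi-level features report their first entering column).
#'
#' @param cohort Validated cohort data frame with a \code{BMI} column.
#' @param alpha Significance level for the `significant` flag.
#' @return List with \code{table} (feature, statistic, p_value,
#'   significant), \code{result} (full [covariance_test()] output) and
#'   \code{path}.
#' @export
feature_screen <- function(cohort, alpha = 0.05) {
  enc <- encode_covariates(cohort, treatment = NULL)
  groups <- vapply(colnames(enc$x), function(cn) {
    hit <- vapply(names(enc$encoder$columns),
                  function(nm) identical(cn, nm) || startsWith(cn, paste0(nm, ".")),
                  logical(1))
    names(enc$encoder$columns)[which(hit)[1L]]
  }, character(1))
  path <- lasso_path(enc$x, cohort$BMI)
  res <- covariance_test(path)
  df <- as.data.frame(res)
  feat <- unname(groups[df$variable])
  first <- !duplicated(feat)
  tab <- data.frame(feature = feat[first],
                    statistic = df$statistic[first],
                    p_value = df$p_value[first])
  tab$significant <- tab$p_value < alpha
  list(table = tab, result = res, path = path, groups = groups)
}
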
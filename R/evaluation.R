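# Group decomposition of the testing data and KS-based comparison of BMI
# distributions.

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum vertical distance between the two empirical CDFs,
#' evaluated over the merged sample points. The default p-value uses the
#' asymptotic Kolmogorov distribution at effective sample size
#' \eqn{mn/(m+n)}; \code{exact = TRUE} delegates to the exact two-sample
#' distribution (ties permitting).
#'
#' @param a,b Non-empty numeric samples.
#' @param exact Use the exact small-sample null distribution.
#' @return Object of class \code{"ks_result"}: \code{D}, \code{p},
#'   \code{m}, \code{n}, \code{method}.
#' @examples
#' ks_two_sample(rnorm(50), rnorm(50, 1))
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA", call. = FALSE)
  m <- length(a); n <- length(b)
  w <- c(a, b)
  ord <- order(w)
  steps <- cumsum(ifelse(ord <= m, 1 / m, -1 / n))
  ws <- w[ord]
  # with ties, the ECDF gap is only attained after the last of each tie group
  last_of_run <- c(ws[-1] != ws[-length(ws)], TRUE)
  D <- max(abs(steps[last_of_run]))
  if (exact) {
    p <- suppressWarnings(stats::ks.test(a, b, exact = TRUE)$p.value)
    method <- "exact"
  } else {
    p <- ks_asymptotic_p(D, m, n)
    method <- "asymptotic"
  }
  structure(list(D = D, p = p, m = m, n = n, method = method),
            class = "ks_result")
}

# Asymptotic two-sided p-value: Kolmogorov series at sqrt(mn/(m+n)) * D.
ks_asymptotic_p <- function(D, m, n) {
  t <- sqrt(m * n / (m + n)) * D
  if (t < 1e-12) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' @export
print.ks_result <- function(x, ...) {
  cat("Two-sample KS test (", x$method, " p-value)\n", sep = "")
  cat("  D =", signif(x$D, 5), " p =", format.pval(x$p, digits = 4),
      " (m =", x$m, ", n =", x$n, ")\n")
  invisible(x)
}

#' One-for-all treatment recommendation on the testing data
#'
#' The general ("better on average") rule recommends to everyone the
#' treatment level whose arm shows the lower mean outcome on the testing
#' data. An exact tie is broken toward T = 0 with a warning.
#'
#' @param y Numeric outcome (BMI) on the testing data.
#' @param t Observed binary treatment on the testing data; both arms must
#'   be present.
#' @return \code{"0"} or \code{"1"}.
#' @export
general_rule <- function(y, t) {
  if (length(y) != length(t)) stop("`y` and `t` lengths differ", call. = FALSE)
  if (!all(t %in% c(0, 1))) stop("`t` must be binary 0/1", call. = FALSE)
  m0 <- mean(y[t == 0]); m1 <- mean(y[t == 1])
  if (is.nan(m0) || is.nan(m1)) {
    stop("both treatment arms must be present to form the general rule",
         call. = FALSE)
  }
  if (m0 == m1) {
    warning("arm means are exactly equal; breaking the tie toward T = 0",
            call. = FALSE)
    return("0")
  }
  if (m0 < m1) "0" else "1"
}

#' Decompose the testing data into O / NO / G groups
#'
#' The \emph{personalized optimal group} O holds the records whose observed
#' treatment equals their personalized optimal decision; the
#' \emph{non-optimal group} NO holds those whose observed treatment
#' differs; records with a tied decision are reported separately and belong
#' to neither. The \emph{general optimal group} G holds the records whose
#' observed treatment equals the one-for-all decision.
#'
#' @param t Observed binary treatment on the testing data.
#' @param decisions Personalized decisions (\code{"0"}/\code{"1"}/
#'   \code{"tie"}), e.g. from [predict.metalearner()] with
#'   \code{type = "decision"}.
#' @param general The one-for-all decision from [general_rule()].
#' @return Object of class \code{"group_decomposition"} with integer index
#'   sets \code{O}, \code{NO}, \code{G}, \code{ties} and the size \code{n}.
#' @export
decompose_groups <- function(t, decisions, general) {
  if (length(t) != length(decisions)) {
    stop("`t` and `decisions` lengths differ", call. = FALSE)
  }
  if (!all(t %in% c(0, 1))) stop("`t` must be binary 0/1", call. = FALSE)
  if (!all(decisions %in% c("0", "1", "tie"))) {
    stop("`decisions` must be \"0\", \"1\" or \"tie\"", call. = FALSE)
  }
  if (!general %in% c("0", "1")) {
    stop("`general` must be \"0\" or \"1\"", call. = FALSE)
  }
  obs <- as.character(as.integer(t))
  structure(list(
    O = which(obs == decisions),
    NO = which(decisions != "tie" & obs != decisions),
    G = which(obs == general),
    ties = which(decisions == "tie"),
    n = length(t), general = general
  ), class = "group_decomposition")
}

#' @export
print.group_decomposition <- function(x, ...) {
  cat("Testing-data group decomposition (n =", x$n, ")\n")
  cat("  personalized optimal |O| =", length(x$O),
      " | non-optimal |NO| =", length(x$NO),
      " | ties =", length(x$ties), "\n")
  cat("  general optimal |G| =", length(x$G),
      " (one-for-all decision T =", x$general, ")\n")
  invisible(x)
}

#' Ratio of treated to untreated counts within a group
#'
#' E.g. the alcohol Yes/No ratio of a group: (records with T = 1) /
#' (records with T = 0), reported to 3 decimals. A zero denominator is
#' undefined and reported as NA, never as infinity.
#'
#' @param t Observed binary treatment restricted to the group, or NULL if
#'   \code{counts} is given.
#' @param counts Alternative: numeric \code{c(n1, n0)} of level-1 and
#'   level-0 counts.
#' @return The rounded ratio, or NA if the level-0 count is zero.
#' @examples
#' treatment_ratio(counts = c(1130, 414))
#' @export
treatment_ratio <- function(t = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (!all(t %in% c(0, 1))) stop("`t` must be binary 0/1", call. = FALSE)
    counts <- c(sum(t == 1), sum(t == 0))
  }
  if (length(counts) != 2L || any(counts < 0)) {
    stop("`counts` must be c(n1, n0) with non-negative entries", call. = FALSE)
  }
  if (counts[2] == 0) return(NA_real_)
  round(counts[1] / counts[2], 3)
}

#' Overlap between two personalized optimal groups
#'
#' Percentage of the first learner's personalized optimal records that are
#' also personalized optimal under the second learner:
#' \eqn{100 |O_a \cap O_b| / |O_a|}.
#'
#' @param O_a,O_b Integer index sets (e.g. the \code{O} component of two
#'   [decompose_groups()] results over the same testing data).
#' @return Percentage in [0, 100]; NA if \code{O_a} is empty.
#' @export
learner_overlap <- function(O_a, O_b) {
  if (!length(O_a)) return(NA_real_)
  100 * length(intersect(O_a, O_b)) / length(O_a)
}
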
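#' Define how a cohort column maps to a binary treatment
#'
#' The decision problem needs a two-option treatment \eqn{T \in \{0, 1\}};
#' lower outcome (BMI) is always the preferred direction. Built-in rules
#' cover the four dietary treatments of interest:
#' \describe{
#'   \item{CALC}{any positive alcohol-intake frequency (Sometimes,
#'     Frequently, Always) -> 1; No -> 0.}
#'   \item{FCVC}{vegetable intake in every meal, FCVC > 2 -> 1; else 0.}
#'   \item{FAVC}{frequent high caloric food, Yes -> 1; No -> 0.}
#'   \item{CH2O}{daily water intake above 2 liters, CH2O > 2 -> 1; else 0.}
#'   \item{T}{identity rule for a column already coded 0/1 (synthetic cohorts).}
#' }
#'
#' @param variable Column name of the treatment.
#' @param rule Optional custom rule: a function mapping the raw column to a
#'   0/1 vector, or a named vector such as \code{c(No = 0, Yes = 1)}.
#'   Required when `variable` has no built-in rule.
#' @param label0,label1 Human-readable names of the two options.
#' @return Object of class \code{"treatment_spec"}.
#' @examples
#' treatment_spec("CALC")
#' treatment_spec("NCP", rule = function(v) as.integer(v > 3),
#'                label1 = "many meals", label0 = "few meals")
#' @export
treatment_spec <- function(variable, rule = NULL, label0 = NULL, label1 = NULL) {
  builtin <- list(
    CALC = list(rule = c(No = 0, Sometimes = 1, Frequently = 1, Always = 1),
                label0 = "zero alcohol intake", label1 = "positive alcohol intake"),
    FCVC = list(rule = function(v) as.integer(v > 2),
                label0 = "low vegetable intake", label1 = "vegetables in every meal"),
    FAVC = list(rule = c(No = 0, Yes = 1),
                label0 = "low caloric-food frequency", label1 = "high caloric-food frequency"),
    CH2O = list(rule = function(v) as.integer(v > 2),
                label0 = "water <= 2 liters/day", label1 = "water > 2 liters/day"),
    T    = list(rule = function(v) as.integer(v),
                label0 = "control", label1 = "treated")
  )
  if (is.null(rule)) {
    if (!variable %in% names(builtin)) {
      stop("no built-in binarization rule for `", variable,
           "`; supply `rule`", call. = FALSE)
    }
    b <- builtin[[variable]]
    rule <- b$rule
    label0 <- label0 %||% b$label0
    label1 <- label1 %||% b$label1
  }
  structure(list(variable = variable, rule = rule,
                 label0 = label0 %||% "option 0",
                 label1 = label1 %||% "option 1",
                 direction = "lower outcome is better"),
            class = "treatment_spec")
}

#' @export
print.treatment_spec <- function(x, ...) {
  cat("Binary treatment on `", x$variable, "`\n", sep = "")
  cat("  T = 1: ", x$label1, "\n  T = 0: ", x$label0, "\n", sep = "")
  cat("  direction: ", x$direction, "\n", sep = "")
  invisible(x)
}

#' Binarize a treatment column
#'
#' Applies a [treatment_spec()] rule to the cohort, producing the observed
#' treatment vector in \{0, 1\}. The rule must cover every observed value.
#'
#' @param cohort Cohort data frame.
#' @param spec A [treatment_spec()].
#' @return Integer vector of 0/1 treatment indicators.
#' @export
binarize_treatment <- function(cohort, spec) {
  stopifnot(inherits(spec, "treatment_spec"))
  if (!spec$variable %in% names(cohort)) {
    stop("treatment column `", spec$variable, "` not found", call. = FALSE)
  }
  v <- cohort[[spec$variable]]
  t <- if (is.function(spec$rule)) {
    spec$rule(v)
  } else {
    unname(spec$rule[as.character(v)])
  }
  bad <- is.na(t) | !(t %in% c(0, 1))
  if (any(bad)) {
    stop("treatment rule for `", spec$variable,
         "` does not map value(s): ",
         paste(utils::head(unique(as.character(v)[bad]), 5L), collapse = ", "),
         call. = FALSE)
  }
  as.integer(t)
}
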
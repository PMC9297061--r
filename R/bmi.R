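#' Compute body mass index
#'
#' BMI = weight / height^2, with weight in kilograms and height in metres.
#'
#' @param weight Numeric vector of body weights (kg); must be positive.
#' @param height Numeric vector of heights (m); must be positive.
#' @return Numeric vector of BMI values (kg/m^2).
#' @examples
#' compute_bmi(80, 1.75)
#' @export
compute_bmi <- function(weight, height) {
  if (length(weight) != length(height)) {
    stop("`weight` and `height` must have equal length", call. = FALSE)
  }
  bad <- which(!is.finite(weight) | !is.finite(height) |
                 weight <= 0 | height <= 0)
  if (length(bad)) {
    stop("non-positive or missing weight/height at record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  weight / height^2
}

#' Obesity category labels in increasing BMI order
#' @export
bmi_categories <- function() {
  c("underweight", "normal", "overweight", "obese_I", "obese_II", "obese_III")
}

#' Categorize BMI into the six standard obesity classes
#'
#' Classes are assigned by half-open intervals \code{[0, 18.5)},
#' \code{[18.5, 25)}, \code{[25, 30)}, \code{[30, 35)}, \code{[35, 40)} and
#' \code{[40, Inf)}, so each boundary value belongs to the class above it.
#'
#' @param bmi Numeric vector of BMI values; must be finite and positive.
#' @return Factor with levels \code{bmi_categories()}.
#' @examples
#' categorize_bmi(c(17, 18.5, 26, 31, 36, 41))
#' @export
categorize_bmi <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("BMI values must be finite and positive", call. = FALSE)
  }
  cut(bmi, breaks = c(0, 18.5, 25, 30, 35, 40, Inf),
      labels = bmi_categories(), right = FALSE)
}

#' Restrict a cohort to overweight and obese individuals
#'
#' Retains records with BMI strictly greater than 24.9 (the lowering-BMI
#' decision problem is only posed for overweight and obese people). Record
#' order is preserved.
#'
#' @param cohort Data frame with a numeric \code{BMI} column.
#' @return The filtered data frame; a warning is raised if nothing remains.
#' @export
filter_overweight <- function(cohort) {
  if (!"BMI" %in% names(cohort)) {
    stop("cohort has no `BMI` column; run read_cohort()/validate_cohort() first",
         call. = FALSE)
  }
  keep <- cohort$BMI > 24.9
  if (!any(keep)) {
    warning("no overweight or obese records (BMI > 24.9) remain", call. = FALSE)
  }
  cohort[keep, , drop = FALSE]
}
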
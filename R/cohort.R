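# Cohort schema, validated reading and writing.

# Declared feature schema of the lifestyle cohort: the 14 demographic and
# dietary features, plus Height/Weight used only to derive the BMI outcome.
# Continuous ranges and categorical level sets are the validation contract.
cohort_schema <- function() {
  list(
    continuous = list(
      Age   = c(10, 100),
      FCVC  = c(1, 3),   # vegetable intake frequency
      NCP   = c(1, 4),   # number of main meals
      CH2O  = c(1, 3),   # daily water intake, liters
      FAF   = c(0, 3),   # physical activity frequency
      TUE   = c(0, 2)    # time on technological devices
    ),
    categorical = list(
      Gender = c("Female", "Male"),
      FHWO   = c("No", "Yes"),  # family history with overweight
      FAVC   = c("No", "Yes"),  # frequent high caloric food
      SCC    = c("No", "Yes"),  # calorie monitoring
      SMOKE  = c("No", "Yes"),
      CAEC   = c("Always", "Frequently", "No", "Sometimes"),
      CALC   = c("Always", "Frequently", "No", "Sometimes"),
      MTRANS = c("Automobile", "Bike", "Motorbike",
                 "Public_Transportation", "Walking")
    ),
    anthropometric = list(
      Height = c(1.0, 2.5),  # meters
      Weight = c(20, 250)    # kilograms
    )
  )
}

# Column-name synonyms seen in public copies of the obesity schema.
.default_col_map <- c(
  family_history_with_overweight = "FHWO",
  CH2O = "CH2O", `CH_2_O` = "CH2O",
  Biking = "Bike"
)

#' Read and validate a lifestyle cohort CSV
#'
#' Reads a header CSV with the 17-column obesity lifestyle schema (Age,
#' Gender, Height, Weight, FHWO, FAVC, FCVC, NCP, CAEC, SMOKE, CH2O, SCC,
#' FAF, TUE, CALC, MTRANS and an optional obesity-level label, which is
#' ignored), validates it against the declared level sets and ranges, and
#' appends derived \code{BMI} and \code{BMI_category} columns.
#'
#' @param path Path to the CSV file.
#' @param col_map Optional named character vector mapping raw column names to
#'   schema names (e.g. \code{c(family_history_with_overweight = "FHWO")});
#'   merged with built-in synonyms.
#' @return Validated data frame with \code{BMI} and \code{BMI_category}.
#' @seealso [validate_cohort()], [write_cohort()]
#' @export
read_cohort <- function(path, col_map = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- c(.default_col_map, col_map)
  hit <- names(raw) %in% names(map)
  names(raw)[hit] <- unname(map[names(raw)[hit]])
  validate_cohort(raw)
}

#' Validate a cohort data frame against the lifestyle schema
#'
#' Checks for required columns, missing values (rejected, never imputed),
#' positive height/weight, continuous ranges and categorical level sets
#' (level case is normalized, e.g. "yes" -> "Yes"), then derives BMI.
#'
#' @param data Data frame with the schema columns.
#' @return Validated data frame with \code{BMI} and \code{BMI_category}
#'   appended (recomputed if already present).
#' @export
validate_cohort <- function(data) {
  sch <- cohort_schema()
  need <- c(names(sch$continuous), names(sch$categorical),
            names(sch$anthropometric))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c(names(sch$continuous), names(sch$anthropometric))) {
    v <- suppressWarnings(as.numeric(data[[nm]]))
    if (anyNA(v)) {
      stop("missing or non-numeric values in `", nm, "` at record(s): ",
           paste(utils::head(which(is.na(v)), 5L), collapse = ", "),
           call. = FALSE)
    }
    rng <- c(sch$continuous, sch$anthropometric)[[nm]]
    out <- which(v < rng[1] - 1e-8 | v > rng[2] + 1e-8)
    if (length(out)) {
      stop("`", nm, "` outside [", rng[1], ", ", rng[2], "] at record(s): ",
           paste(utils::head(out, 5L), collapse = ", "), call. = FALSE)
    }
    data[[nm]] <- v
  }
  for (nm in names(sch$categorical)) {
    v <- as.character(data[[nm]])
    lv <- sch$categorical[[nm]]
    idx <- match(tolower(v), tolower(lv))
    if (anyNA(idx)) {
      bad <- unique(v[is.na(idx)])
      stop("`", nm, "` has value(s) outside {", paste(lv, collapse = ", "),
           "}: ", paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    data[[nm]] <- lv[idx]
  }
  data$BMI <- compute_bmi(data$Weight, data$Height)
  data$BMI_category <- categorize_bmi(data$BMI)
  data
}

#' Write a validated cohort back to CSV
#'
#' Round-trips the cohort with its derived \code{BMI} and
#' \code{BMI_category} columns appended.
#'
#' @param cohort Validated cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Published summary counts of the obesity lifestyle cohort
#'
#' Returns the published per-category counts of the public obesity-levels
#' cohort (2111 adults from Colombia, Peru and Mexico): the six BMI-category
#' counts over the full cohort, and the categorical feature counts over its
#' overweight/obese subset, together with the covariance-test screen
#' reported for that subset. Note the two subset totals deliberately
#' disagree: the categorical feature counts sum to 1544 while the
#' BMI-category counts imply 1552 individuals with BMI >= 25; both are
#' reported as published, without reconciliation.
#'
#' @return List with elements \code{bmi_categories} (named counts),
#'   \code{features} (data frame: feature, level, count),
#'   \code{screen} (data frame: feature, statistic, p_value),
#'   \code{n_total}, \code{n_overweight_by_bmi}, \code{n_overweight_by_features}.
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "obesity_reference_counts.csv",
                      package = "metacate", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  bmi <- tab[tab$table == "bmi_category", ]
  feat <- tab[tab$table == "feature_count", c("feature", "level", "count")]
  scr <- tab[tab$table == "covtest", c("feature", "statistic", "p_value")]
  bmi_counts <- stats::setNames(bmi$count, bmi$level)
  list(
    bmi_categories = bmi_counts,
    features = feat,
    screen = scr,
    n_total = sum(bmi_counts),
    n_overweight_by_bmi = sum(bmi_counts[c("overweight", "obese_I",
                                           "obese_II", "obese_III")]),
    n_overweight_by_features = sum(feat$count[feat$feature == "FHWO"])
  )
}

#' Check a cohort CSV against the published category counts
#'
#' Recomputes BMI categories from a user-supplied copy of the public
#' obesity-levels dataset and compares the counts with the published ones.
#'
#' @param path Path to the cohort CSV.
#' @return List with \code{match} (logical), \code{observed} and
#'   \code{expected} count vectors.
#' @export
verify_cohort_counts <- function(path) {
  cohort <- read_cohort(path)
  observed <- table(cohort$BMI_category)
  expected <- reference_counts()$bmi_categories
  observed <- stats::setNames(as.integer(observed[names(expected)]),
                              names(expected))
  list(match = identical(unname(observed), unname(as.integer(expected))),
       observed = observed, expected = expected)
}
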
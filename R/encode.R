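#' Encode cohort covariates as a numeric design matrix
#'
#' Builds the covariate design for the base learners: all lifestyle and
#' demographic features except the treatment column itself, with categorical
#' features one-hot encoded under a drop-first scheme in lexicographic level
#' order (so a k-level factor contributes k - 1 indicator columns and the
#' design stays full rank). Height, Weight, the BMI outcome and any latent
#' truth columns (\code{.truth_*}, produced by the synthetic generator) are
#' never covariates. Constant columns are dropped with a warning.
#'
#' @param cohort Cohort data frame.
#' @param treatment Name of the treatment column to exclude (or a
#'   [treatment_spec()]).
#' @param encoder Optional encoder returned by a previous call; reusing it
#'   guarantees an identical column layout on new data (required when
#'   predicting on a test split).
#' @return List with \code{x} (numeric matrix) and \code{encoder}.
#' @export
encode_covariates <- function(cohort, treatment = NULL, encoder = NULL) {
  if (inherits(treatment, "treatment_spec")) treatment <- treatment$variable
  new_encoder <- is.null(encoder)
  if (new_encoder) {
    drop_cols <- c(treatment, "Height", "Weight", "BMI", "BMI_category",
                   "NObeyesdad", "T", "y",
                   grep("^\\.truth_", names(cohort), value = TRUE))
    use <- setdiff(names(cohort), drop_cols)
    if (!length(use)) stop("no covariate columns left to encode", call. = FALSE)
    cols <- list()
    for (nm in use) {
      v <- cohort[[nm]]
      if (is.numeric(v)) {
        cols[[nm]] <- list(name = nm, type = "numeric")
      } else {
        lv <- sort(unique(as.character(v)))
        if (length(lv) < 2L) {
          warning("dropping constant covariate column: ", nm, call. = FALSE)
          next
        }
        cols[[nm]] <- list(name = nm, type = "categorical", levels = lv)
      }
    }
    if (!length(cols)) stop("no non-constant covariates to encode", call. = FALSE)
    encoder <- structure(list(columns = cols), class = "cohort_encoder")
  }
  blocks <- lapply(encoder$columns, function(col) {
    if (!col$name %in% names(cohort)) {
      stop("encoder column `", col$name, "` missing from data", call. = FALSE)
    }
    v <- cohort[[col$name]]
    if (col$type == "numeric") {
      m <- matrix(as.numeric(v), ncol = 1,
                  dimnames = list(NULL, col$name))
    } else {
      v <- as.character(v)
      unknown <- setdiff(unique(v), col$levels)
      if (length(unknown)) {
        stop("`", col$name, "` has level(s) unseen by the encoder: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      keep <- col$levels[-1L]  # drop-first reference level
      m <- vapply(keep, function(lv) as.numeric(v == lv),
                  numeric(length(v)))
      m <- matrix(m, nrow = length(v),
                  dimnames = list(NULL, paste(col$name, keep, sep = ".")))
    }
    m
  })
  x <- do.call(cbind, blocks)
  if (new_encoder) {
    const <- apply(x, 2L, function(col) length(unique(col)) == 1L)
    if (any(const) && nrow(x) > 1L) {
      warning("dropping constant covariate column(s): ",
              paste(colnames(x)[const], collapse = ", "), call. = FALSE)
      x <- x[, !const, drop = FALSE]
    }
    encoder$keep <- colnames(x)
  } else {
    # reusing an encoder reproduces its exact column layout
    x <- x[, encoder$keep, drop = FALSE]
  }
  list(x = x, encoder = encoder)
}

#' Augment a design with treatment and first-order interactions
#'
#' Returns \code{[x, t, x * t]}: the covariates, the binary treatment, and
#' every treatment-by-covariate interaction. The interaction block is zero
#' on control rows and equals the covariate block on treated rows. This is
#' the design the S and SXwint learners fit their joint outcome model on.
#'
#' @param x Numeric covariate matrix (n x p).
#' @param t Binary 0/1 treatment vector of length n.
#' @return Numeric matrix with 2p + 1 columns.
#' @export
build_interactions <- function(x, t) {
  x <- as.matrix(x)
  if (length(t) != nrow(x)) stop("`t` length must match rows of `x`", call. = FALSE)
  if (!all(t %in% c(0, 1))) stop("`t` must be binary 0/1", call. = FALSE)
  inter <- x * t
  colnames(inter) <- paste0(colnames(x), ":t")
  cbind(x, t = t, inter)
}
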
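#' Run the full personalized-decision analysis
#'
#' End-to-end pipeline: load or simulate a cohort, restrict to overweight
#' and obese records, screen features with the lasso covariance test, and
#' for each requested treatment fit the requested metalearners, predict
#' personalized optimal decisions on a common testing half, decompose the
#' testing data into personalized optimal (O), non-optimal (NO) and general
#' optimal (G) groups, and compare BMI distributions with two-sample KS
#' tests.
#'
#' Split topology: one seeded permutation divides the cohort into a
#' training and a testing half; T, S and X learners fit on the whole
#' training half, while SX and SXwint split that same half again into
#' equal training and re-training parts. Every learner is therefore
#' evaluated on the identical testing records, which also fixes the G
#' group across learners for a given treatment.
#'
#' @param data Cohort input: a CSV path (read with [read_cohort()]), a
#'   validated data frame, or a [synthetic_config()].
#' @param treatments Character vector of treatment columns; each needs a
#'   built-in [treatment_spec()] rule (\code{CALC}, \code{FCVC},
#'   \code{FAVC}, \code{CH2O}, or \code{T} for synthetic cohorts), or pass
#'   a named list of [treatment_spec()] objects.
#' @param learners Metalearner kinds to fit.
#' @param base A [base_learner()].
#' @param seed Integer master seed for splits and stochastic learners.
#' @param filter Restrict to BMI > 24.9 before the analysis (default TRUE).
#' @param resplit_per_treatment Draw a fresh split for each treatment
#'   instead of sharing one split across treatments (default FALSE).
#' @param screen Run the covariance-test feature screen (default TRUE).
#' @param outdir Optional directory; when given, per-treatment report,
#'   ratio, overlap and decision CSVs plus the feature screen are written
#'   there.
#' @return Object of class \code{"cate_analysis"}: per-treatment results
#'   (fits, decisions, groups, KS tests, ratios, overlap matrix), the
#'   feature screen, and the splits used.
#' @export
run_analysis <- function(data,
                         treatments = "CALC",
                         learners = c("T", "X", "S", "SX", "SXwint"),
                         base = base_learner(),
                         seed = 1,
                         filter = TRUE,
                         resplit_per_treatment = FALSE,
                         screen = TRUE,
                         outdir = NULL) {
  cohort <- if (inherits(data, "synthetic_config")) {
    generate_cohort(data)
  } else if (is.character(data)) {
    read_cohort(data)
  } else if (is.data.frame(data)) {
    if (all(c("Height", "Weight") %in% names(data)) && !"BMI" %in% names(data)) {
      validate_cohort(data)
    } else data
  } else {
    stop("`data` must be a CSV path, a data frame or a synthetic_config",
         call. = FALSE)
  }
  if (!"BMI" %in% names(cohort)) {
    stop("cohort has no `BMI` outcome column", call. = FALSE)
  }
  if (filter) cohort <- filter_overweight(cohort)
  n <- nrow(cohort)
  if (n < 8L) stop("cohort too small after filtering (n = ", n, ")",
                   call. = FALSE)
  if (!length(learners)) stop("`learners` must be non-empty", call. = FALSE)
  learners <- match.arg(learners, c("T", "X", "S", "SX", "SXwint"),
                        several.ok = TRUE)

  specs <- if (is.list(treatments) && all(vapply(treatments, inherits,
                                                 logical(1), "treatment_spec"))) {
    stats::setNames(treatments,
                    vapply(treatments, `[[`, character(1), "variable"))
  } else {
    stats::setNames(lapply(treatments, treatment_spec), treatments)
  }

  screen_out <- if (screen) feature_screen(cohort) else NULL

  make_splits <- function(s) {
    halves <- split_cohort(n, c(train = 0.5, test = 0.5), seed = s)
    sub <- split_cohort(length(halves$train),
                        c(train = 0.5, retrain = 0.5),
                        seed = stage_seed(s, "retrain-split"))
    list(train = halves$train, test = halves$test,
         sx_train = sub$train, sx_retrain = sub$retrain)
  }

  results <- list()
  for (ti in seq_along(specs)) {
    spec <- specs[[ti]]
    trt <- names(specs)[ti]
    sp <- make_splits(if (resplit_per_treatment) stage_seed(seed, trt) else seed)
    t_all <- binarize_treatment(cohort, spec)
    enc <- encode_covariates(cohort, treatment = spec)
    x <- enc$x
    y <- cohort$BMI
    tr <- sp$train; te <- sp$test

    fits <- list(); taus <- list(); decs <- list(); groups <- list()
    rows <- list()
    general <- general_rule(y[te], t_all[te])
    for (kind in learners) {
      fit <- tryCatch({
        if (kind %in% c("SX", "SXwint")) {
          metalearner(x[tr, , drop = FALSE], y[tr], t_all[tr], kind = kind,
                      base = base, train = sp$sx_train,
                      retrain = sp$sx_retrain,
                      seed = stage_seed(seed, paste(trt, kind)))
        } else {
          metalearner(x[tr, , drop = FALSE], y[tr], t_all[tr], kind = kind,
                      base = base,
                      seed = stage_seed(seed, paste(trt, kind)))
        }
      }, error = function(e) {
        stop("[", trt, "/", kind, " fit] ", conditionMessage(e), call. = FALSE)
      })
      tau <- predict(fit, x[te, , drop = FALSE])
      dec <- decide_optimal(tau)
      grp <- decompose_groups(t_all[te], dec, general)
      ks1 <- if (length(grp$O) && length(grp$NO)) {
        ks_two_sample(y[te][grp$O], y[te][grp$NO])
      }
      ks2 <- if (length(grp$O) && length(grp$G)) {
        ks_two_sample(y[te][grp$O], y[te][grp$G])
      }
      fits[[kind]] <- fit; taus[[kind]] <- tau; decs[[kind]] <- dec
      groups[[kind]] <- grp
      rows[[kind]] <- data.frame(
        learner = kind,
        KS1_D = if (is.null(ks1)) NA_real_ else ks1$D,
        KS1_p = if (is.null(ks1)) NA_real_ else ks1$p,
        KS2_D = if (is.null(ks2)) NA_real_ else ks2$D,
        KS2_p = if (is.null(ks2)) NA_real_ else ks2$p,
        n_O = length(grp$O), n_NO = length(grp$NO),
        n_G = length(grp$G), n_ties = length(grp$ties),
        ratio_O = treatment_ratio(t_all[te][grp$O]),
        ratio_NO = treatment_ratio(t_all[te][grp$NO]))
    }
    report <- do.call(rbind, rows)
    rownames(report) <- NULL
    overlap <- outer(learners, learners,
                     Vectorize(function(a, b) {
                       learner_overlap(groups[[a]]$O, groups[[b]]$O)
                     }))
    dimnames(overlap) <- list(learners, learners)
    results[[trt]] <- list(
      spec = spec, split = sp, treatment = t_all,
      general = general, fits = fits, tau = taus,
      decisions = decs, groups = groups,
      report = report, overlap = overlap,
      ratio_testing = treatment_ratio(t_all[te]),
      ratio_cohort = treatment_ratio(t_all))
  }

  out <- structure(list(
    n = n, seed = seed, learners = learners,
    treatments = results, screen = screen_out,
    cohort = cohort
  ), class = "cate_analysis")
  if (!is.null(outdir)) write_reports(out, outdir)
  out
}

#' Write pipeline reports to CSV
#'
#' Emits, per treatment: the KS/group-size report, the treated/untreated
#' ratio table, the learner-overlap matrix, and per-record estimated
#' effects and decisions; plus the feature-screen table.
#'
#' @param analysis A [run_analysis()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_reports <- function(analysis, outdir) {
  stopifnot(inherits(analysis, "cate_analysis"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (trt in names(analysis$treatments)) {
    res <- analysis$treatments[[trt]]
    utils::write.csv(res$report,
                     file.path(outdir, paste0("report_", trt, ".csv")),
                     row.names = FALSE)
    ratios <- data.frame(
      group = c("testing", "cohort",
                paste0(res$report$learner, "_O"),
                paste0(res$report$learner, "_NO")),
      ratio = c(res$ratio_testing, res$ratio_cohort,
                res$report$ratio_O, res$report$ratio_NO))
    utils::write.csv(ratios,
                     file.path(outdir, paste0("ratios_", trt, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$overlap),
                     file.path(outdir, paste0("overlap_", trt, ".csv")))
    dec <- data.frame(id = res$split$test)
    for (kind in names(res$tau)) {
      dec[[paste0("tau_", kind)]] <- res$tau[[kind]]
      dec[[paste0("decision_", kind)]] <- res$decisions[[kind]]
    }
    utils::write.csv(dec,
                     file.path(outdir, paste0("decisions_", trt, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(analysis$screen)) {
    utils::write.csv(analysis$screen$table,
                     file.path(outdir, "feature_screen.csv"),
                     row.names = FALSE)
  }
  invisible(outdir)
}

#' @export
print.cate_analysis <- function(x, ...) {
  cat("Personalized-decision analysis: n =", x$n,
      "| learners:", paste(x$learners, collapse = ", "), "\n")
  if (!is.null(x$screen)) {
    sig <- x$screen$table$feature[x$screen$table$significant]
    cat("significant features (covariance test, 5%):",
        paste(sig, collapse = ", "), "\n")
  }
  for (trt in names(x$treatments)) {
    res <- x$treatments[[trt]]
    cat("\nTreatment:", trt,
        "(one-for-all decision: T =", res$general, ")\n")
    df <- res$report
    df$KS1_D <- signif(df$KS1_D, 4); df$KS2_D <- signif(df$KS2_D, 4)
    df$KS1_p <- format.pval(df$KS1_p, digits = 3)
    df$KS2_p <- format.pval(df$KS2_p, digits = 3)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
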
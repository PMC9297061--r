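#' Reproducible random partition of a cohort
#'
#' Shuffles the record indices with a seeded permutation and cuts them into
#' named parts whose sizes follow the requested fractions under
#' largest-remainder rounding (each part gets floor(n * f); leftover records
#' go to the parts with the largest fractional remainders, earlier parts
#' winning ties). The parts are disjoint and exhaustive.
#'
#' @param n Number of records, or a data frame whose rows are split.
#' @param fractions Named numeric vector of proportions summing to 1, e.g.
#'   \code{c(train = 0.25, retrain = 0.25, test = 0.5)}.
#' @param seed Integer seed driving the permutation.
#' @return Named list of integer index vectors.
#' @examples
#' split_cohort(8, c(train = 0.25, retrain = 0.25, test = 0.5), seed = 1)
#' @export
split_cohort <- function(n, fractions = c(train = 0.5, test = 0.5), seed = 1) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n)
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    names(fractions) <- paste0("part", seq_along(fractions))
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must sum to 1", call. = FALSE)
  }
  sizes <- floor(n * fractions)
  left <- n - sum(sizes)
  if (left > 0) {
    rem <- n * fractions - sizes
    bump <- order(-rem, seq_along(rem))[seq_len(left)]
    sizes[bump] <- sizes[bump] + 1L
  }
  if (any(sizes == 0L)) {
    stop("split part(s) empty for n = ", n, ": ",
         paste(names(sizes)[sizes == 0L], collapse = ", "), call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- Map(function(a, b) sort(perm[a:b]), starts, ends)
  names(out) <- names(fractions)
  out
}
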
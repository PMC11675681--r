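#' Sample entropy of an RR segment
#'
#' SampEn(m, r) is `-ln(A/B)`, where `B` counts pairs of distinct m-length
#' templates whose Chebyshev distance is at most `r` and `A` counts the same
#' for (m+1)-length templates; self-matches are excluded. Lower values mean a
#' more regular series. The tolerance may be given in ms or as a fraction of
#' the segment's standard deviation (the field-standard convention
#' `r = 0.2 * SD`, the default here).
#'
#' The implementation vectorises over template offsets (for each lag it
#' computes the running Chebyshev maximum of the absolute difference series),
#' which is algebraically identical to the textbook double loop over template
#' pairs; equality against a naive oracle is part of the test suite.
#'
#' @inheritParams poincare_points
#' @param m embedding (template) length in beats, default 2.
#' @param r tolerance; interpretation set by `r_type`.
#' @param r_type `"sd_fraction"` (default: `r * sd(x)`) or `"absolute"` (ms).
#' @return SampEn value (dimensionless); `NA` when no template pair matches
#'   at length m or m+1.
#' @export
sampen <- function(x, m = 2, r = 0.2, r_type = c("sd_fraction", "absolute")) {
  x <- as_intervals(x)
  r_type <- match.arg(r_type)
  n <- length(x)
  if (n < m + 2L) stop("need at least m + 2 intervals", call. = FALSE)
  tol <- if (r_type == "sd_fraction") r * stats::sd(x) else r
  if (tol < 0) stop("tolerance must be non-negative", call. = FALSE)
  cnt <- sampen_counts(x, m, tol)
  if (cnt$B == 0 || cnt$A == 0) return(NA_real_)
  -log(cnt$A / cnt$B)
}

# Counts of matching template pairs (i < j counted once; the A/B ratio is
# unaffected by the symmetric double-count convention).
sampen_counts <- function(x, m, tol) {
  n <- length(x)
  a <- 0
  b <- 0
  # template starts i, j = i + lag both range over 1..n-m (the convention
  # in which every m-template has an (m+1)-extension, so a constant series
  # gives A/B = 1 exactly)
  for (lag in seq_len(n - m - 1L)) {
    e <- abs(x[(1 + lag):n] - x[1:(n - lag)])  # length n - lag
    le <- length(e)
    w <- e[1:(le - m)]
    if (m > 1L) {
      for (k in 1:(m - 1L)) w <- pmax(w, e[(1 + k):(le - m + k)])
    }
    b <- b + sum(w <= tol)
    w <- pmax(w, e[(1 + m):le])
    a <- a + sum(w <= tol)
  }
  list(A = a, B = b)
}
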
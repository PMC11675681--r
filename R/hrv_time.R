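#' Poincare-plot coordinates of an RR series
#'
#' For consecutive normal-to-normal intervals, the Poincare plot is the
#' scatter of (x_i, x_{i+1}). Each point is described by its signed distance
#' from the identity line, `d_i = (x_{i+1} - x_i)/sqrt(2)`, and its signed
#' position along the identity line relative to the plot centroid,
#' `s_i = (x_i + x_{i+1} - 2*xbar)/sqrt(2)`, where `xbar` is the mean over
#' all plot coordinates. `d_i > 0` corresponds to a heart-rate deceleration
#' (the RR interval lengthens), `d_i < 0` to an acceleration.
#'
#' These are second-moment coordinates: SD1/SD2 and their
#' deceleration/acceleration components are root mean squares of `d` and `s`
#' (no re-centering), which is the convention under which the asymmetry
#' partitions of [variance_decomposition()] are exact identities.
#'
#' @param x numeric vector of NN intervals (ms) or an [rr_series()].
#' @return A list with vectors `x1`, `x2`, `d`, `s` and the scalar `xbar`.
#' @export
poincare_points <- function(x) {
  x <- as_intervals(x)
  n <- length(x)
  if (n < 3L) stop("need at least 3 intervals", call. = FALSE)
  x1 <- x[-n]
  x2 <- x[-1]
  xbar <- (sum(x1) + sum(x2)) / (2 * (n - 1))  # mean over all plot coordinates
  list(x1 = x1, x2 = x2,
       d = (x2 - x1) / sqrt(2),
       s = (x1 + x2 - 2 * xbar) / sqrt(2),
       xbar = xbar)
}

# Accept raw numeric vectors or rr_series throughout the descriptor layer.
# rr_series inputs must be artifact-free (use mask_artifacts() first).
as_intervals <- function(x) {
  if (inherits(x, "rr_series")) {
    if (any(x$annotations != "normal")) {
      stop("series contains artifact beats; apply mask_artifacts() first",
           call. = FALSE)
    }
    return(x$intervals)
  }
  as.numeric(x)
}

#' Standard deviation of NN intervals (SDNN)
#'
#' @param x NN intervals (ms) or an [rr_series()].
#' @param divisor `"sample"` (n-1, default) or `"population"` (n).
#' @return SDNN in ms.
#' @export
sdnn <- function(x, divisor = c("sample", "population")) {
  x <- as_intervals(x)
  divisor <- match.arg(divisor)
  n <- length(x)
  if (n < 2L) stop("need at least 2 intervals", call. = FALSE)
  v <- stats::var(x)
  if (divisor == "population") v <- v * (n - 1) / n
  sqrt(v)
}

#' Short-term Poincare variability SD1
#'
#' Root mean square of the distances of Poincare points from the identity
#' line: `SD1^2 = mean(d_i^2)`.
#'
#' @inheritParams poincare_points
#' @return SD1 in ms.
#' @export
sd1 <- function(x) {
  pp <- poincare_points(x)
  sqrt(mean(pp$d^2))
}

#' Long-term Poincare variability SD2
#'
#' Root mean square of the positions of Poincare points along the identity
#' line about the centroid: `SD2^2 = mean(s_i^2)`.
#'
#' @inheritParams poincare_points
#' @return SD2 in ms.
#' @export
sd2 <- function(x) {
  pp <- poincare_points(x)
  sqrt(mean(pp$s^2))
}

#' Proportion of large successive differences (pNN30)
#'
#' Percentage of successive-interval differences strictly exceeding 30 ms in
#' absolute value. The directional split into deceleration and acceleration
#' exceedances is provided by [threshold_counts()]; the three satisfy
#' `pnn30 == pnn30dec + pnn30acc` exactly.
#'
#' @inheritParams poincare_points
#' @param threshold_ms difference threshold in ms (default 30).
#' @return Percentage in `[0, 100]`.
#' @export
pnn30 <- function(x, threshold_ms = 30) {
  x <- as_intervals(x)
  if (length(x) < 2L) stop("need at least 2 intervals", call. = FALSE)
  dx <- diff(x)
  # written as the sum of the two directional terms so the partition
  # pnn30 == pnn30dec + pnn30acc holds to the last bit
  100 * mean(dx > threshold_ms) + 100 * mean(dx < -threshold_ms)
}
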
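#' Classify successive RR differences
#'
#' Each difference `delta_i = x_{i+1} - x_i` is a deceleration (`"dec"`,
#' interval lengthens, heart slows), an acceleration (`"acc"`, interval
#' shortens) or neutral (`"neutral"`, unchanged).
#'
#' @inheritParams poincare_points
#' @return Character vector of length `n - 1` in `{"dec","acc","neutral"}`.
#' @export
classify_deltas <- function(x) {
  x <- as_intervals(x)
  if (length(x) < 2L) stop("need at least 2 intervals", call. = FALSE)
  d <- diff(x)
  out <- rep("neutral", length(d))
  out[d > 0] <- "dec"
  out[d < 0] <- "acc"
  out
}

#' Deceleration/acceleration decomposition of Poincare variance
#'
#' Splits the short-term, long-term, and total Poincare-plot variability into
#' components driven solely by decelerations or accelerations:
#' `SD1d^2 + SD1a^2 = SD1^2`, `SD2d^2 + SD2a^2 = SD2^2`, and
#' `SDNNd^2 + SDNNa^2 = (SD1^2 + SD2^2)/2`, each an exact identity.
#' Points on the identity line (no change) contribute half of their `s^2`
#' to each of the long-term components so the partitions close.
#'
#' @inheritParams poincare_points
#' @return Named list `sd1d`, `sd1a`, `sd2d`, `sd2a`, `sdnnd`, `sdnna` (ms).
#' @export
variance_decomposition <- function(x) {
  pp <- poincare_points(x)
  n <- length(pp$d)
  dec <- pp$d > 0
  acc <- pp$d < 0
  neu <- pp$d == 0
  sd1d2 <- sum(pp$d[dec]^2) / n
  sd1a2 <- sum(pp$d[acc]^2) / n
  sd2d2 <- (sum(pp$s[dec]^2) + 0.5 * sum(pp$s[neu]^2)) / n
  sd2a2 <- (sum(pp$s[acc]^2) + 0.5 * sum(pp$s[neu]^2)) / n
  list(sd1d = sqrt(sd1d2), sd1a = sqrt(sd1a2),
       sd2d = sqrt(sd2d2), sd2a = sqrt(sd2a2),
       sdnnd = sqrt((sd1d2 + sd2d2) / 2),
       sdnna = sqrt((sd1a2 + sd2a2) / 2))
}

#' Monotonic runs of the RR series
#'
#' A run is a maximal unbroken block of successive differences of one type
#' (all decelerations, all accelerations, or all neutral); its length is the
#' number of differences in the block. `DRi`/`ARi` count
#' deceleration/acceleration runs of length i; `DRMAX`/`ARMAX` are the
#' longest such runs.
#'
#' @inheritParams poincare_points
#' @return A list of class `runs_distribution`: `dr_counts`, `ar_counts`,
#'   `neutral_counts` (named integer vectors, names = run length),
#'   `dr_max`, `ar_max`, `n_deltas`.
#' @export
runs_partition <- function(x) {
  cls <- classify_deltas(x)
  r <- rle(cls)
  tab <- function(type) {
    len <- r$lengths[r$values == type]
    if (!length(len)) return(integer(0))
    tt <- table(len)
    out <- as.integer(tt)
    names(out) <- names(tt)
    out
  }
  dr <- tab("dec")
  ar <- tab("acc")
  ne <- tab("neutral")
  structure(
    list(dr_counts = dr, ar_counts = ar, neutral_counts = ne,
         dr_max = if (length(dr)) max(as.integer(names(dr))) else 0L,
         ar_max = if (length(ar)) max(as.integer(names(ar))) else 0L,
         n_deltas = length(cls)),
    class = "runs_distribution"
  )
}

#' Count runs of a given type and length
#' @param dist a [runs_partition()] result.
#' @param type `"dec"` or `"acc"`.
#' @param length run length i (e.g. 4 for DR4/AR4).
#' @return Integer count (0 when absent).
#' @export
run_count <- function(dist, type = c("dec", "acc"), length = 4L) {
  type <- match.arg(type)
  cnt <- if (type == "dec") dist$dr_counts else dist$ar_counts
  v <- cnt[as.character(length)]
  if (is.na(v)) 0L else as.integer(v)
}

#' Shannon-entropy partition of the runs distribution
#'
#' With `R` the total number of runs and `p(type, i)` the relative frequency
#' of runs of that type and length, the full Shannon entropy of the
#' run-type/length distribution splits into the deceleration component
#' `HDR = -sum_i p(dec, i) log2 p(dec, i)`, the acceleration component `HAR`
#' defined analogously, and a neutral remainder; `HDR + HAR <= H_total`.
#' Neutral runs are included in `R` by default.
#'
#' @param dist a [runs_partition()] result.
#' @param base logarithm base (default 2, bits).
#' @param include_neutral include neutral runs in the normalising total.
#' @return List `hdr`, `har`, `h_total`.
#' @export
runs_entropy <- function(dist, base = 2, include_neutral = TRUE) {
  stopifnot(inherits(dist, "runs_distribution"))
  nd <- as.numeric(dist$dr_counts)
  na_ <- as.numeric(dist$ar_counts)
  ne <- if (include_neutral) as.numeric(dist$neutral_counts) else numeric(0)
  total <- sum(nd, na_, ne)
  if (total == 0) stop("empty runs distribution", call. = FALSE)
  h <- function(cnt) {
    p <- cnt[cnt > 0] / total
    if (!length(p)) return(0)
    -sum(p * log(p, base = base))
  }
  list(hdr = h(nd), har = h(na_), h_total = h(nd) + h(na_) + h(ne))
}

#' Directional large-difference percentages (pNN30dec / pNN30acc)
#'
#' Percentage of successive differences strictly greater than +30 ms
#' (deceleration exceedances) and strictly below -30 ms (acceleration
#' exceedances); their sum is [pnn30()] exactly.
#'
#' @inheritParams pnn30
#' @return List `pnn30dec`, `pnn30acc` (percent).
#' @export
threshold_counts <- function(x, threshold_ms = 30) {
  x <- as_intervals(x)
  if (length(x) < 2L) stop("need at least 2 intervals", call. = FALSE)
  dx <- diff(x)
  list(pnn30dec = 100 * mean(dx > threshold_ms),
       pnn30acc = 100 * mean(dx < -threshold_ms))
}
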
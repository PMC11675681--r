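#' Cut a recording into consecutive 5-minute windows
#'
#' Windows are half-open `[k*window_s, (k+1)*window_s)`; an interval belongs
#' to the window containing its onset. A trailing partial window is dropped.
#' Segment indices are 0-based so that segment k spans `[k*300, (k+1)*300)`
#' seconds by construction.
#'
#' @param rr an [rr_series()].
#' @param window_s window length in seconds (default 300).
#' @return A list with one element per segment:
#'   `list(segment_index, start_s, end_s, rr)` where `rr` is the RR
#'   sub-series whose onsets fall in the window.
#' @export
make_segments <- function(rr, window_s = 300) {
  stopifnot(inherits(rr, "rr_series"))
  total_s <- rr$t_cum[length(rr$intervals)] +
    rr$intervals[length(rr$intervals)] / 1000
  n_seg <- floor(total_s / window_s)
  if (n_seg < 1L) {
    stop("recording shorter than one window (", window_s, " s)",
         call. = FALSE)
  }
  idx <- floor(rr$t_cum / window_s)
  lapply(seq_len(n_seg) - 1L, function(k) {
    sel <- which(idx == k)
    sub <- if (length(sel)) {
      rr_series(rr$intervals[sel], subject_id = rr$subject_id,
                annotations = rr$annotations[sel],
                t_start = rr$t_cum[sel[1]])
    } else {
      NULL
    }
    list(segment_index = k, start_s = k * window_s,
         end_s = (k + 1) * window_s, rr = sub)
  })
}

# Half-up rounding (round() in R rounds half to even, which would turn a
# 0.25/0.35 boundary case the wrong way for the 1-decimal stage grid).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-12) / p
}

#' Per-stage occupancy fractions of one segment
#'
#' Computes the proportion of the window `[start_s, end_s)` covered by each
#' sleep stage of the hypnogram, rounded half-up to one decimal — the grid on
#' which the certain-stage and transition rules operate.
#'
#' @param start_s,end_s segment boundaries in seconds.
#' @param hyp a [hypnogram()] covering the segment.
#' @param round if `FALSE`, return the exact (unrounded) fractions.
#' @return Named numeric vector over `sleep_stages()`.
#' @export
stage_fractions <- function(start_s, end_s, hyp, round = TRUE) {
  stopifnot(inherits(hyp, "hypnogram"), end_s > start_s)
  span_end <- hyp$end_s[nrow(hyp)]
  if (start_s < 0 || end_s > span_end + 1e-9) {
    stop("segment [", start_s, ", ", end_s, ") outside hypnogram span",
         call. = FALSE)
  }
  ov <- pmax(0, pmin(hyp$end_s, end_s) - pmax(hyp$start_s, start_s))
  fr <- vapply(sleep_stages(), function(s) sum(ov[hyp$stage == s]),
               numeric(1)) / (end_s - start_s)
  if (round) round_half_up(fr, 1) else fr
}

#' Certain-stage indicators
#'
#' A stage is "certain" in a segment when its rounded occupancy fraction is
#' at least `threshold` (default 0.7). At most one stage can be certain.
#'
#' @param fractions named fractions as from [stage_fractions()].
#' @param threshold certainty threshold on the fraction grid.
#' @return Named integer vector of 0/1 indicators over the stages.
#' @export
certain_stage <- function(fractions, threshold = 0.7) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  out <- as.integer(fractions >= threshold)
  names(out) <- names(fractions)
  out
}

#' The stage-transition pairs that are labeled
#'
#' The seven transition types carried through labeling and modeling.
#' @return A two-column character matrix (`from`, `to`).
#' @export
transition_pairs <- function() {
  m <- matrix(c("N1", "N2",
                "N2", "N3",
                "N2", "R",
                "N3", "N2",
                "N3", "R",
                "R",  "N2",
                "W",  "N1"), ncol = 2, byrow = TRUE)
  colnames(m) <- c("from", "to")
  m
}

#' Mark stage transitions across a recording's segments
#'
#' For a transition S -> E and segment t (on the rounded fraction grid), the
#' indicator is 1 when either rule fires:
#' \describe{
#'   \item{A}{both stages present: `f_S[t] > 0`, `f_E[t] > 0`,
#'     `f_E[t] <= thr`, and `f_E[t] >= f_E[t-1]` (the ending stage is not
#'     receding; `f_E[0]` is taken as 0 before the first segment);}
#'   \item{B}{boundary-aligned change: `f_S[t] > 0`, `f_E[t] == 0`, and the
#'     next segment has `0 < f_E[t+1] <= thr`.}
#' }
#'
#' @param frac a numeric matrix (segments x stages, columns named by
#'   `sleep_stages()`) of rounded stage fractions, rows in segment order, or
#'   a list of vectors from [stage_fractions()].
#' @param pairs two-column matrix of (from, to) stage pairs; defaults to
#'   [transition_pairs()].
#' @param threshold the ending-stage ceiling (default 0.6).
#' @return Integer matrix (segments x pairs), columns named
#'   `trans_<from>_<to>`.
#' @export
mark_transitions <- function(frac, pairs = transition_pairs(),
                             threshold = 0.6) {
  if (is.list(frac) && !is.data.frame(frac)) {
    frac <- do.call(rbind, frac)
  }
  frac <- as.matrix(frac)
  if (!all(sleep_stages() %in% colnames(frac))) {
    stop("fraction matrix must have columns ", paste(sleep_stages(),
         collapse = ", "), call. = FALSE)
  }
  pairs <- as.matrix(pairs)
  bad <- !(pairs[, 1] %in% sleep_stages() & pairs[, 2] %in% sleep_stages())
  if (any(bad)) {
    stop("unknown transition pair: ", paste(pairs[bad, ][1:2], collapse = "-"),
         call. = FALSE)
  }
  tt <- nrow(frac)
  out <- matrix(0L, tt, nrow(pairs),
                dimnames = list(NULL, paste0("trans_", pairs[, 1], "_",
                                             pairs[, 2])))
  for (p in seq_len(nrow(pairs))) {
    fs <- frac[, pairs[p, 1]]
    fe <- frac[, pairs[p, 2]]
    fe_prev <- c(0, fe[-tt])
    rule_a <- fs > 0 & fe > 0 & fe <= threshold & fe >= fe_prev
    rule_b <- rep(FALSE, tt)
    if (tt > 1L) {
      fe_next <- c(fe[-1], 0)
      rule_b <- fs > 0 & fe == 0 & fe_next > 0 & fe_next <= threshold
      rule_b[tt] <- FALSE
    }
    out[, p] <- as.integer(rule_a | rule_b)
  }
  out
}
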
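#' Construct an RR-interval series
#'
#' An `rr_series` holds one subject's beat-to-beat (RR) intervals in
#' milliseconds, a per-beat annotation (`"normal"` or `"artifact"`), and the
#' cumulative onset time of each interval in seconds (`t_cum[1] == t_start`).
#' Intervals outside the physiologic validity window (200, 3000) ms are kept
#' but auto-flagged as artifacts; intervals must be positive and below 5000 ms.
#'
#' @param intervals numeric vector of RR intervals in milliseconds.
#' @param subject_id character scalar identifying the subject (cluster).
#' @param annotations optional character vector (`"normal"`/`"artifact"`),
#'   recycled defaults to `"normal"`. Flags are combined with the automatic
#'   physiologic-window flagging (an interval marked artifact stays artifact).
#' @param t_start onset time (s) of the first interval; non-zero for
#'   sub-series produced by splitting.
#' @return An object of class `rr_series` with fields `subject_id`,
#'   `intervals`, `annotations`, `t_cum`.
#' @examples
#' rr <- rr_series(c(800, 810, 790))
#' rr$t_cum  # 0.00 0.80 1.61
#' @export
rr_series <- function(intervals, subject_id = "S1", annotations = NULL,
                      t_start = 0) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) {
    stop("empty RR series", call. = FALSE)
  }
  if (anyNA(intervals)) {
    stop("RR intervals contain missing values", call. = FALSE)
  }
  if (any(intervals <= 0) || any(intervals >= 5000)) {
    stop("RR intervals must lie in (0, 5000) ms", call. = FALSE)
  }
  if (is.null(annotations)) {
    annotations <- rep("normal", length(intervals))
  }
  annotations <- as.character(annotations)
  if (length(annotations) != length(intervals)) {
    stop("annotations and intervals differ in length", call. = FALSE)
  }
  bad <- !annotations %in% c("normal", "artifact")
  if (any(bad)) {
    stop("unknown annotation: ", annotations[bad][1], call. = FALSE)
  }
  annotations[intervals <= 200 | intervals >= 3000] <- "artifact"
  n <- length(intervals)
  t_cum <- t_start + cumsum(c(0, intervals[-n])) / 1000
  structure(
    list(subject_id = as.character(subject_id), intervals = intervals,
         annotations = annotations, t_cum = t_cum),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> subject %s: %d beats, %.1f min, %d artifact(s)\n",
              x$subject_id, length(x$intervals),
              sum(x$intervals) / 60000, sum(x$annotations == "artifact")))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Read an RR-interval file
#'
#' Two dialects are supported: a bare one-column list of intervals in ms, and
#' a two-column CSV `interval_ms,annotation` with a header line. The dialect
#' is sniffed from the first line unless given explicitly.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"one-column"` or `"two-column"`.
#' @param subject_id subject identifier attached to the series; defaults to
#'   the file name without extension.
#' @return An [rr_series()].
#' @export
read_rr <- function(path, dialect = c("auto", "one-column", "two-column"),
                    subject_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty RR file: ", path, call. = FALSE)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (dialect == "auto") {
    dialect <- if (grepl(",", lines[1])) "two-column" else "one-column"
  }
  if (dialect == "one-column") {
    vals <- suppressWarnings(as.numeric(lines))
    if (anyNA(vals)) {
      stop("unparsable RR value at line ", which(is.na(vals))[1],
           call. = FALSE)
    }
    return(rr_series(vals, subject_id = subject_id))
  }
  # two-column CSV with header
  body <- lines[-1]
  if (length(body) == 0L) stop("empty RR file: ", path, call. = FALSE)
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed CSV row at line ", which(lengths(parts) != 2L)[1] + 1L,
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  if (anyNA(vals)) {
    stop("unparsable RR value at line ", which(is.na(vals))[1] + 1L,
         call. = FALSE)
  }
  ann <- trimws(vapply(parts, `[`, "", 2L))
  rr_series(vals, subject_id = subject_id, annotations = ann)
}

#' Write an RR-interval file
#'
#' @param rr an [rr_series()].
#' @param path output file path.
#' @param dialect `"one-column"` (annotations lost if any are artifacts) or
#'   `"two-column"` (lossless).
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path, dialect = c("two-column", "one-column")) {
  stopifnot(inherits(rr, "rr_series"))
  dialect <- match.arg(dialect)
  vals <- vapply(rr$intervals, function(v) {
    s <- formatC(v, digits = 15, format = "g")   # try short, stay lossless
    if (as.numeric(s) != v) s <- formatC(v, digits = 17, format = "g")
    s
  }, "")
  if (dialect == "one-column") {
    writeLines(vals, path)
  } else {
    writeLines(c("interval_ms,annotation",
                 paste(vals, rr$annotations, sep = ",")), path)
  }
  invisible(path)
}

#' Construct a hypnogram
#'
#' Ordered, contiguous sleep-stage bouts over a recording. Stages follow the
#' AASM vocabulary: W (wake), N1, N2, N3 (non-REM) and R (REM).
#'
#' @param stage character vector of stage labels.
#' @param start_s,end_s bout boundaries in seconds; bouts must start at 0 and
#'   be contiguous (`end_s[k] == start_s[k+1]`) with no gaps or overlaps.
#' @param subject_id subject identifier.
#' @return An object of class `hypnogram`: a data frame with columns `stage`,
#'   `start_s`, `end_s` and attribute `subject_id`.
#' @export
hypnogram <- function(stage, start_s, end_s, subject_id = "S1") {
  stage <- as.character(stage)
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  if (length(stage) == 0L) stop("empty hypnogram", call. = FALSE)
  bad <- !stage %in% sleep_stages()
  if (any(bad)) {
    stop("unknown sleep stage label: ", stage[bad][1], call. = FALSE)
  }
  if (length(stage) != length(start_s) || length(stage) != length(end_s)) {
    stop("stage/start_s/end_s lengths differ", call. = FALSE)
  }
  if (start_s[1] != 0) stop("hypnogram must start at 0 s", call. = FALSE)
  if (any(end_s <= start_s)) stop("bout with non-positive length", call. = FALSE)
  if (length(stage) > 1L &&
      any(abs(end_s[-length(end_s)] - start_s[-1]) > 1e-9)) {
    stop("hypnogram bouts must be contiguous (gap or overlap found)",
         call. = FALSE)
  }
  structure(
    data.frame(stage = stage, start_s = start_s, end_s = end_s,
               stringsAsFactors = FALSE),
    subject_id = as.character(subject_id),
    class = c("hypnogram", "data.frame")
  )
}

#' The five sleep stage labels
#' @return `c("W", "N1", "N2", "N3", "R")`
#' @export
sleep_stages <- function() c("W", "N1", "N2", "N3", "R")

#' Read a hypnogram CSV
#'
#' Expects a header line and rows `stage,start_s,end_s`.
#'
#' @param path file path.
#' @param subject_id subject identifier; defaults to the file name.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stage", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    stop("hypnogram file must have columns stage,start_s,end_s", call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  hypnogram(df$stage, df$start_s, df$end_s, subject_id = subject_id)
}

#' Write a hypnogram CSV
#' @param hyp a [hypnogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  utils::write.csv(as.data.frame(hyp)[c("stage", "start_s", "end_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove or isolate artifact beats
#'
#' Descriptors in this package are defined on normal-to-normal (sinus)
#' intervals only. Two policies are offered for beats flagged as artifacts:
#' `"drop"` removes them and concatenates the remaining intervals onto a
#' compressed time axis, while `"split"` (the default elsewhere in the
#' pipeline) breaks the series at every artifact so that no successive-beat
#' pair, run, or Poincare pair ever spans an edited beat.
#'
#' @param rr an [rr_series()].
#' @param policy `"split"` or `"drop"`.
#' @return For `"drop"`, a single `rr_series`; for `"split"`, a list of
#'   `rr_series` (possibly of length one), each retaining absolute onset
#'   times.
#' @export
mask_artifacts <- function(rr, policy = c("split", "drop")) {
  stopifnot(inherits(rr, "rr_series"))
  policy <- match.arg(policy)
  ok <- rr$annotations == "normal"
  if (!any(ok)) stop("all beats are artifacts", call. = FALSE)
  if (policy == "drop") {
    return(rr_series(rr$intervals[ok], subject_id = rr$subject_id))
  }
  if (all(ok)) return(list(rr))
  grp <- cumsum(!ok)           # runs of normal beats between artifacts
  keep <- split(which(ok), grp[ok])
  out <- lapply(keep, function(idx) {
    rr_series(rr$intervals[idx], subject_id = rr$subject_id,
              t_start = rr$t_cum[idx[1]])
  })
  names(out) <- NULL
  out
}
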
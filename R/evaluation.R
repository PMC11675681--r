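#' Confusion matrix at a probability threshold
#'
#' Predicts positive when `prob >= threshold` (ties predict positive).
#'
#' @param labels binary 0/1 vector of true classes.
#' @param probs predicted probabilities, same length.
#' @param threshold decision threshold (default 0.5).
#' @return An object of class `confusion_matrix`: list `tn`, `fp`, `fn`,
#'   `tp`.
#' @export
confusion <- function(labels, probs, threshold = 0.5) {
  if (length(labels) != length(probs)) {
    stop("labels and probs differ in length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  pred <- as.integer(probs >= threshold)
  confusion_matrix(tn = sum(labels == 0 & pred == 0),
                   fp = sum(labels == 0 & pred == 1),
                   fn = sum(labels == 1 & pred == 0),
                   tp = sum(labels == 1 & pred == 1))
}

#' Build a confusion matrix from counts
#' @param tn,fp,fn,tp non-negative counts.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be non-negative with positive total", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(actual = c("negative", "positive"),
                              predicted = c("negative", "positive")))
  print(m)
  invisible(x)
}

#' Threshold classification metrics from a confusion matrix
#'
#' Accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`, recall `tp/(tp+fn)` and
#' the F1 score (harmonic mean of precision and recall). Undefined ratios
#' (zero denominators) are reported as `NA`, never coerced to 0.
#'
#' @param cm a [confusion_matrix()].
#' @param digits if non-`NULL`, round half-up to this many decimals (reports
#'   use 2).
#' @return Named list `accuracy`, `precision`, `recall`, `f1`.
#' @export
cm_metrics <- function(cm, digits = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  acc <- (cm$tp + cm$tn) / total
  prec <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_
  rec <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else {
    NA_real_
  }
  out <- list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
  if (!is.null(digits)) out <- lapply(out, round_half_up, digits = digits)
  out
}

#' Area under the ROC curve (rank estimator)
#'
#' The Mann-Whitney form: the probability that a random positive scores
#' above a random negative, with ties counting one half. Exactly equals the
#' brute-force count over all positive/negative pairs.
#'
#' @param labels binary 0/1 vector.
#' @param probs scores (any monotone scale).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, probs) {
  if (length(labels) != length(probs)) {
    stop("labels and probs differ in length", call. = FALSE)
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Segment-label distribution bookkeeping
#'
#' Counts how many segments carry each binary label (certain stage or
#' transition) and expresses each count as a percentage of all labeled
#' segment instances (the sum of the counts), rounded half-up to two
#' decimals — the layout of a cohort-description table. Accepts either a
#' labeled segment table or a pre-tabulated named count vector.
#'
#' @param x a segment table (data frame with `certain_*`/`trans_*` columns)
#'   or a named numeric vector of counts.
#' @param label_cols for the data-frame method, the label columns to count
#'   (default: all `certain_*` and `trans_*` columns).
#' @return Data frame with columns `label`, `count`, `percent`.
#' @export
stage_distribution <- function(x, label_cols = NULL) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) stop("empty table", call. = FALSE)
    if (is.null(label_cols)) {
      label_cols <- grep("^(certain|trans)_", names(x), value = TRUE)
    }
    counts <- vapply(label_cols, function(cn) sum(x[[cn]] == 1), numeric(1))
  } else {
    counts <- x
    if (is.null(names(counts))) stop("counts must be named", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("no labeled segments", call. = FALSE)
  data.frame(label = names(counts), count = as.numeric(counts),
             percent = round_half_up(100 * as.numeric(counts) / total, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluate a fitted one-vs-all model on a segment table
#'
#' @param fit a `gee_fit`.
#' @param table segment table holding the response column and covariates.
#' @param threshold decision threshold for the hard labels.
#' @return List with the `confusion_matrix`, `auc`, and the [cm_metrics()].
#' @export
evaluate_model <- function(fit, table, threshold = 0.5) {
  keep <- stats::complete.cases(table[c(fit$response, fit$covariates)])
  tab <- table[keep, , drop = FALSE]
  probs <- stats::predict(fit, tab)
  labels <- tab[[fit$response]]
  cm <- confusion(labels, probs, threshold)
  list(confusion = cm,
       auc = auc(labels, probs),
       metrics = cm_metrics(cm),
       n = length(labels))
}
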
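#' Feature names produced per segment
#'
#' The covariate vocabulary of the one-vs-all models: the symmetric HRV and
#' complexity descriptors (SDNN, SD1, SampEn, LF_HF, pnn30; SD2 is exported
#' too although the models do not use it) and the asymmetric descriptors
#' (SD1a, SD1d, pnn30dec, pnn30acc, AR4, DR4, ARMAX, DRMAX, HDR, HAR).
#' @return Character vector of column names.
#' @export
feature_names <- function() {
  c("SDNN", "SD1", "SD2", "SampEn", "LF_HF", "pnn30",
    "SD1a", "SD1d", "pnn30dec", "pnn30acc",
    "AR4", "DR4", "ARMAX", "DRMAX", "HDR", "HAR")
}

# Feature block for one artifact-free 5-min window, combining split
# sub-series so that no pairwise quantity spans an edited beat.
segment_feature_row <- function(parts, sampen_m, sampen_r, spectral_rr,
                                min_beats) {
  out <- stats::setNames(as.list(rep(NA_real_, length(feature_names()))),
                         feature_names())
  all_int <- unlist(lapply(parts, function(p) p$intervals))
  n <- length(all_int)
  if (n < min_beats) return(out)
  out$SDNN <- sdnn(all_int)

  # pool Poincare coordinates and deltas over the clean parts
  pp_parts <- lapply(parts, function(p) {
    if (length(p$intervals) >= 3L) poincare_points(p$intervals) else NULL
  })
  pp_parts <- pp_parts[!vapply(pp_parts, is.null, logical(1))]
  if (length(pp_parts)) {
    d <- unlist(lapply(pp_parts, `[[`, "d"))
    s <- unlist(lapply(pp_parts, `[[`, "s"))
    np <- length(d)
    out$SD1 <- sqrt(mean(d^2))
    out$SD2 <- sqrt(mean(s^2))
    out$SD1d <- sqrt(sum(d[d > 0]^2) / np)
    out$SD1a <- sqrt(sum(d[d < 0]^2) / np)
  }
  deltas <- unlist(lapply(parts, function(p) {
    if (length(p$intervals) >= 2L) diff(p$intervals) else numeric(0)
  }))
  if (length(deltas)) {
    out$pnn30dec <- 100 * mean(deltas > 30)
    out$pnn30acc <- 100 * mean(deltas < -30)
    out$pnn30 <- out$pnn30dec + out$pnn30acc
  }

  # runs: count within parts, merge the distributions
  dists <- lapply(parts, function(p) {
    if (length(p$intervals) >= 2L) runs_partition(p$intervals) else NULL
  })
  dists <- dists[!vapply(dists, is.null, logical(1))]
  if (length(dists)) {
    merged <- merge_runs(dists)
    out$DR4 <- run_count(merged, "dec", 4L)
    out$AR4 <- run_count(merged, "acc", 4L)
    out$DRMAX <- merged$dr_max
    out$ARMAX <- merged$ar_max
    ent <- runs_entropy(merged)
    out$HDR <- ent$hdr
    out$HAR <- ent$har
  }

  # sample entropy on the longest clean part
  longest <- parts[[which.max(vapply(parts, length, integer(1)))]]
  if (length(longest$intervals) >= sampen_m + 2L) {
    out$SampEn <- sampen(longest$intervals, m = sampen_m, r = sampen_r)
  }

  out$LF_HF <- tryCatch(band_powers(spectral_rr)$lf_hf,
                        error = function(e) NA_real_)
  out
}

merge_runs <- function(dists) {
  add <- function(a, b) {
    keys <- union(names(a), names(b))
    out <- stats::setNames(integer(length(keys)), keys)
    out[names(a)] <- out[names(a)] + a
    out[names(b)] <- out[names(b)] + b
    out
  }
  acc <- dists[[1]]
  for (d in dists[-1]) {
    acc$dr_counts <- add(acc$dr_counts, d$dr_counts)
    acc$ar_counts <- add(acc$ar_counts, d$ar_counts)
    acc$neutral_counts <- add(acc$neutral_counts, d$neutral_counts)
    acc$n_deltas <- acc$n_deltas + d$n_deltas
  }
  acc$dr_max <- if (length(acc$dr_counts)) {
    max(as.integer(names(acc$dr_counts)))
  } else 0L
  acc$ar_max <- if (length(acc$ar_counts)) {
    max(as.integer(names(acc$ar_counts)))
  } else 0L
  acc
}

#' Per-segment features and labels for one subject
#'
#' Cuts the recording into 5-min windows, computes every descriptor of
#' [feature_names()] per window (splitting at artifact beats so no pairwise
#' quantity bridges an edited beat), attaches the rounded stage fractions,
#' the certain-stage indicators, and the transition indicators.
#'
#' @param rr an [rr_series()].
#' @param hyp the subject's [hypnogram()].
#' @param window_s window length in seconds (default 300).
#' @param sampen_m,sampen_r sample-entropy parameters (template length;
#'   tolerance as a fraction of the segment SD).
#' @param certain_threshold,transition_threshold labeling thresholds
#'   (defaults 0.7 and 0.6).
#' @param min_beats minimum beats for a window's features (default 30;
#'   windows below it get `NA` features but keep their labels).
#' @return A `data.frame` (the subject's slice of the segment table).
#' @export
segment_table <- function(rr, hyp, window_s = 300, sampen_m = 2,
                          sampen_r = 0.2, certain_threshold = 0.7,
                          transition_threshold = 0.6, min_beats = 30) {
  stopifnot(inherits(rr, "rr_series"), inherits(hyp, "hypnogram"))
  segs <- make_segments(rr, window_s = window_s)
  hyp_end <- hyp$end_s[nrow(hyp)]
  segs <- Filter(function(s) s$end_s <= hyp_end + 1e-9, segs)
  if (!length(segs)) stop("no segment covered by the hypnogram", call. = FALSE)

  feat <- lapply(segs, function(s) {
    if (is.null(s$rr) || length(s$rr$intervals) < 2L) {
      return(stats::setNames(as.list(rep(NA_real_,
             length(feature_names()))), feature_names()))
    }
    parts <- mask_artifacts(s$rr, policy = "split")
    segment_feature_row(parts, sampen_m, sampen_r, s$rr,
                        min_beats = min_beats)
  })
  feat <- do.call(rbind, lapply(feat, function(f) as.data.frame(f)))

  frac <- t(vapply(segs, function(s) {
    stage_fractions(s$start_s, s$end_s, hyp)
  }, numeric(5)))
  colnames(frac) <- paste0("frac_", sleep_stages())
  cert <- t(apply(frac, 1, certain_stage, threshold = certain_threshold))
  colnames(cert) <- paste0("certain_", sleep_stages())
  raw <- frac
  colnames(raw) <- sleep_stages()
  trans <- mark_transitions(raw, threshold = transition_threshold)

  cbind(
    data.frame(subject_id = rr$subject_id,
               segment_index = vapply(segs, `[[`, numeric(1),
                                      "segment_index")),
    feat, as.data.frame(frac), as.data.frame(cert), as.data.frame(trans)
  )
}

#' Segment table for a whole cohort
#'
#' @param cohort list of `list(rr, hyp)` pairs (as from
#'   [generate_cohort()] or assembled from [read_rr()]/[read_hypnogram()]).
#' @param ... passed to [segment_table()].
#' @return Row-bound segment table over all subjects.
#' @export
cohort_segment_table <- function(cohort, ...) {
  do.call(rbind, lapply(cohort, function(s) {
    segment_table(s$rr, s$hyp, ...)
  }))
}

#' All one-vs-all response columns
#' @return Character vector: 5 certain-stage and 7 transition label columns.
#' @export
response_names <- function() {
  pairs <- transition_pairs()
  c(paste0("certain_", sleep_stages()),
    paste0("trans_", pairs[, 1], "_", pairs[, 2]))
}

#' End-to-end pipeline run on a cohort
#'
#' Features and labels, stratified subject split, one-vs-all GEE models with
#' backward selection for every requested response, prediction on the
#' held-out subjects, and confusion-matrix/AUC evaluation. Responses whose
#' training or test slice lacks both classes (or has fewer positives than
#' `min_positives`) are skipped and recorded in the manifest.
#'
#' @param cohort list of `list(rr, hyp)` pairs.
#' @param responses label columns to model (default [response_names()]).
#' @param covariates model covariates (default: the full descriptor
#'   vocabulary minus SD2).
#' @param corstr working correlation (default `"exchangeable"`).
#' @param criterion backward-selection criterion (`"aic"` or `"qic"`).
#' @param train_frac,n_strata,seed split parameters (see
#'   [stratified_subject_split()]).
#' @param threshold decision threshold for hard labels.
#' @param min_positives minimum positive segments required in each of the
#'   train and test slices (default 10).
#' @param select run backward selection (`TRUE`) or fit the full model.
#' @param ... passed to [segment_table()].
#' @return List of class `hra_pipeline`: `segment_table`, `split`, `models`
#'   (named list of `gee_fit`), `evaluation` (named list from
#'   [evaluate_model()]), `skipped` (named character of reasons), `manifest`.
#' @export
run_pipeline <- function(cohort,
                         responses = response_names(),
                         covariates = setdiff(feature_names(), "SD2"),
                         corstr = "exchangeable", criterion = "aic",
                         train_frac = 0.7, n_strata = 4, seed = 1,
                         threshold = 0.5, min_positives = 10,
                         select = TRUE, ...) {
  tab <- cohort_segment_table(cohort, ...)
  split <- stratified_subject_split(tab, train_frac = train_frac,
                                    n_strata = n_strata, seed = seed)
  train <- tab[tab$subject_id %in% split$train_subjects, , drop = FALSE]
  test <- tab[tab$subject_id %in% split$test_subjects, , drop = FALSE]

  models <- list()
  evaluation <- list()
  skipped <- character(0)
  for (resp in responses) {
    n_pos_tr <- sum(train[[resp]] == 1, na.rm = TRUE)
    n_pos_te <- sum(test[[resp]] == 1, na.rm = TRUE)
    if (n_pos_tr < min_positives || n_pos_tr == nrow(train)) {
      skipped[resp] <- sprintf("train has %d positives", n_pos_tr)
      next
    }
    fit <- tryCatch({
      if (select) {
        backward_select(train, resp, covariates, "subject_id",
                        corstr = corstr, criterion = criterion)
      } else {
        fit_gee(train, resp, covariates, "subject_id", corstr = corstr)
      }
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      skipped[resp] <- conditionMessage(fit)
      next
    }
    models[[resp]] <- fit
    if (n_pos_te >= min_positives && n_pos_te < nrow(test)) {
      evaluation[[resp]] <- evaluate_model(fit, test, threshold = threshold)
    } else {
      # mirror the fallback used when the held-out slice is too sparse:
      # evaluate on the training subjects and flag it
      ev <- evaluate_model(fit, train, threshold = threshold)
      ev$on_training_set <- TRUE
      evaluation[[resp]] <- ev
    }
  }
  manifest <- list(
    n_subjects = length(unique(tab$subject_id)),
    n_segments = nrow(tab),
    train_subjects = split$train_subjects,
    test_subjects = split$test_subjects,
    achieved_train_fraction = split$achieved_train_fraction,
    corstr = corstr, criterion = criterion, seed = seed,
    responses_fit = names(models), responses_skipped = skipped
  )
  structure(list(segment_table = tab, split = split, models = models,
                 evaluation = evaluation, skipped = skipped,
                 manifest = manifest),
            class = "hra_pipeline")
}

#' @export
print.hra_pipeline <- function(x, ...) {
  cat(sprintf("<hra_pipeline> %d subjects, %d segments; %d model(s) fit, %d skipped\n",
              x$manifest$n_subjects, x$manifest$n_segments,
              length(x$models), length(x$skipped)))
  for (resp in names(x$evaluation)) {
    ev <- x$evaluation[[resp]]
    m <- cm_metrics(ev$confusion, digits = 2)
    cat(sprintf("  %-16s AUC %.2f acc %.2f prec %.2f rec %.2f F1 %.2f%s\n",
                resp, ev$auc, m$accuracy, m$precision, m$recall, m$f1,
                if (isTRUE(ev$on_training_set)) " (training set)" else ""))
  }
  invisible(x)
}
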
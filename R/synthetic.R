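#' Stage-conditioned RR dynamics for the synthetic cohort
#'
#' One row per sleep stage, giving the parameters of the beat-by-beat RR
#' generator while that stage is active:
#' \describe{
#'   \item{mean_rr}{mean RR interval (ms);}
#'   \item{sd_scale}{total noise scale (ms), split between a white component
#'     and an AR(1) component;}
#'   \item{lf_amp, hf_amp}{amplitudes (ms) of sinusoidal oscillators at
#'     0.10 Hz (Mayer-wave / LF band) and 0.25 Hz (respiratory / HF band);}
#'   \item{ar1_rho}{lag-1 autocorrelation of the coloured noise;}
#'   \item{asym_skew}{per-beat probability of a deceleration event: one
#'     abrupt RR lengthening followed by a gradual multi-beat recovery ramp,
#'     producing the longer and more numerous acceleration runs seen in real
#'     heart rate asymmetry;}
#'   \item{complexity_noise}{share (0..1) of the noise variance that is
#'     white; higher values raise sample entropy.}
#' }
#'
#' Defaults follow the qualitative physiology of sleep: slower heart rate
#' and HF (vagal) dominance in deep NREM, raised LF/HF and variability in
#' REM and wake.
#'
#' @param ... named per-stage overrides, e.g.
#'   `N2 = list(lf_amp = 30, hf_amp = 6)`.
#' @return Data frame with row names `W, N1, N2, N3, R`.
#' @export
stage_dynamics <- function(...) {
  dyn <- data.frame(
    mean_rr = c(W = 850, N1 = 950, N2 = 1000, N3 = 1050, R = 920),
    sd_scale = c(40, 30, 25, 18, 45),
    lf_amp = c(20, 15, 12, 6, 28),
    hf_amp = c(8, 12, 15, 18, 8),
    ar1_rho = c(0.85, 0.80, 0.80, 0.75, 0.90),
    asym_skew = c(0.020, 0.020, 0.030, 0.020, 0.040),
    complexity_noise = c(0.70, 0.35, 0.45, 0.35, 0.60)
  )
  over <- list(...)
  for (st in names(over)) {
    if (!st %in% rownames(dyn)) stop("unknown stage: ", st, call. = FALSE)
    for (f in names(over[[st]])) {
      if (!f %in% names(dyn)) stop("unknown dynamics field: ", f,
                                   call. = FALSE)
      dyn[st, f] <- over[[st]][[f]]
    }
  }
  stopifnot(all(dyn$mean_rr >= 600 & dyn$mean_rr <= 1400),
            all(dyn$lf_amp >= 0), all(dyn$hf_amp >= 0),
            all(dyn$ar1_rho >= 0 & dyn$ar1_rho < 1),
            all(dyn$asym_skew >= 0 & dyn$asym_skew <= 1))
  dyn
}

#' Cohort-level configuration for the synthetic generator
#'
#' @param n_subjects number of subjects (default 31).
#' @param recording_hours recording length per subject (default 8).
#' @param epoch_s scoring epoch for the stage Markov chain (default 30 s).
#' @param occupancy named stage-occupancy targets summing to 1. The default
#'   puts N2 near one quarter of the night with generous wake, matching a
#'   sleep-clinic population rather than healthy sleepers.
#' @param persistence probability of staying in the current stage at each
#'   epoch; with the default transition construction the occupancy targets
#'   are the exact stationary law for any persistence.
#' @param transition optional explicit stage transition matrix (rows sum
#'   to 1); overrides the default construction
#'   `P = persistence * I + (1 - persistence) * occupancy`.
#' @param subject_jitter list of between-subject random-effect scales:
#'   `mean_rr_sd` (ms, additive normal on the stage means) and `amp_cv`
#'   (lognormal CV multiplying sd_scale/lf_amp/hf_amp per subject). Set both
#'   to 0 for an exchangeable-alpha-free cohort.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 31, recording_hours = 8, epoch_s = 30,
                          occupancy = c(W = 0.29, N1 = 0.12, N2 = 0.27,
                                        N3 = 0.14, R = 0.18),
                          persistence = 0.88, transition = NULL,
                          subject_jitter = list(mean_rr_sd = 40,
                                                amp_cv = 0.20)) {
  stopifnot(n_subjects >= 1, recording_hours > 0, epoch_s > 0)
  occupancy <- occupancy[sleep_stages()]
  if (anyNA(occupancy) || abs(sum(occupancy) - 1) > 1e-8) {
    stop("occupancy must name all five stages and sum to 1", call. = FALSE)
  }
  if (is.null(transition)) {
    transition <- persistence * diag(5) +
      (1 - persistence) * matrix(occupancy, 5, 5, byrow = TRUE)
    dimnames(transition) <- list(sleep_stages(), sleep_stages())
  } else {
    transition <- as.matrix(transition)
    if (any(abs(rowSums(transition) - 1) > 1e-8) || any(transition < 0)) {
      stop("transition matrix rows must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  structure(list(n_subjects = n_subjects, recording_hours = recording_hours,
                 epoch_s = epoch_s, occupancy = occupancy,
                 transition = transition, subject_jitter = subject_jitter),
            class = "cohort_config")
}

#' Simulate a night's hypnogram
#'
#' First-order Markov chain over the five stages on the scoring-epoch grid,
#' started from the occupancy target law and merged into bouts.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer seed.
#' @param subject_id subject identifier for the hypnogram.
#' @return A [hypnogram()].
#' @export
generate_hypnogram <- function(cfg, seed = 1, subject_id = "S1") {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  n_ep <- ceiling(cfg$recording_hours * 3600 / cfg$epoch_s)
  stages <- sleep_stages()
  P <- cfg$transition[stages, stages]
  s <- character(n_ep)
  s[1] <- sample(stages, 1, prob = cfg$occupancy)
  for (k in seq_len(n_ep - 1L)) {
    s[k + 1L] <- sample(stages, 1, prob = P[s[k], ])
  }
  r <- rle(s)
  ends <- cumsum(r$lengths) * cfg$epoch_s
  starts <- c(0, ends[-length(ends)])
  hypnogram(r$values, starts, ends, subject_id = subject_id)
}

#' Simulate a stage-conditioned RR series under a hypnogram
#'
#' Beat-by-beat generator: at each beat the active stage sets the mean RR,
#' the two sinusoidal oscillators (0.10 and 0.25 Hz, random phases), the
#' AR(1)-plus-white noise mixture, and the deceleration-event process (an
#' abrupt lengthening followed by a geometric recovery ramp, the source of
#' run asymmetry). Time advances by the generated interval; intervals are
#' clamped to (250, 2800) ms so every series passes validation.
#'
#' @param hyp a [hypnogram()].
#' @param dyn a [stage_dynamics()] table.
#' @param seed integer seed.
#' @param phases optional length-2 oscillator phases (radians); random by
#'   default.
#' @return An [rr_series()] spanning the hypnogram.
#' @export
generate_rr <- function(hyp, dyn, seed = 1, phases = NULL) {
  stopifnot(inherits(hyp, "hypnogram"))
  dyn <- dyn[sleep_stages(), ]          # row order must match stage codes
  set.seed(seed)
  if (is.null(phases)) phases <- stats::runif(2, 0, 2 * pi)
  end_s <- hyp$end_s[nrow(hyp)]
  # stage lookup on a 1-s grid: cheap and exact for epoch-aligned bouts
  grid_stage <- rep(match(hyp$stage, sleep_stages()),
                    times = round(hyp$end_s - hyp$start_s))
  n_grid <- length(grid_stage)
  # plain numeric vectors indexed by stage: fast inside the beat loop
  mean_rr <- dyn$mean_rr
  sd_w <- dyn$sd_scale * sqrt(dyn$complexity_noise)
  sd_a <- dyn$sd_scale * sqrt(1 - dyn$complexity_noise)
  rho <- dyn$ar1_rho
  rho_c <- sqrt(1 - rho^2)
  lf_amp <- dyn$lf_amp
  hf_amp <- dyn$hf_amp
  skew <- dyn$asym_skew
  jump <- dyn$sd_scale
  n_max <- ceiling(end_s / (min(mean_rr) / 1000) * 1.3) + 16L
  rr <- numeric(n_max)
  t <- 0
  i <- 0L
  ar <- 0
  event <- 0
  while (t < end_s) {
    i <- i + 1L
    st <- grid_stage[min(n_grid, floor(t) + 1)]
    ar <- rho[st] * ar + rho_c[st] * stats::rnorm(1, 0, sd_a[st])
    if (event <= 1 && stats::runif(1) < skew[st]) {
      event <- stats::rnorm(1, 5, 1) * jump[st]     # abrupt lengthening
    }
    x <- mean_rr[st] + ar + stats::rnorm(1, 0, sd_w[st]) +
      lf_amp[st] * sin(2 * pi * 0.10 * t + phases[1]) +
      hf_amp[st] * sin(2 * pi * 0.25 * t + phases[2]) +
      event
    event <- event * 0.72                           # gradual recovery ramp
    x <- min(max(x, 250), 2800)
    rr[i] <- x
    t <- t + x / 1000
  }
  rr_series(rr[seq_len(i)], subject_id = attr(hyp, "subject_id"))
}

#' Simulate a full cohort with subject-level random effects
#'
#' Generates `n_subjects` independent (hypnogram, RR series) pairs. Each
#' subject perturbs the stage dynamics — an additive normal shift of all
#' stage mean RRs and lognormal multipliers on the noise/oscillator
#' amplitudes — which induces the within-subject (cluster) correlation that
#' the GEE working correlation is meant to absorb.
#'
#' @param cfg a [cohort_config()].
#' @param dyn a [stage_dynamics()] table.
#' @param seed master integer seed; every subject's draws derive from it.
#' @return List of `n_subjects` elements `list(rr, hyp)`.
#' @export
generate_cohort <- function(cfg, dyn = stage_dynamics(), seed = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  jit <- cfg$subject_jitter
  out <- vector("list", cfg$n_subjects)
  for (k in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", k)
    sseed <- seed * 1000L + k
    set.seed(sseed)
    dk <- dyn
    dk$mean_rr <- pmin(1400, pmax(600,
      dk$mean_rr + stats::rnorm(1, 0, jit$mean_rr_sd)))
    if (jit$amp_cv > 0) {
      mult <- stats::rlnorm(3, -jit$amp_cv^2 / 2, jit$amp_cv)
      dk$sd_scale <- dk$sd_scale * mult[1]
      dk$lf_amp <- dk$lf_amp * mult[2]
      dk$hf_amp <- dk$hf_amp * mult[3]
    }
    hyp <- generate_hypnogram(cfg, seed = sseed + 1L, subject_id = sid)
    rr <- generate_rr(hyp, dk, seed = sseed + 2L)
    out[[k]] <- list(rr = rr, hyp = hyp)
  }
  out
}

#' Write a synthetic cohort to disk in the package text formats
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; writes `<subject>_rr.csv` and
#'   `<subject>_hypnogram.csv` per subject.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (subj in cohort) {
    sid <- subj$rr$subject_id
    write_rr(subj$rr, file.path(dir, paste0(sid, "_rr.csv")))
    write_hypnogram(subj$hyp, file.path(dir, paste0(sid, "_hypnogram.csv")))
  }
  invisible(dir)
}
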
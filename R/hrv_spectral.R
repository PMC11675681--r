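#' LF and HF band powers of an RR tachogram
#'
#' Estimates the power spectral density of the RR-interval tachogram over a
#' segment and integrates it over the low-frequency (0.04–0.15 Hz) and
#' high-frequency (0.15–0.4 Hz) bands; the sympathovagal balance index is
#' their ratio LF/HF.
#'
#' The default estimator resamples the irregularly sampled tachogram
#' (value = interval in ms at its onset time) to an even grid by cubic-spline
#' interpolation, removes the mean, and applies a Welch-style averaged
#' periodogram: Hann-tapered windows of `welch_window_s` seconds with 50%
#' overlap, one-sided PSD normalised so that its integral equals the signal
#' variance (Parseval). Band powers are trapezoidal integrals over half-open
#' bands `[low, high)` so that 0.15 Hz is not counted twice. A Lomb–Scargle
#' alternative operating directly on the uneven samples is available with
#' `method = "lomb"`; its periodogram is rescaled so the total power equals
#' the sample variance.
#'
#' @param rr an [rr_series()] (onset times are required, so a bare numeric
#'   vector is not accepted here).
#' @param method `"welch"` or `"lomb"`.
#' @param resample_hz even-grid sampling rate for the Welch path (default 4).
#' @param welch_window_s Welch window length in seconds (default 120).
#' @param lf,hf numeric length-2 band edges in Hz.
#' @return A list with `lf_power`, `hf_power` (ms^2) and `lf_hf`
#'   (`NA` when the HF power is zero).
#' @export
band_powers <- function(rr, method = c("welch", "lomb"), resample_hz = 4,
                        welch_window_s = 120,
                        lf = c(0.04, 0.15), hf = c(0.15, 0.40)) {
  stopifnot(inherits(rr, "rr_series"))
  method <- match.arg(method)
  ok <- rr$annotations == "normal"
  t <- rr$t_cum[ok]
  v <- rr$intervals[ok]
  if (length(v) < 30L || (max(t) - min(t)) < 60) {
    stop("need at least 30 beats spanning at least 60 s", call. = FALSE)
  }
  if (method == "welch") {
    grid <- seq(min(t), max(t), by = 1 / resample_hz)
    y <- stats::spline(t, v, xout = grid, method = "fmm")$y
    y <- y - mean(y)
    psd <- welch_psd(y, fs = resample_hz,
                     nper = round(welch_window_s * resample_hz))
  } else {
    psd <- lomb_psd(t, v, fmax = 0.5, df = 1 / (max(t) - min(t)))
  }
  list(lf_power = band_integral(psd, lf[1], lf[2]),
       hf_power = band_integral(psd, hf[1], hf[2]),
       lf_hf = {
         lfp <- band_integral(psd, lf[1], lf[2])
         hfp <- band_integral(psd, hf[1], hf[2])
         if (hfp > 0) lfp / hfp else NA_real_
       })
}

# Welch averaged periodogram; one-sided density in units^2 per Hz.
# Segments of length nper, 50% overlap, Hann taper, per-segment mean removal.
welch_psd <- function(y, fs, nper) {
  n <- length(y)
  nper <- min(nper, n)
  step <- max(1L, floor(nper / 2))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nper) / (nper + 1)))  # Hann
  scale <- fs * sum(w^2)
  acc <- 0
  for (s in starts) {
    seg <- y[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / (length(starts) * scale)
  nf <- floor(nper / 2) + 1L
  freq <- (seq_len(nf) - 1L) * fs / nper
  dens <- p[seq_len(nf)]
  # fold negative frequencies into the one-sided density
  inner <- seq(2L, nf - if (nper %% 2 == 0) 1L else 0L)
  dens[inner] <- 2 * dens[inner]
  list(freq = freq, psd = dens)
}

# Classical Lomb-Scargle periodogram on uneven samples, rescaled so that the
# trapezoidal integral over (0, fmax] equals the sample variance.
lomb_psd <- function(t, v, fmax, df) {
  v <- v - mean(v)
  freq <- seq(df, fmax, by = df)
  p <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    0.5 * (sum(v * ct)^2 / sum(ct^2) + sum(v * st)^2 / sum(st^2))
  }, numeric(1))
  total <- trapz(freq, p)
  if (total > 0) p <- p * stats::var(v) / total
  list(freq = freq, psd = p)
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# Trapezoidal band power over the half-open band [low, high).
band_integral <- function(psd, low, high) {
  sel <- psd$freq >= low & psd$freq < high
  if (sum(sel) < 2L) return(0)
  trapz(psd$freq[sel], psd$psd[sel])
}
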
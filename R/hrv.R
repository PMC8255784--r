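#' HRV frequency bands
#'
#' The low-frequency (0.04-0.15 Hz) and high-frequency (0.15-0.40 Hz) bands
#' used for rabbit RR-interval spectral analysis.
#'
#' @param lf_lo,lf_hi,hf_lo,hf_hi Band edges in Hz.
#' @return A list of class `hrv_bands`.
#' @export
hrv_bands <- function(lf_lo = 0.04, lf_hi = 0.15, hf_lo = 0.15, hf_hi = 0.40) {
  stopifnot_msg(0 < lf_lo && lf_lo < lf_hi && lf_hi <= hf_lo && hf_lo < hf_hi,
                "band edges must satisfy 0 < lf_lo < lf_hi <= hf_lo < hf_hi")
  structure(list(lf_lo = lf_lo, lf_hi = lf_hi, hf_lo = hf_lo, hf_hi = hf_hi),
            class = "hrv_bands")
}

#' Lomb-Scargle periodogram of an RR tachogram
#'
#' Classical variance-normalized Lomb-Scargle periodogram of the unevenly
#' sampled RR series — no resampling or interpolation of the tachogram is
#' involved, which is the point of the estimator. The series is mean-centred
#' internally. Alongside the dimensionless normalized power, a density in
#' ms^2/Hz is attached, scaled so that for an evenly sampled record the
#' integral over frequency recovers the series variance (one-sided).
#'
#' @param beat_times_s Beat times in seconds (the tachogram abscissa: the time
#'   of the interval's end).
#' @param rr_ms RR values in ms, same length; typically the cleaned series
#'   from [clean_rr()].
#' @param freq_grid_hz Strictly increasing frequency grid in Hz (default
#'   0.02-0.5 Hz in 0.005 Hz steps).
#' @return A `psd_estimate` tibble: `freq_hz`, `power_norm` (variance
#'   normalized), `power_ms2_hz` (density); attribute `normalization`.
#' @export
lomb_scargle <- function(beat_times_s, rr_ms,
                         freq_grid_hz = seq(0.02, 0.5, by = 0.005)) {
  stopifnot_msg(length(beat_times_s) == length(rr_ms),
                "times and RR must have the same length")
  stopifnot_msg(length(rr_ms) >= 30, "need at least 30 beats")
  stopifnot_msg(all(diff(freq_grid_hz) > 0) && length(freq_grid_hz) >= 2,
                "`freq_grid_hz` must be strictly increasing")
  t <- as.numeric(beat_times_s)
  y <- as.numeric(rr_ms) - mean(rr_ms)
  s2 <- var(y)
  n <- length(y)
  p <- vapply(freq_grid_hz, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    num_c <- sum(y * ct)^2 / sum(ct^2)
    num_s <- sum(y * st)^2 / sum(st^2)
    (num_c + num_s) / (2 * s2)
  }, numeric(1))
  if (s2 == 0) p[] <- 0
  span <- diff(range(t))
  density <- p * 2 * s2 * span / n
  out <- tibble::tibble(freq_hz = freq_grid_hz, power_norm = p,
                        power_ms2_hz = density)
  attr(out, "normalization") <- "lomb_variance_normalized"
  class(out) <- c("psd_estimate", class(out))
  out
}

#' Band power of a PSD estimate
#'
#' Trapezoidal integral of the spectral density over `[lo_hz, hi_hz)`.
#'
#' @param psd A `psd_estimate` from [lomb_scargle()].
#' @param lo_hz,hi_hz Band edges (must lie within the grid span).
#' @param scale Which column to integrate: `"ms2"` (default, `power_ms2_hz`)
#'   or `"normalized"` (`power_norm`).
#' @return Band power (ms^2 for the default scale).
#' @export
band_power <- function(psd, lo_hz, hi_hz, scale = c("ms2", "normalized")) {
  scale <- match.arg(scale)
  stopifnot_msg(lo_hz < hi_hz, "empty band")
  f <- psd$freq_hz
  stopifnot_msg(lo_hz >= min(f) && hi_hz <= max(f) + 1e-12,
                "band [%g, %g] outside the grid span [%g, %g]",
                lo_hz, hi_hz, min(f), max(f))
  y <- if (scale == "ms2") psd$power_ms2_hz else psd$power_norm
  # restrict to [lo, hi), interpolating the edges onto the grid
  yi <- function(x) approx(f, y, xout = x, rule = 2)$y
  inside <- f > lo_hz & f < hi_hz
  fx <- c(lo_hz, f[inside], hi_hz)
  fy <- c(yi(lo_hz), y[inside], yi(hi_hz))
  sum(diff(fx) * (head(fy, -1) + tail(fy, -1)) / 2)
}

#' LF/HF ratio
#'
#' @param lf,hf Band powers; `hf` must be positive, otherwise the ratio is
#'   undefined and returned as `NA` with a warning.
#' @return lf/hf.
#' @export
lf_hf_ratio <- function(lf, hf) {
  if (any(hf <= 0)) {
    warn("HF power is zero: LF/HF undefined, returning NA")
    return(ifelse(hf > 0, lf / hf, NA_real_))
  }
  lf / hf
}

#' Final-minutes baseline window
#'
#' Returns the beats of the last `minutes` of the baseline phase — the
#' half-open window `[baseline_end - 60 * minutes, baseline_end)`. When the
#' baseline is shorter than the window, the full baseline is returned with a
#' warning.
#'
#' @param series A `beat_series`.
#' @param minutes Window length (default 5).
#' @param phase Baseline phase label (default `"baseline"`).
#' @return The sub-series (same columns).
#' @export
baseline_window <- function(series, minutes = 5, phase = "baseline") {
  assert_beat_series(series)
  base <- series[series$phase == phase, ]
  stopifnot_msg(nrow(base) > 0, "no beats in phase '%s'", phase)
  proto <- attr(series, "protocol")
  end_s <- if (!is.null(proto) && phase %in% proto$phase) {
    proto$end_s[proto$phase == phase]
  } else max(base$time_s)
  start_s <- if (!is.null(proto) && phase %in% proto$phase) {
    proto$start_s[proto$phase == phase]
  } else min(base$time_s) - base$rr_ms[1] / 1000
  if (end_s - start_s < 60 * minutes + 1e-9) {
    if (end_s - start_s < 60 * minutes - 1e-9) {
      warn(sprintf("baseline (%.0f s) shorter than %g min window: using all of it",
                   end_s - start_s, minutes))
    }
    return(base)
  }
  base[base$time_s >= end_s - 60 * minutes & base$time_s < end_s, ]
}

#' Frequency-domain HRV of a beat series
#'
#' The full published HRV chain: take the last 5 min of baseline, clean the
#' RR tachogram with the 20% rule ([clean_rr()]), estimate the spectrum by
#' [lomb_scargle()], and integrate the LF and HF bands.
#'
#' @param series A `beat_series`.
#' @param bands An [hrv_bands()].
#' @param minutes Baseline window length (default 5).
#' @param freq_grid_hz Frequency grid for the periodogram.
#' @return A one-row tibble of class `hrv_result`: `lf`, `hf`, `lf_hf`,
#'   `n_beats`, `n_cleaned`, `window_start_s`, `window_end_s`,
#'   `normalization`.
#' @export
hrv_analysis <- function(series, bands = hrv_bands(), minutes = 5,
                         freq_grid_hz = seq(0.02, 0.5, by = 0.005)) {
  win <- baseline_window(series, minutes = minutes)
  cl <- clean_rr(win$rr_ms)
  psd <- lomb_scargle(win$time_s, cl$rr_ms, freq_grid_hz)
  lf <- band_power(psd, bands$lf_lo, bands$lf_hi)
  hf <- band_power(psd, bands$hf_lo, bands$hf_hi)
  out <- tibble::tibble(
    lf = lf, hf = hf,
    lf_hf = if (hf > 0) lf / hf else NA_real_,
    n_beats = nrow(win), n_cleaned = cl$n_replaced,
    window_start_s = min(win$time_s), window_end_s = max(win$time_s),
    normalization = attr(psd, "normalization")
  )
  class(out) <- c("hrv_result", class(out))
  out
}
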
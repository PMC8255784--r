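#' R-peak detection configuration
#'
#' Parameters of the derivative-threshold R-peak detector. The threshold is a
#' fraction of the maximum absolute first difference of the (lightly
#' smoothed) signal; a refractory period suppresses re-triggering within a
#' beat; after each threshold crossing the R peak is localized as the signal
#' extremum within a short search window. The published method leaves these
#' parameters unstated; the defaults are tuned for rabbit heart rates of
#' 100-200 bpm and are all configurable.
#'
#' @param derivative_threshold_frac Fraction of max |first difference| used
#'   as the slope threshold (default 0.4).
#' @param refractory_ms Minimum separation of successive detections, ms
#'   (default 120).
#' @param search_back_ms Window after a threshold crossing searched for the R
#'   extremum, ms (default 40).
#' @param smooth_ms Moving-average width applied before differencing, ms
#'   (default 5; 0 disables).
#' @param min_peak_frac Amplitude confirmation: a detected extremum must reach
#'   this fraction of the global maximum |signal| (default 0.25).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(derivative_threshold_frac = 0.4,
                             refractory_ms = 120,
                             search_back_ms = 40,
                             smooth_ms = 5,
                             min_peak_frac = 0.25) {
  stopifnot_msg(derivative_threshold_frac > 0 && derivative_threshold_frac < 1,
                "`derivative_threshold_frac` must be in (0, 1)")
  stopifnot_msg(refractory_ms > 0, "`refractory_ms` must be positive")
  structure(list(derivative_threshold_frac = derivative_threshold_frac,
                 refractory_ms = refractory_ms,
                 search_back_ms = search_back_ms,
                 smooth_ms = smooth_ms,
                 min_peak_frac = min_peak_frac),
            class = "detection_config")
}

#' Detect R peaks by the derivative-threshold algorithm
#'
#' Finds threshold crossings of the absolute first difference and localizes
#' each R peak as the extremum of |signal - baseline| within the search
#' window, honouring the refractory period. Works for both polarities, so
#' inverted TdP complexes are detected too. A flat (constant) trace returns
#' no detections.
#'
#' @param waveform An `ecg_waveform` (tibble `time_s`, `mv` with an `fs_hz`
#'   attribute) or a data frame with those columns plus `fs_hz` given.
#' @param config A [detection_config()].
#' @param fs_hz Sampling rate override when `waveform` carries none.
#' @return Numeric vector of detected R times in seconds.
#' @export
#' @examples
#' s <- make_beat_series(profile_yc(), phase_protocol("baseline", 10), seed = 1)
#' w <- render_waveform(s, fs_hz = 500)
#' detect_r_peaks(w)
detect_r_peaks <- function(waveform, config = detection_config(),
                           fs_hz = NULL) {
  stopifnot_msg(is.data.frame(waveform) && nrow(waveform) > 1,
                "`waveform` must be a non-empty data frame")
  fs <- fs_hz %||% attr(waveform, "fs_hz")
  stopifnot_msg(!is.null(fs) && fs > 0, "sampling rate unknown")
  x <- waveform$mv
  if (config$smooth_ms > 0) {
    k <- max(1L, round(fs * config$smooth_ms / 1000))
    if (k > 1) {
      xs <- stats::filter(x, rep(1 / k, k), sides = 2)
      xs[is.na(xs)] <- x[is.na(xs)]
      x <- as.numeric(xs)
    }
  }
  d <- abs(diff(x))
  dmax <- max(d)
  if (dmax == 0) return(numeric(0))
  thr <- config$derivative_threshold_frac * dmax
  base <- median(x)
  amp_min <- config$min_peak_frac * max(abs(x - base))
  cross <- which(d >= thr)
  if (length(cross) == 0) return(numeric(0))
  refr <- config$refractory_ms / 1000 * fs
  win <- max(1L, round(config$search_back_ms / 1000 * fs))
  peaks <- integer(0)
  last <- -Inf
  for (i in cross) {
    if (i - last < refr) next
    hi <- min(length(x), i + win)
    seg <- abs(x[i:hi] - base)
    j <- i + which.max(seg) - 1L
    if (abs(x[j] - base) < amp_min) next
    if (length(peaks) > 0 && j - peaks[length(peaks)] < refr) next
    peaks <- c(peaks, j)
    last <- j
  }
  (peaks - 1) / fs
}

#' RR intervals from beat times
#'
#' @param beat_times_s Strictly increasing beat times in seconds (>= 2).
#' @return RR intervals in ms, length `length(beat_times_s) - 1`.
#' @export
#' @examples
#' rr_from_peaks(c(0, 0.4, 0.8)) # 400 400
rr_from_peaks <- function(beat_times_s) {
  stopifnot_msg(length(beat_times_s) >= 2, "need at least 2 beats")
  stopifnot_msg(all(diff(beat_times_s) > 0),
                "beat times must be strictly increasing")
  1000 * diff(beat_times_s)
}

#' Clean ectopic RR intervals by the 20% rule
#'
#' Flags intervals deviating from the mean of the raw series by more than
#' `threshold_frac` (single pass, global mean) and replaces them by linear
#' interpolation between the nearest retained neighbours; flagged values at
#' the boundary take the nearest retained value. This is the standard
#' pre-processing applied to the RR tachogram before spectral HRV analysis.
#'
#' @param rr_ms RR series in ms (length >= 3).
#' @param threshold_frac Relative deviation threshold (default 0.20).
#' @return A list of class `cleaned_rr`: `rr_ms` (cleaned), `ectopic_indices`,
#'   `n_replaced`.
#' @export
#' @examples
#' clean_rr(c(400, 400, 700, 400, 400))
clean_rr <- function(rr_ms, threshold_frac = 0.20) {
  stopifnot_msg(length(rr_ms) >= 3, "need at least 3 intervals")
  m <- mean(rr_ms)
  flagged <- which(abs(rr_ms - m) / m > threshold_frac)
  stopifnot_msg(length(flagged) < length(rr_ms),
                "all intervals flagged: no anchor left for interpolation")
  out <- rr_ms
  if (length(flagged) > 0) {
    keep <- setdiff(seq_along(rr_ms), flagged)
    out[flagged] <- approx(keep, rr_ms[keep], xout = flagged,
                           method = "linear", rule = 2)$y
  }
  structure(list(rr_ms = out, ectopic_indices = flagged,
                 n_replaced = length(flagged)),
            class = "cleaned_rr")
}

# T-end by the tangent method: steepest downslope after the T peak,
# extrapolated to the isoelectric baseline.
tangent_tend <- function(x, fs, from, to, base) {
  seg <- from:to
  tpk <- seg[which.max(abs(x[seg] - base))]
  after <- tpk:min(to + round(0.04 * fs), length(x) - 1)
  if (length(after) < 3) return(NA_integer_)
  slopes <- diff(x[after])
  k <- after[which.max(abs(slopes))]
  sl <- x[k + 1] - x[k]
  if (sl == 0) return(NA_integer_)
  cross <- k + (base - x[k]) / sl
  if (!is.finite(cross) || cross <= tpk) return(NA_integer_)
  as.integer(round(cross))
}

#' Measure per-beat QT intervals
#'
#' QT = (T-end - Q-onset) * 1000 / fs. When the waveform carries ground-truth
#' fiducials (synthetic data) and `use_fiducials = TRUE`, those take
#' precedence; otherwise Q onset is located as a fixed offset before each R
#' peak and T end by the tangent method (steepest T downslope extrapolated to
#' the isoelectric baseline). Beats where T end cannot be located — including
#' polymorphic TdP complexes, which have no measurable QT — are returned as
#' `NA`, never fabricated.
#'
#' @param waveform An `ecg_waveform`.
#' @param beat_times_s R times in seconds (defaults to the fiducial R times).
#' @param use_fiducials Prefer ground-truth fiducials when present.
#' @param fs_hz Sampling-rate override.
#' @return QT per beat in ms (NA where unmeasurable).
#' @export
measure_qt <- function(waveform, beat_times_s = NULL, use_fiducials = TRUE,
                       fs_hz = NULL) {
  fs <- fs_hz %||% attr(waveform, "fs_hz")
  stopifnot_msg(!is.null(fs) && fs > 0, "sampling rate unknown")
  fid <- waveform_fiducials(waveform)
  if (use_fiducials && !is.null(fid)) {
    return((fid$tend - fid$q) * 1000 / fs)
  }
  stopifnot_msg(!is.null(beat_times_s), "beat times required without fiducials")
  x <- waveform$mv
  base <- median(x)
  r_idx <- round(beat_times_s * fs) + 1
  rr <- c(diff(r_idx), if (length(r_idx) > 1) diff(r_idx)[length(r_idx) - 1]
          else round(0.4 * fs))
  vapply(seq_along(r_idx), function(i) {
    q <- r_idx[i] - round(0.035 * fs)
    from <- r_idx[i] + round(0.06 * fs)
    to <- min(r_idx[i] + round(0.75 * rr[i]), length(x) - 2)
    if (q < 1 || from >= to) return(NA_real_)
    tend <- tangent_tend(x, fs, from, to, base)
    if (is.na(tend)) return(NA_real_)
    (tend - q) * 1000 / fs
  }, numeric(1))
}

#' Build a beat table from a waveform
#'
#' Convenience wrapper chaining [detect_r_peaks()], [rr_from_peaks()] and
#' [measure_qt()] into the per-beat tibble the downstream metrics consume.
#'
#' @inheritParams detect_r_peaks
#' @param use_fiducials Passed to [measure_qt()].
#' @return Tibble `time_s`, `rr_ms` (NA for the first beat), `qt_ms`.
#' @export
beats_from_waveform <- function(waveform, config = detection_config(),
                                use_fiducials = FALSE, fs_hz = NULL) {
  times <- detect_r_peaks(waveform, config, fs_hz = fs_hz)
  stopifnot_msg(length(times) >= 2, "fewer than 2 beats detected")
  qt <- measure_qt(waveform, times, use_fiducials = use_fiducials,
                   fs_hz = fs_hz)
  tibble::tibble(time_s = times,
                 rr_ms = c(NA_real_, rr_from_peaks(times)),
                 qt_ms = if (length(qt) == length(times)) qt
                         else rep(NA_real_, length(times)))
}
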
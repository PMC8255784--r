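# Per-beat template geometry (seconds, mV). A rabbit lead-II-like PQRST
# built from Gaussian bumps; QRS duration ~70 ms needs >= 250 Hz sampling.
wave_template <- list(
  p  = list(dt = -0.085, amp = 0.12, sd = 0.012),
  q  = list(dt = -0.035, amp = -0.08, sd = 0.005),
  r  = list(dt = 0.000, amp = 1.00, sd = 0.006),
  s  = list(dt = 0.022, amp = -0.22, sd = 0.005)
)

add_gauss <- function(x, fs, t0, amp, sd_s) {
  lo <- max(1L, floor((t0 - 4 * sd_s) * fs) + 1L)
  hi <- min(length(x), ceiling((t0 + 4 * sd_s) * fs) + 1L)
  if (lo > hi) return(x)
  tt <- (seq.int(lo, hi) - 1) / fs
  x[lo:hi] <- x[lo:hi] + amp * exp(-0.5 * ((tt - t0) / sd_s)^2)
  x
}

#' Render a synthetic ECG waveform from a beat series
#'
#' Each normal or ectopic beat becomes a template PQRST complex with the R
#' peak at the beat time and the T wave scaled so the QT span matches the
#' beat's `qt_ms`. TdP beats are rendered as broad polymorphic complexes with
#' sinusoidally modulated amplitude and alternating polarity (the twisting
#' morphology). Ground-truth fiducial sample indices (1-based; P, Q, R, S,
#' T-end) are attached for every beat.
#'
#' `amp_jitter` scales each beat's whole complex by `1 + amp_jitter * z`
#' (z standard normal) and additionally applies a smooth multiplicative
#' amplitude wander of the same relative scale — the subtle beat-to-beat
#' amplitude irregularity that amplitude-aware entropy is designed to detect.
#'
#' @param series A `beat_series`.
#' @param fs_hz Sampling rate, >= 250 Hz (default 1000).
#' @param noise_sd_mv SD of additive white noise in mV.
#' @param seed Integer seed (noise and jitter).
#' @param amp_jitter Fractional per-beat amplitude jitter (default 0).
#' @return An `ecg_waveform`: tibble (`time_s`, `mv`) with attributes
#'   `fs_hz` and `fiducials` (tibble `beat`, `p`, `q`, `r`, `s`, `tend`).
#' @export
#' @examples
#' s <- make_beat_series(profile_yc(), phase_protocol(c("baseline"), 10), seed = 1)
#' w <- render_waveform(s, fs_hz = 500)
render_waveform <- function(series, fs_hz = 1000, noise_sd_mv = 0, seed = 1,
                            amp_jitter = 0) {
  assert_beat_series(series)
  stopifnot_msg(fs_hz >= 250, "`fs_hz` must be at least 250 Hz")
  set.seed(as.integer(seed %% 2147483629))
  n_beats <- nrow(series)
  n <- ceiling((max(series$time_s) + 0.3) * fs_hz) + 1L
  x <- numeric(n)
  scale_beat <- 1 + amp_jitter * rnorm(n_beats)
  scale_beat <- pmax(scale_beat, 0.2)

  fid <- matrix(NA_integer_, nrow = n_beats, ncol = 5,
                dimnames = list(NULL, c("p", "q", "r", "s", "tend")))
  tdp_k <- 0L
  for (i in seq_len(n_beats)) {
    r_t <- series$time_s[i]
    sc <- scale_beat[i]
    if (series$label[i] == "tdp") {
      tdp_k <- if (i > 1 && series$label[i - 1] == "tdp") tdp_k + 1L else 0L
      pol <- if (tdp_k %% 2L == 0L) 1 else -1
      amp <- 0.9 * (0.55 + 0.45 * abs(sin(pi * (tdp_k + 1) / 6))) * sc
      x <- add_gauss(x, fs_hz, r_t, pol * amp, 0.018)
      fid[i, "r"] <- as.integer(round(r_t * fs_hz) + 1L)
      next
    }
    qt_s <- series$qt_ms[i] / 1000
    for (cmp in wave_template) {
      x <- add_gauss(x, fs_hz, r_t + cmp$dt, sc * cmp$amp, cmp$sd)
    }
    q_t <- r_t + wave_template$q$dt
    tend_t <- q_t + qt_s
    t_sd <- qt_s / 8
    x <- add_gauss(x, fs_hz, tend_t - 2.5 * t_sd, sc * 0.32, t_sd)
    fid[i, ] <- as.integer(round(c(
      r_t + wave_template$p$dt, q_t, r_t, r_t + wave_template$s$dt, tend_t
    ) * fs_hz) + 1L)
  }
  if (amp_jitter > 0) {
    # smooth multiplicative wander: white noise low-passed by a moving mean
    w <- rnorm(n)
    k <- max(3L, round(fs_hz * 0.15))
    w <- stats::filter(w, rep(1 / k, k), sides = 2)
    w[is.na(w)] <- 0
    w <- as.numeric(w) * sqrt(k) # restore unit-ish variance after averaging
    x <- x * (1 + amp_jitter * w)
  }
  if (noise_sd_mv > 0) x <- x + rnorm(n, 0, noise_sd_mv)

  out <- tibble::tibble(time_s = (seq_len(n) - 1) / fs_hz, mv = x)
  attr(out, "fs_hz") <- fs_hz
  attr(out, "fiducials") <- tibble::as_tibble(cbind(beat = seq_len(n_beats),
                                                    fid))
  class(out) <- c("ecg_waveform", class(out))
  out
}

#' Waveform attributes
#'
#' Accessors for the sampling rate and ground-truth fiducials of an
#' `ecg_waveform`.
#'
#' @param waveform An `ecg_waveform`.
#' @return `waveform_fs()` the sampling rate in Hz; `waveform_fiducials()` a
#'   tibble of 1-based sample indices per beat (`NA` where undefined, e.g.
#'   TdP complexes carry only `r`).
#' @export
waveform_fs <- function(waveform) {
  fs <- attr(waveform, "fs_hz")
  stopifnot_msg(!is.null(fs) && fs > 0, "waveform has no sampling rate")
  fs
}

#' @rdname waveform_fs
#' @export
waveform_fiducials <- function(waveform) attr(waveform, "fiducials")
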
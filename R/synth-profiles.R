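#' Experimental phase protocol
#'
#' The in vivo protocol the simulator emulates: a 10 min drug-free baseline,
#' 10 min of alpha-1-adrenergic sensitization (methoxamine), then 20 + 20 min
#' of IKr block (dofetilide, low then high dose) on top of methoxamine.
#'
#' @param phases Character vector of phase labels, in order.
#' @param durations_s Numeric vector of phase durations in seconds.
#' @return A tibble with columns `phase`, `duration_s`, `start_s`, `end_s`,
#'   of class `phase_protocol`.
#' @export
#' @examples
#' phase_protocol()
phase_protocol <- function(phases = c("baseline", "methoxamine",
                                      "dofetilide_low", "dofetilide_high"),
                           durations_s = c(600, 600, 1200, 1200)) {
  stopifnot_msg(length(phases) == length(durations_s),
                "`phases` and `durations_s` must have the same length")
  stopifnot_msg(!anyDuplicated(phases), "phase labels must be unique")
  stopifnot_msg(all(durations_s > 0), "all phase durations must be positive")
  out <- tibble::tibble(
    phase = as.character(phases),
    duration_s = as.numeric(durations_s),
    end_s = cumsum(as.numeric(durations_s))
  )
  out$start_s <- out$end_s - out$duration_s
  out <- out[, c("phase", "duration_s", "start_s", "end_s")]
  class(out) <- c("phase_protocol", class(out))
  out
}

#' Group-level simulation profile
#'
#' Describes one experimental group for the synthetic cohort generator:
#' per-phase RR and QT targets (means and beat-to-beat spreads, ms),
#' beat-to-beat QTc jitter (which drives short-term variability), sinusoidal
#' RR modulations in the HRV bands, per-phase ectopy rates, a bigeminy flag,
#' the probability of being a TdP responder under the high-dose phase, and
#' the amplitude-jitter level applied to the rendered baseline ECG of
#' arrhythmia-prone animals.
#'
#' @param name Group label.
#' @param rr_mean_ms,rr_sd_ms Named numeric vectors (one entry per phase) of
#'   RR interval mean and beat-level SD in ms.
#' @param qt_mean_ms,qt_sd_ms Named numeric vectors of QT mean and SD in ms.
#' @param qtc_jitter_ms Scale (SD, ms) of the independent beat-to-beat QTc
#'   jitter. For i.i.d. Gaussian jitter of SD s the expected STV is
#'   s * sqrt(2/pi) (about 0.8 s), so the default 6.8 ms targets the ~5.4 ms
#'   STV typical of baseline recordings.
#' @param rr_mod Tibble with columns `freq_hz`, `amp_ms`: sinusoidal RR
#'   modulations, the generator's stand-in for autonomic LF/HF variability.
#' @param seb_rate,meb_rate Named numeric vectors of expected single / multiple
#'   ectopic-beat events per minute per phase.
#' @param bigeminy Logical; inject one bigeminy episode in the high-dose phase.
#' @param tdp_propensity Probability in \[0, 1\] that an animal of this group
#'   is a TdP responder under the high-dose phase.
#' @param amp_jitter_prone Fractional per-beat ECG amplitude jitter applied to
#'   arrhythmia-prone animals at baseline (the subtle irregularity that
#'   entropy analysis is meant to pick up); arrhythmia-free animals get 0.
#' @return A list of class `group_profile`.
#' @export
#' @examples
#' profile_yc()
group_profile <- function(name,
                          rr_mean_ms, rr_sd_ms,
                          qt_mean_ms, qt_sd_ms,
                          qtc_jitter_ms = 6.8,
                          rr_mod = tibble::tibble(freq_hz = c(0.10, 0.30),
                                                  amp_ms = c(6, 6)),
                          seb_rate = 0, meb_rate = 0,
                          bigeminy = FALSE,
                          tdp_propensity = 0,
                          amp_jitter_prone = 0.08) {
  phases <- names(rr_mean_ms)
  stopifnot_msg(!is.null(phases), "`rr_mean_ms` must be named by phase")
  norm_phase_vec <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(as.numeric(x), length(phases)), phases)
    }
    stopifnot_msg(setequal(names(x), phases),
                  "`%s` must be named by the same phases as `rr_mean_ms`", what)
    x[phases]
  }
  rr_sd_ms <- norm_phase_vec(rr_sd_ms, "rr_sd_ms")
  qt_mean_ms <- norm_phase_vec(qt_mean_ms, "qt_mean_ms")
  qt_sd_ms <- norm_phase_vec(qt_sd_ms, "qt_sd_ms")
  seb_rate <- norm_phase_vec(seb_rate, "seb_rate")
  meb_rate <- norm_phase_vec(meb_rate, "meb_rate")

  stopifnot_msg(all(rr_mean_ms > 0) && all(qt_mean_ms > 0),
                "all interval means must be positive")
  stopifnot_msg(all(rr_sd_ms >= 0) && all(qt_sd_ms >= 0),
                "all interval SDs must be non-negative")
  bad <- phases[qt_mean_ms >= rr_mean_ms]
  stopifnot_msg(length(bad) == 0,
                "qt_mean must be below rr_mean in every phase; violated in: %s",
                paste(bad, collapse = ", "))
  stopifnot_msg(all(seb_rate >= 0) && all(meb_rate >= 0),
                "ectopy rates must be non-negative")
  stopifnot_msg(is_scalar_number(tdp_propensity) &&
                  tdp_propensity >= 0 && tdp_propensity <= 1,
                "`tdp_propensity` must be in [0, 1]")
  stopifnot_msg(is.data.frame(rr_mod) &&
                  all(c("freq_hz", "amp_ms") %in% names(rr_mod)),
                "`rr_mod` must have columns freq_hz and amp_ms")
  stopifnot_msg(all(rr_mod$freq_hz > 0), "modulation frequencies must be > 0")
  stopifnot_msg(qtc_jitter_ms >= 0, "`qtc_jitter_ms` must be non-negative")

  structure(
    list(name = name, phases = phases,
         rr_mean_ms = rr_mean_ms, rr_sd_ms = rr_sd_ms,
         qt_mean_ms = qt_mean_ms, qt_sd_ms = qt_sd_ms,
         qtc_jitter_ms = qtc_jitter_ms, rr_mod = rr_mod,
         seb_rate = seb_rate, meb_rate = meb_rate,
         bigeminy = bigeminy, tdp_propensity = tdp_propensity,
         amp_jitter_prone = amp_jitter_prone),
    class = "group_profile"
  )
}

# Shared defaults behind the three stock profiles. Interval targets follow
# the group-level statistics of the methoxamine-sensitized rabbit protocol;
# the low-dose dofetilide phase (not separately tabulated) is set midway
# between the methoxamine and high-dose values.
stock_profile <- function(name, rr, rr_sd, qt, qt_sd, seb_hd, meb_hd,
                          tdp_propensity, hf_amp = 6) {
  ph <- c("baseline", "methoxamine", "dofetilide_low", "dofetilide_high")
  zero <- stats::setNames(rep(0, 4), ph)
  seb <- zero; seb[c("dofetilide_low", "dofetilide_high")] <- c(seb_hd / 2, seb_hd)
  meb <- zero; meb[c("dofetilide_low", "dofetilide_high")] <- c(meb_hd / 2, meb_hd)
  group_profile(
    name = name,
    rr_mean_ms = stats::setNames(rr, ph),
    rr_sd_ms = stats::setNames(rr_sd, ph),
    qt_mean_ms = stats::setNames(qt, ph),
    qt_sd_ms = stats::setNames(qt_sd, ph),
    rr_mod = tibble::tibble(freq_hz = c(0.10, 0.30), amp_ms = c(6, hf_amp)),
    seb_rate = seb, meb_rate = meb,
    tdp_propensity = tdp_propensity
  )
}

#' Stock group profiles
#'
#' Ready-made simulation profiles for the three experimental groups of the
#' sensitized-rabbit TdP protocol: young controls (`profile_yc`, high TdP
#' propensity 0.83), adult controls (`profile_ac`, 0.18), and adult
#' cholesterol-fed animals (`profile_ch`, 0.21). Interval targets per phase
#' mirror the published group means and SDs; the low-dose dofetilide phase is
#' interpolated between its neighbours.
#'
#' @return A `group_profile`.
#' @export
profile_yc <- function() {
  stock_profile("YC",
                rr = c(381, 502, 540, 579), rr_sd = c(66, 81, 86, 91),
                qt = c(220, 250, 281, 312), qt_sd = c(26, 24, 22, 19),
                seb_hd = 1.2, meb_hd = 0.6, tdp_propensity = 0.83,
                hf_amp = 3)
}

#' @rdname profile_yc
#' @export
profile_ac <- function() {
  stock_profile("AC",
                rr = c(404, 549, 540, 532), rr_sd = c(69, 88, 78, 67),
                qt = c(225, 250, 287, 324), qt_sd = c(26, 31, 39, 46),
                seb_hd = 0.25, meb_hd = 0.12, tdp_propensity = 0.18)
}

#' @rdname profile_yc
#' @export
profile_ch <- function() {
  stock_profile("CH",
                rr = c(376, 443, 518, 593), rr_sd = c(57, 83, 94, 104),
                qt = c(205, 228, 262, 297), qt_sd = c(21, 43, 37, 30),
                seb_hd = 0.25, meb_hd = 0.12, tdp_propensity = 0.21)
}
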
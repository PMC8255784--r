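#' Classify arrhythmia episodes directly from a waveform
#'
#' Waveform-level operationalization of the event definitions (the published
#' classification was manual): beats are detected with [detect_r_peaks()],
#' a TdP episode is a run of at least five detected complexes whose RR is
#' below `tdp_rr_frac` of the record median RR with polarity alternation
#' across the run envelope (at least two sign changes of the R deflection),
#' and remaining premature beats deviating more than `ectopic_frac` below the
#' median RR are labelled ectopic. The label-mode path ([classify_runs()] on
#' generator labels) bypasses this reconstruction for exact testing.
#'
#' Polymorphic TdP complexes are broader and slower-rising than a normal QRS,
#' so the classifier defaults to a lower slope threshold than plain R-peak
#' detection; the amplitude-confirmation step keeps noise from triggering
#' detections at that setting.
#'
#' @param waveform An `ecg_waveform`.
#' @param config A [detection_config()].
#' @param tdp_rr_frac RR fraction of the median defining TdP-fast beats
#'   (default 0.6).
#' @param ectopic_frac Relative RR shortening flagging an ectopic beat
#'   (default 0.2, matching the cleaning rule).
#' @return A list: `episodes` (as [classify_runs()]), `beat_times_s`,
#'   `labels` (inferred per-beat labels).
#' @export
classify_waveform <- function(waveform,
                              config = detection_config(
                                derivative_threshold_frac = 0.15,
                                min_peak_frac = 0.4),
                              tdp_rr_frac = 0.6, ectopic_frac = 0.2) {
  times <- detect_r_peaks(waveform, config)
  stopifnot_msg(length(times) >= 3, "too few beats detected")
  fs <- waveform_fs(waveform)
  rr <- c(NA_real_, rr_from_peaks(times))
  med <- median(rr, na.rm = TRUE)
  base <- median(waveform$mv)
  pol <- sign(waveform$mv[round(times * fs) + 1] - base)

  lab <- rep("normal", length(times))
  fast <- !is.na(rr) & rr < tdp_rr_frac * med
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] >= 5) {
      idx <- starts[i]:ends[i]
      if (sum(diff(pol[idx]) != 0) >= 2) lab[idx] <- "tdp"
    }
  }
  premature <- !is.na(rr) & lab == "normal" & rr < med &
    (med - rr) / med > ectopic_frac
  lab[premature] <- "ectopic"
  list(episodes = classify_runs(lab, times),
       beat_times_s = times, labels = lab)
}
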
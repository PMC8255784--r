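#' Plot an ECG waveform
#'
#' Voltage trace with detected or ground-truth R markers.
#'
#' @param object An `ecg_waveform`.
#' @param r_times_s Optional R times to mark (defaults to fiducial R times).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecg_waveform <- function(object, r_times_s = NULL, ...) {
  fs <- waveform_fs(object)
  fid <- waveform_fiducials(object)
  if (is.null(r_times_s) && !is.null(fid)) {
    r_times_s <- (fid$r[!is.na(fid$r)] - 1) / fs
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "ECG (mV)")
  if (!is.null(r_times_s) && length(r_times_s) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = r_times_s,
                                 colour = "red", alpha = 0.3,
                                 linetype = "dotted")
  }
  p
}

#' Plot a beat series tachogram
#'
#' RR against beat time, coloured by beat label, with phase boundaries.
#'
#' @param object A `beat_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beat_series <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_s, y = .data$rr_ms,
                                    colour = .data$label)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::labs(x = "time (s)", y = "RR (ms)", colour = "beat")
  proto <- attr(object, "protocol")
  if (!is.null(proto)) {
    p <- p + ggplot2::geom_vline(xintercept = proto$end_s, alpha = 0.3)
  }
  p
}

#' Plot a PSD estimate
#'
#' Spectral density with the LF and HF bands shaded.
#'
#' @param object A `psd_estimate`.
#' @param bands An [hrv_bands()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psd_estimate <- function(object, bands = hrv_bands(), ...) {
  shade <- tibble::tibble(
    band = c("LF", "HF"),
    lo = c(bands$lf_lo, bands$hf_lo),
    hi = c(bands$lf_hi, bands$hf_hi)
  )
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$freq_hz, y = .data$power_ms2_hz)) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$band),
                       alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(PSD~(ms^2/Hz)),
                  fill = "band")
}

#' Quadrant plot of entropy stratification
#'
#' AAPE against IEIN sigma per animal, with the threshold lines defining the
#' bottom-left low-risk quadrant.
#'
#' @param data Tibble with columns `aape`, `iein_sigma` and a grouping column.
#' @param thresholds A [quadrant_thresholds()].
#' @param colour Name of the grouping column (default `"category"`).
#' @return A ggplot.
#' @export
plot_quadrant <- function(data, thresholds = quadrant_thresholds(),
                          colour = "category") {
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data$aape, y = .data$iein_sigma,
                               colour = .data[[colour]])) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = thresholds$aape_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thresholds$iein_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "AAPE", y = expression(IEIN~sigma))
}
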
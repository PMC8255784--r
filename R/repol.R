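#' Rabbit rate-corrected QT
#'
#' The linear QT correction developed for the sensitized rabbit model:
#' QTc = QT - 0.175 * (RR - 300), all in ms. At the reference RR of 300 ms
#' the correction vanishes. The slope and reference are constants of the
#' rabbit correction but exposed for other models.
#'
#' @param qt_ms QT interval(s), ms.
#' @param rr_ms RR interval(s), ms; must be positive.
#' @param slope Correction slope (default 0.175).
#' @param rr_ref_ms Reference RR, ms (default 300).
#' @return QTc in ms (vectorized).
#' @export
#' @examples
#' qtc_rabbit(312, 579) # 263.175
#' qtc_rabbit(228, 443) # 202.975
qtc_rabbit <- function(qt_ms, rr_ms,
                       slope = qtc_rabbit_constants[["slope"]],
                       rr_ref_ms = qtc_rabbit_constants[["rr_ref_ms"]]) {
  stopifnot_msg(all(rr_ms > 0, na.rm = TRUE), "`rr_ms` must be positive")
  qt_ms - slope * (rr_ms - rr_ref_ms)
}

#' Short-term variability of repolarization
#'
#' STV = sum(|D[n-1] - D[n]|) / (n_diffs * sqrt(2)) over `n_diffs`
#' consecutive first differences of the QTc series D — the mean orthogonal
#' deviation from the identity line of the Poincare plot. Thirty consecutive
#' beat-to-beat differences are standard, i.e. the last 31 beats of the
#' series by default. `mode = "strict30"` instead uses the last 30 beats
#' (29 differences) while keeping the divisor at `n_diffs`, for comparison
#' with reports that count beats rather than differences.
#'
#' @param d_series QTc series in ms (most recent last).
#' @param n_diffs Number of consecutive first differences (default 30).
#' @param mode `"diffs"` (default: `n_diffs` differences from `n_diffs + 1`
#'   beats) or `"strict30"` (`n_diffs` beats, `n_diffs - 1` differences,
#'   divisor unchanged).
#' @param window `"last"` (default: the final window of the series) or
#'   `"sliding"` (mean STV over all complete windows).
#' @return STV in ms.
#' @export
#' @examples
#' stv(rep(200, 31))                    # 0
#' stv(rep(c(200, 210), length.out = 31)) # 300 / (30 * sqrt(2))
stv <- function(d_series, n_diffs = 30, mode = c("diffs", "strict30"),
                window = c("last", "sliding")) {
  mode <- match.arg(mode)
  window <- match.arg(window)
  stopifnot_msg(n_diffs >= 2, "`n_diffs` must be at least 2")
  d_series <- d_series[!is.na(d_series)]
  need <- if (mode == "diffs") n_diffs + 1 else n_diffs
  stopifnot_msg(length(d_series) >= need,
                "series too short: need %d beats, got %d",
                need, length(d_series))
  one <- function(win) sum(abs(diff(win))) / (n_diffs * sqrt(2))
  if (window == "last") {
    return(one(tail(d_series, need)))
  }
  starts <- seq_len(length(d_series) - need + 1)
  mean(vapply(starts, function(s) one(d_series[s:(s + need - 1)]), numeric(1)))
}

#' Per-phase interval summary
#'
#' Group-level mean and SD of RR, QT, QTc and STV per phase, across the
#' animals of a cohort — the layout of a standard ECG-parameters table.
#' QTc is computed per beat by [qtc_rabbit()]; STV per animal and phase from
#' the final 31-beat window; TdP beats (no measurable QT) are excluded.
#'
#' @param cohort A `tdp_cohort` (list-column `series`) or a tibble with
#'   columns `animal_id` and `series`.
#' @param phases Phases to summarize (default: all present).
#' @param round_ms Round means/SDs half-up to integer ms (STV to 1 decimal),
#'   matching report-table presentation. Default FALSE.
#' @return A tibble: `group`, `phase`, then mean/SD columns for `rr`, `qt`,
#'   `qtc`, `stv`, and `n` animals.
#' @export
phase_summary <- function(cohort, phases = NULL, round_ms = FALSE) {
  stopifnot_msg(is.data.frame(cohort) && nrow(cohort) >= 1,
                "`cohort` must have at least one animal")
  per_animal <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    s <- cohort$series[[i]]
    s <- s[s$label != "tdp", ]
    s$qtc_ms <- qtc_rabbit(s$qt_ms, s$rr_ms)
    dplyr::group_by(s, .data$phase) |>
      dplyr::summarise(
        rr = mean(.data$rr_ms), qt = mean(.data$qt_ms),
        qtc = mean(.data$qtc_ms),
        stv = if (dplyr::n() >= 31) stv(.data$qtc_ms) else NA_real_,
        .groups = "drop"
      ) |>
      dplyr::mutate(animal_id = cohort$animal_id[i],
                    group = if ("group" %in% names(cohort)) cohort$group[i]
                            else "all")
  })
  if (!is.null(phases)) {
    per_animal <- per_animal[per_animal$phase %in% phases, ]
    stopifnot_msg(nrow(per_animal) > 0, "no beats in the requested phase(s)")
  }
  out <- per_animal |>
    dplyr::group_by(.data$group, .data$phase) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("rr", "qt", "qtc", "stv")),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~ifelse(sum(!is.na(.x)) > 1,
                                      sd(.x, na.rm = TRUE), 0))),
      n = dplyr::n(), .groups = "drop"
    )
  if (round_ms) {
    ms_cols <- c("rr_mean", "rr_sd", "qt_mean", "qt_sd", "qtc_mean", "qtc_sd")
    out[ms_cols] <- lapply(out[ms_cols], round_half_up)
    out[c("stv_mean", "stv_sd")] <-
      lapply(out[c("stv_mean", "stv_sd")], round_half_up, digits = 1)
  }
  out
}
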
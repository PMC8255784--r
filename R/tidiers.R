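#' Tidy a cleaned RR series
#'
#' @param x A `cleaned_rr` from [clean_rr()].
#' @param ... Unused.
#' @return A tibble with one row per interval: `index`, `rr_ms`, `replaced`.
#' @export
tidy.cleaned_rr <- function(x, ...) {
  tibble::tibble(index = seq_along(x$rr_ms), rr_ms = x$rr_ms,
                 replaced = seq_along(x$rr_ms) %in% x$ectopic_indices)
}

#' @rdname tidy.cleaned_rr
#' @return `glance()`: one row with `n`, `n_replaced`, `mean_rr_ms`.
#' @export
glance.cleaned_rr <- function(x, ...) {
  tibble::tibble(n = length(x$rr_ms), n_replaced = x$n_replaced,
                 mean_rr_ms = mean(x$rr_ms))
}

#' Tidy a PSD estimate
#'
#' @param x A `psd_estimate` from [lomb_scargle()].
#' @param ... Unused.
#' @return `tidy()`: the frequency/power table. `glance()`: one row with LF
#'   and HF band powers and their ratio at the default bands.
#' @export
tidy.psd_estimate <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.psd_estimate
#' @export
glance.psd_estimate <- function(x, ...) {
  b <- hrv_bands()
  lf <- band_power(x, b$lf_lo, b$lf_hi)
  hf <- band_power(x, b$hf_lo, b$hf_hi)
  tibble::tibble(lf = lf, hf = hf,
                 lf_hf = if (hf > 0) lf / hf else NA_real_,
                 normalization = attr(x, "normalization") %||% NA_character_)
}

#' Tidy a proportion-test result
#'
#' @param x A `prop_test_result`.
#' @param ... Unused.
#' @return A broom-style tibble: `estimate1`, `estimate2`, `statistic`,
#'   `p.value`, `method`.
#' @export
tidy.prop_test_result <- function(x, ...) {
  tibble::tibble(estimate1 = x$p1, estimate2 = x$p2, statistic = x$z,
                 p.value = x$p_value,
                 method = "two-sample pooled-proportion z test")
}

#' Tidy an animal outcome
#'
#' @param x An `animal_outcome`.
#' @param ... Unused.
#' @return The outcome fields as a plain tibble.
#' @export
tidy.animal_outcome <- function(x, ...) tibble::as_tibble(x)

#' Tidy an entropy result
#'
#' @param x An `entropy_result`.
#' @param ... Unused.
#' @return `tidy()`: the result fields. `glance()`: one row with the values
#'   plus the AAPE configuration used.
#' @export
tidy.entropy_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.entropy_result
#' @export
glance.entropy_result <- function(x, ...) {
  cfg <- attr(x, "ordinal_config")
  tibble::tibble(aape = x$aape, iein_sigma = x$iein_sigma,
                 m = cfg$m %||% NA_integer_, tau = cfg$tau %||% NA_integer_,
                 A = cfg$A %||% NA_real_)
}
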
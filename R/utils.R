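#' Round half away from zero
#'
#' Report tables round to the printed precision with halves going up
#' (5 -> 10), unlike base [round()] which rounds halves to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)   # 1
#' round_half_up(2.5)   # 3, where round() gives 2
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Derive a reproducible 32-bit sub-seed from (seed, stream index).
# Keeps every derived seed strictly below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 100003 + as.double(index) * 7919 + 1) %%
               2147483629)
}

# Stop with a message unless cond holds; msg may use sprintf-style args.
stopifnot_msg <- function(cond, msg, ...) {
  if (!isTRUE(cond)) abort(sprintf(msg, ...))
  invisible(TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

beat_labels <- c("normal", "ectopic", "tdp")

assert_beat_series <- function(series) {
  stopifnot_msg(is.data.frame(series), "`series` must be a data frame")
  needed <- c("time_s", "rr_ms", "qt_ms", "label", "phase")
  missing <- setdiff(needed, names(series))
  stopifnot_msg(length(missing) == 0,
                "beat series is missing columns: %s",
                paste(missing, collapse = ", "))
  stopifnot_msg(all(diff(series$time_s) > 0),
                "beat times must be strictly increasing")
  bad <- setdiff(unique(series$label), beat_labels)
  stopifnot_msg(length(bad) == 0,
                "unknown beat label(s): %s", paste(bad, collapse = ", "))
  invisible(series)
}
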
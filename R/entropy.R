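#' Ordinal-pattern configuration
#'
#' Parameters of the ordinal-pattern entropies. Ties are broken by order of
#' occurrence (the earlier sample ranks lower) by default; `tie = "dither"`
#' instead perturbs tied samples with tiny seeded noise.
#'
#' @param m Pattern order (embedding dimension), >= 2; default 4.
#' @param tau Embedding delay, >= 1; default 1.
#' @param A Amplitude-adjustment coefficient in \[0, 1\] mixing the mean
#'   absolute amplitude term (weight A/m) with the mean absolute
#'   amplitude-difference term (weight (1-A)/(m-1)); default 0.5, the
#'   standard choice.
#' @param base Logarithm base for the entropy (default natural).
#' @param tie `"earlier"` (default) or `"dither"`.
#' @return A list of class `ordinal_config`.
#' @export
ordinal_config <- function(m = 4, tau = 1, A = 0.5, base = exp(1),
                           tie = c("earlier", "dither")) {
  tie <- match.arg(tie)
  stopifnot_msg(m >= 2, "`m` must be at least 2")
  stopifnot_msg(tau >= 1, "`tau` must be at least 1")
  stopifnot_msg(A >= 0 && A <= 1, "`A` must be in [0, 1]")
  structure(list(m = as.integer(m), tau = as.integer(tau), A = A,
                 base = base, tie = tie),
            class = "ordinal_config")
}

# Embed a series into the n_vec x m matrix of delay vectors.
embed_series <- function(x, m, tau) {
  n_vec <- length(x) - (m - 1) * tau
  stopifnot_msg(n_vec >= 1, "series too short: need at least %d samples",
                (m - 1) * tau + 1)
  idx <- seq_len(n_vec)
  vapply(seq_len(m), function(k) x[idx + (k - 1) * tau],
         numeric(n_vec)) |> matrix(nrow = n_vec)
}

# Rank matrix (0-based) with ties broken by order of occurrence.
rank_matrix <- function(E) {
  m <- ncol(E)
  R <- matrix(0L, nrow(E), m)
  for (k in seq_len(m)) {
    r <- integer(nrow(E))
    for (j in seq_len(m)) {
      if (j == k) next
      r <- r + (E[, j] < E[, k]) + (E[, j] == E[, k] & j < k)
    }
    R[, k] <- r
  }
  R
}

#' Ordinal pattern of a window
#'
#' Maps a length-m window to the index of its rank permutation in
#' `[0, factorial(m))` via the Lehmer code. Ties are broken by the configured
#' rule (default: the earlier sample ranks lower). The map is bijective over
#' distinct-valued windows: the ascending window is 0 and the descending one
#' is `factorial(m) - 1`.
#'
#' @param window Numeric vector of length m (m >= 2).
#' @param tie Tie rule, as in [ordinal_config()].
#' @return Integer pattern index.
#' @export
#' @examples
#' ordinal_pattern(c(1, 2)) # 0 (ascending)
#' ordinal_pattern(c(2, 1)) # 1 (descending)
ordinal_pattern <- function(window, tie = "earlier") {
  m <- length(window)
  stopifnot_msg(m >= 2, "window must have at least 2 values")
  if (tie == "dither" && anyDuplicated(window)) {
    window <- window + seq_along(window) * 1e-12 * max(abs(window), 1)
  }
  r <- as.integer(rank_matrix(matrix(window, nrow = 1)))
  lehmer_index(matrix(r, nrow = 1))[1]
}

# Lehmer-code index of each row of a 0-based rank matrix.
lehmer_index <- function(R) {
  m <- ncol(R)
  idx <- numeric(nrow(R))
  for (i in seq_len(m - 1)) {
    code <- rowSums(R[, (i + 1):m, drop = FALSE] < R[, i])
    idx <- idx + code * factorial(m - i)
  }
  as.integer(idx)
}

# Shared core: per-vector weights aggregated by pattern, Shannon entropy.
ordinal_entropy <- function(x, config, amplitude_aware) {
  m <- config$m; tau <- config$tau
  x <- as.numeric(x)
  stopifnot_msg(length(x) >= (m - 1) * tau + 1,
                "series too short for m = %d, tau = %d", m, tau)
  if (config$tie == "dither") {
    x <- x + stats::runif(length(x), -1, 1) * 1e-12 * max(abs(x), 1)
  }
  E <- embed_series(x, m, tau)
  key <- lehmer_index(rank_matrix(E))
  if (amplitude_aware) {
    A <- config$A
    amp <- rowSums(abs(E)) * (A / m)
    dif <- rowSums(abs(E[, -1, drop = FALSE] - E[, -m, drop = FALSE])) *
      ((1 - A) / (m - 1))
    w <- amp + dif
    if (sum(w) == 0) w <- rep(1, length(w)) # all-zero series: count patterns
  } else {
    w <- rep(1, length(key))
  }
  tot <- rowsum(w, key)
  p <- as.numeric(tot) / sum(tot)
  p <- p[p > 0]
  -sum(p * log(p, base = config$base))
}

#' Amplitude-aware permutation entropy
#'
#' Ordinal-pattern entropy in which each embedded vector contributes a weight
#' `(A/m) * sum(|x_k|) + ((1-A)/(m-1)) * sum(|x_k - x_(k-1)|)` to its
#' pattern's probability (weights are normalized over all vectors before the
#' Shannon entropy). Sensitive to amplitude irregularity that pure
#' ordinal-count entropy ([repe()]) ignores; invariant under positive
#' rescaling of the series.
#'
#' @param series Numeric series.
#' @param config An [ordinal_config()].
#' @return Entropy value in `[0, log(factorial(m))]` (configured base).
#' @export
#' @examples
#' aape(c(4, 1, 3, 2, 5), ordinal_config(m = 2)) # ~0.6902 nats
aape <- function(series, config = ordinal_config()) {
  ordinal_entropy(series, config, amplitude_aware = TRUE)
}

#' Robust empirical permutation entropy
#'
#' Count-based ordinal-pattern entropy: every embedded vector contributes
#' weight one. Equals [aape()] whenever all vectors carry identical amplitude
#' weight, and is invariant under strictly monotone transforms of the series.
#'
#' @inheritParams aape
#' @return Entropy value in `[0, log(factorial(m))]`.
#' @export
repe <- function(series, config = ordinal_config()) {
  ordinal_entropy(series, config, amplitude_aware = FALSE)
}

#' Information-exergy index configuration
#'
#' Parameters of the [iein_sigma()] reconstruction: the windowed-entropy
#' trace (window length and hop, in samples of the analyzed series; ordinal
#' order of the trace windows), and the block analysis of the trace
#' (trace points per block, trajectory-matrix embedding dimension).
#'
#' @param window Samples per entropy window (default 250).
#' @param hop Hop between windows (default half the window).
#' @param trace_m Ordinal order used inside each window (default 3).
#' @param block_len Trace points per block (default 16).
#' @param embed_dim Rows of the block trajectory (Hankel) matrix (default 4).
#' @return A list of class `iein_config`.
#' @export
iein_config <- function(window = 250, hop = window %/% 2, trace_m = 3,
                        block_len = 16, embed_dim = 4) {
  stopifnot_msg(window >= trace_m + 1, "`window` must exceed `trace_m`")
  stopifnot_msg(hop >= 1, "`hop` must be >= 1")
  stopifnot_msg(block_len > embed_dim, "`block_len` must exceed `embed_dim`")
  structure(list(window = as.integer(window), hop = as.integer(hop),
                 trace_m = as.integer(trace_m),
                 block_len = as.integer(block_len),
                 embed_dim = as.integer(embed_dim)),
            class = "iein_config")
}

#' Information-exergy index (sigma)
#'
#' An SVD-based summary of how the irregularity of a record develops in
#' time, reconstructed as a concrete, versioned pipeline:
#' (1) a windowed ordinal-entropy trace of the series; (2) a block-wise
#' Hankel trajectory matrix of the trace; (3) singular values per block;
#' (4) energy shares `p_i = s_i^2 / sum(s_j^2)`; (5) per-block exergy =
#' block energy times the Shannon information of the shares; (6) sigma =
#' the standard deviation of block exergy across the record. Records whose
#' irregularity drifts over time therefore score higher sigma than
#' stationary records of equal global entropy; sigma is always >= 0 and
#' deterministic for a fixed input.
#'
#' @param series Numeric series (enough samples for two blocks).
#' @param config An [iein_config()].
#' @return Sigma (non-negative scalar).
#' @export
iein_sigma <- function(series, config = iein_config()) {
  w <- config$window; h <- config$hop
  x <- as.numeric(series)
  starts <- seq(1, length(x) - w + 1, by = h)
  ord <- ordinal_config(m = config$trace_m)
  stopifnot_msg(length(starts) >= 2 * config$block_len,
                "record too short for two blocks (%d windows, need %d)",
                length(starts), 2 * config$block_len)
  trace <- vapply(starts, function(s) repe(x[s:(s + w - 1)], ord), numeric(1))
  n_blocks <- length(trace) %/% config$block_len
  d <- config$embed_dim
  exergy <- vapply(seq_len(n_blocks), function(b) {
    seg <- trace[((b - 1) * config$block_len + 1):(b * config$block_len)]
    ncol_h <- length(seg) - d + 1
    H <- vapply(seq_len(ncol_h), function(j) seg[j:(j + d - 1)], numeric(d))
    s <- svd(matrix(H, nrow = d), nu = 0, nv = 0)$d
    e <- s^2
    tot <- sum(e)
    if (tot == 0) return(0)
    p <- e / tot
    p <- p[p > 0]
    tot * (-sum(p * log(p)))
  }, numeric(1))
  sd(exergy)
}

# Decimate with a moving-average anti-alias filter, then subsample.
decimate_series <- function(x, factor) {
  if (factor <= 1) return(x)
  k <- as.integer(factor)
  f <- stats::filter(x, rep(1 / k, k), sides = 2)
  f[is.na(f)] <- x[is.na(f)]
  as.numeric(f)[seq(1, length(x), by = k)]
}

#' Baseline entropy analysis of one animal
#'
#' Computes AAPE and IEIN sigma on the baseline segment of an ECG record.
#' The analysis operates on the raw waveform samples, decimated to
#' `target_fs_hz` so that the m-sample ordinal windows span a few
#' milliseconds of signal rather than quantization noise; an interval-level
#' variant (AAPE of the baseline RR series) is used automatically when a
#' `beat_series` is supplied instead of a waveform. Records without a
#' baseline segment of at least `min_seconds` are excluded with a reason
#' rather than analyzed.
#'
#' @param x An `ecg_waveform` or a `beat_series`.
#' @param config An [ordinal_config()] for AAPE.
#' @param iein An [iein_config()].
#' @param segment_s Length-2 numeric, the analyzed segment in seconds
#'   (default: the first `max_seconds` of the record/baseline).
#' @param max_seconds Default segment length (60 s).
#' @param min_seconds Minimum acceptable segment (20 s).
#' @param target_fs_hz Decimation target for waveform input (250 Hz).
#' @return A one-row tibble of class `entropy_result`: `aape`, `iein_sigma`,
#'   `segment_start_s`, `segment_end_s`, `excluded`, `reason`; the configs
#'   are attached as attributes.
#' @export
entropy_for_animal <- function(x, config = ordinal_config(),
                               iein = iein_config(),
                               segment_s = NULL,
                               max_seconds = 60, min_seconds = 20,
                               target_fs_hz = 250) {
  excluded <- function(reason) {
    out <- tibble::tibble(aape = NA_real_, iein_sigma = NA_real_,
                          segment_start_s = NA_real_, segment_end_s = NA_real_,
                          excluded = TRUE, reason = reason)
    class(out) <- c("entropy_result", class(out))
    out
  }
  if (inherits(x, "ecg_waveform")) {
    fs <- waveform_fs(x)
    t_max <- max(x$time_s)
    seg <- segment_s %||% c(0, min(max_seconds, t_max))
    if (diff(seg) < min_seconds) {
      return(excluded(sprintf(
        "artifact-free segment too short (%.1f s < %g s)", diff(seg),
        min_seconds)))
    }
    samp <- x$mv[x$time_s >= seg[1] & x$time_s < seg[2]]
    dec <- max(1L, round(fs / target_fs_hz))
    series <- decimate_series(samp, dec)
  } else {
    assert_beat_series(x)
    win <- x[x$phase == x$phase[1], ]
    seg <- segment_s %||% range(win$time_s)
    if (diff(seg) < min_seconds) {
      return(excluded(sprintf(
        "baseline segment too short (%.1f s < %g s)", diff(seg), min_seconds)))
    }
    series <- win$rr_ms[win$time_s >= seg[1] & win$time_s <= seg[2]]
  }
  out <- tibble::tibble(
    aape = aape(series, config),
    iein_sigma = tryCatch(iein_sigma(series, iein),
                          error = function(e) NA_real_),
    segment_start_s = seg[1], segment_end_s = seg[2],
    excluded = FALSE, reason = NA_character_
  )
  attr(out, "ordinal_config") <- config
  attr(out, "iein_config") <- iein
  class(out) <- c("entropy_result", class(out))
  out
}
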
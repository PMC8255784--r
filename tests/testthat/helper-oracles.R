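# Independent oracles used across the suite. These deliberately re-derive
# each quantity by the most literal route available (explicit loops, direct
# formula evaluation) so they share no code with the implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force amplitude-aware permutation entropy: explicit enumeration of
# every embedded vector, weights accumulated in a keyed list.
oracle_aape <- function(x, m, tau = 1, A = 0.5, counts_only = FALSE) {
  n_vec <- length(x) - (m - 1) * tau
  w <- list()
  for (i in seq_len(n_vec)) {
    v <- x[i + (0:(m - 1)) * tau]
    key <- paste(rank(v, ties.method = "first"), collapse = "-")
    wt <- if (counts_only) 1 else {
      (A / m) * sum(abs(v)) + ((1 - A) / (m - 1)) * sum(abs(diff(v)))
    }
    w[[key]] <- (w[[key]] %||% 0) + wt
  }
  tot <- unlist(w)
  if (sum(tot) == 0) tot <- rep(1, length(tot))
  p <- tot / sum(tot)
  stopifnot(abs(sum(p) - 1) < 1e-12)
  -sum(p * log(p))
}

# Direct STV formula: sum of absolute consecutive differences over the last
# (n_diffs + 1) values, divided by n_diffs * sqrt(2).
oracle_stv <- function(d, n_diffs = 30) {
  d <- d[(length(d) - n_diffs):length(d)]
  s <- 0
  for (i in 2:length(d)) s <- s + abs(d[i] - d[i - 1])
  s / (n_diffs * sqrt(2))
}

# Classical periodogram |DFT|^2 / n of a mean-centred series at frequency f.
oracle_periodogram <- function(t, y, f) {
  y <- y - mean(y)
  Mod(sum(y * exp(-2i * pi * f * t)))^2 / length(y)
}

# Match detected against true event times within a tolerance; returns
# precision/recall/F1.
peak_prf <- function(detected, truth, tol_s) {
  tp <- 0
  used <- rep(FALSE, length(detected))
  for (tt in truth) {
    d <- abs(detected - tt)
    j <- which(!used & d < tol_s)
    if (length(j) > 0) {
      used[j[which.min(d[j])]] <- TRUE
      tp <- tp + 1
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0 else
    2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec, f1 = f1, tp = tp, fp = fp, fn = fn)
}

# Event-level F1: an episode matches a truth event when kinds agree and the
# time spans overlap (with tol_s slack).
event_prf <- function(found, truth, tol_s = 0.5) {
  used <- rep(FALSE, nrow(found))
  tp <- 0
  for (i in seq_len(nrow(truth))) {
    hit <- which(!used &
                   found$kind == truth$kind[i] &
                   found$start_time_s < truth$end_time_s[i] + tol_s &
                   found$end_time_s > truth$start_time_s[i] - tol_s)
    if (length(hit) > 0) {
      used[hit[1]] <- TRUE
      tp <- tp + 1
    }
  }
  fp <- nrow(found) - tp
  fn <- nrow(truth) - tp
  2 * tp / max(2 * tp + fp + fn, 1)
}

# Compact single-phase profile for fast test series.
test_profile <- function(rr = 380, rr_sd = 10, qt = 220, qt_sd = 0,
                         jitter = 0, mod = tibble::tibble(freq_hz = numeric(),
                                                          amp_ms = numeric()),
                         phases = "baseline") {
  n <- length(phases)
  group_profile("test",
                rr_mean_ms = stats::setNames(rep_len(rr, n), phases),
                rr_sd_ms = stats::setNames(rep_len(rr_sd, n), phases),
                qt_mean_ms = stats::setNames(rep_len(qt, n), phases),
                qt_sd_ms = stats::setNames(rep_len(qt_sd, n), phases),
                qtc_jitter_ms = jitter, rr_mod = mod)
}
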
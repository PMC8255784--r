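test_that("constant RR yields (near) zero power everywhere", {
  t <- cumsum(rep(0.4, 60))
  ps <- lomb_scargle(t, rep(400, 60))
  expect_true(all(ps$power_norm == 0))
  expect_equal(band_power(ps, 0.04, 0.40), 0)
})

test_that("Lomb-Scargle equals the classical periodogram on even sampling", {
  set.seed(3)
  n <- 256; dt <- 0.5
  t <- (0:(n - 1)) * dt
  y <- 12 * sin(2 * pi * 0.11 * t) + 4 * cos(2 * pi * 0.23 * t) + rnorm(n)
  freqs <- (1:100) / (n * dt) # Fourier frequencies
  ps <- lomb_scargle(t, y, freqs)
  cl <- vapply(freqs, function(f) oracle_periodogram(t, y, f), numeric(1))
  rel <- abs(ps$power_norm - cl / var(y)) / pmax(cl / var(y), 1e-10)
  expect_lt(max(rel), 1e-6)
})

test_that("injected RR modulations are recovered in the correct band", {
  mk <- function(f_hz) {
    make_beat_series(
      test_profile(rr_sd = 3, jitter = 0,
                   mod = tibble::tibble(freq_hz = f_hz, amp_ms = 10)),
      phase_protocol("baseline", 600), seed = 4)
  }
  s_lf <- baseline_window(mk(0.10))
  ps_lf <- lomb_scargle(s_lf$time_s, s_lf$rr_ms)
  peak <- ps_lf$freq_hz[which.max(ps_lf$power_norm)]
  expect_lt(abs(peak - 0.10), 0.005 + 1e-9) # within one grid step
  expect_gt(band_power(ps_lf, 0.04, 0.15) / band_power(ps_lf, 0.15, 0.40), 10)

  s_hf <- baseline_window(mk(0.30))
  ps_hf <- lomb_scargle(s_hf$time_s, s_hf$rr_ms)
  expect_gt(band_power(ps_hf, 0.15, 0.40) / band_power(ps_hf, 0.04, 0.15), 10)
})

test_that("band powers are additive across a split", {
  s <- baseline_window(make_beat_series(test_profile(rr_sd = 8, jitter = 0),
                                        phase_protocol("baseline", 420),
                                        seed = 5))
  ps <- lomb_scargle(s$time_s, s$rr_ms)
  lf <- band_power(ps, 0.04, 0.15)
  hf <- band_power(ps, 0.15, 0.40)
  expect_equal(lf + hf, band_power(ps, 0.04, 0.40), tolerance = 1e-9)
  expect_error(band_power(ps, 0.3, 0.3), "empty band")
  expect_error(band_power(ps, 0.3, 0.9), "outside")
})

test_that("total band power grows with modulation amplitude", {
  pw <- vapply(c(2, 6, 12), function(a) {
    s <- baseline_window(make_beat_series(
      test_profile(rr_sd = 2, jitter = 0,
                   mod = tibble::tibble(freq_hz = 0.12, amp_ms = a)),
      phase_protocol("baseline", 420), seed = 6))
    band_power(lomb_scargle(s$time_s, s$rr_ms), 0.04, 0.40)
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("lf_hf_ratio handles the trivial and degenerate cases", {
  expect_equal(lf_hf_ratio(3, 3), 1)
  expect_equal(lf_hf_ratio(2, 4), 0.5)
  expect_warning(r <- lf_hf_ratio(2, 0), "undefined")
  expect_true(is.na(r))
})

test_that("baseline_window honours the half-open last-5-minutes convention", {
  s <- make_beat_series(test_profile(), phase_protocol("baseline", 600),
                        seed = 7)
  win <- baseline_window(s)
  expect_true(all(win$time_s >= 300 & win$time_s < 600))
  expect_gt(min(win$time_s), 299)
  # a beat exactly at 300.0 s is included
  s300 <- s
  s300$time_s[min(which(s$time_s >= 300))] <- 300.0
  expect_true(300.0 %in% baseline_window(s300)$time_s)

  short <- make_beat_series(test_profile(), phase_protocol("baseline", 300),
                            seed = 8)
  expect_equal(nrow(baseline_window(short)), nrow(short))
  tiny <- make_beat_series(test_profile(), phase_protocol("baseline", 120),
                           seed = 9)
  expect_warning(w <- baseline_window(tiny), "shorter")
  expect_equal(nrow(w), nrow(tiny))
})

test_that("RR cleaning protects band powers from a single ectopic", {
  s <- baseline_window(make_beat_series(
    test_profile(rr_sd = 2, jitter = 0,
                 mod = tibble::tibble(freq_hz = 0.25, amp_ms = 8)),
    phase_protocol("baseline", 420), seed = 10))
  rr <- s$rr_ms
  rr_ect <- rr
  rr_ect[300] <- rr[300] * 1.9 # one gross ectopic interval
  total <- function(x) band_power(lomb_scargle(s$time_s, x), 0.04, 0.40)
  raw_shift <- abs(total(rr_ect) - total(rr)) / total(rr)
  cleaned <- clean_rr(rr_ect)$rr_ms
  clean_shift <- abs(total(cleaned) - total(rr)) / total(rr)
  expect_gt(raw_shift, 0.20)
  expect_lt(clean_shift, 0.05)
})

test_that("suppressed HF modulation raises the LF/HF ratio", {
  ratio_for <- function(hf_amp, seed) {
    s <- baseline_window(make_beat_series(
      test_profile(rr_sd = 4, jitter = 0,
                   mod = tibble::tibble(freq_hz = c(0.10, 0.30),
                                        amp_ms = c(6, hf_amp))),
      phase_protocol("baseline", 420), seed = seed))
    cl <- clean_rr(s$rr_ms)$rr_ms
    ps <- lomb_scargle(s$time_s, cl)
    band_power(ps, 0.04, 0.15) / band_power(ps, 0.15, 0.40)
  }
  wins <- vapply(1:20, function(seed) {
    ratio_for(2, seed) > ratio_for(6, seed)
  }, logical(1))
  expect_gte(mean(wins), 0.9) # paired sign test, one-sided
})

test_that("hrv_analysis chains window, cleaning and spectrum", {
  pr <- test_profile(rr_sd = 4, jitter = 3,
                     mod = tibble::tibble(freq_hz = c(0.10, 0.30),
                                          amp_ms = c(6, 6)))
  s <- make_beat_series(pr, phase_protocol("baseline", 600), seed = 11)
  res <- hrv_analysis(s)
  expect_s3_class(res, "hrv_result")
  expect_true(res$lf > 0 && res$hf > 0)
  expect_equal(res$lf_hf, res$lf / res$hf)
  expect_gte(res$window_start_s, 300)
})
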
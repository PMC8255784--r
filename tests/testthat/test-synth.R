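test_that("zero-variance profile yields constant intervals in every phase", {
  pr <- test_profile(rr = 400, rr_sd = 0, qt = 220, qt_sd = 0, jitter = 0,
                     phases = c("baseline", "methoxamine"))
  s <- make_beat_series(pr, phase_protocol(c("baseline", "methoxamine"),
                                           c(30, 30)), seed = 1)
  expect_true(all(abs(s$rr_ms - 400) < 1e-9))
  expect_true(all(abs(s$qt_ms - 220) < 1e-9))
})

test_that("generated phase means hit the profile targets within 3 SE", {
  s <- make_beat_series(profile_yc(),
                        phase_protocol(c("baseline", "methoxamine"),
                                       c(600, 600)), seed = 1)
  base <- s[s$phase == "baseline", ]
  n <- nrow(base)
  expect_lt(abs(mean(base$rr_ms) - 381), 3 * 66 / sqrt(n))
  expect_lt(abs(mean(base$qt_ms) - 220), 3 * sd(base$qt_ms) / sqrt(n))
  met <- s[s$phase == "methoxamine", ]
  expect_lt(abs(mean(met$rr_ms) - 502), 3 * 81 / sqrt(nrow(met)))
})

test_that("beat times are monotone and RR-consistent across random seeds", {
  pr <- test_profile(rr_sd = 40, jitter = 5)
  proto <- phase_protocol("baseline", 30)
  for (seed in 1:100) {
    s <- make_beat_series(pr, proto, seed = seed)
    expect_true(all(diff(s$time_s) > 0))
    expect_lt(max(abs(diff(s$time_s) * 1000 - s$rr_ms[-1])), 1e-6)
    expect_true(all(s$qt_ms < s$rr_ms))
  }
})

test_that("series generation is deterministic for a fixed seed", {
  pr <- test_profile(rr_sd = 30, jitter = 4)
  a <- make_beat_series(pr, phase_protocol("baseline", 60), seed = 9)
  b <- make_beat_series(pr, phase_protocol("baseline", 60), seed = 9)
  expect_identical(a, b)
})

test_that("incompatible interval means are rejected naming the phase", {
  expect_error(
    group_profile("bad",
                  rr_mean_ms = c(baseline = 300),
                  rr_sd_ms = c(baseline = 10),
                  qt_mean_ms = c(baseline = 320),
                  qt_sd_ms = c(baseline = 5)),
    "baseline")
  expect_error(phase_protocol("baseline", -5), "positive")
})

test_that("zero rates and no bigeminy leave the series unchanged", {
  s <- make_beat_series(test_profile(), phase_protocol("baseline", 60),
                        seed = 2)
  expect_identical(inject_ectopy(s, 0, 0, FALSE, seed = 1), s)
  expect_identical(inject_tdp(s, 0), s)
})

test_that("MEB runs have 2-4 beats and ectopic RR deviates > 25%", {
  s <- make_beat_series(test_profile(), phase_protocol("baseline", 600),
                        seed = 3)
  s2 <- inject_ectopy(s, seb_rate = 1, meb_rate = 3, seed = 11)
  ev <- truth_events(s2)
  meb <- ev[ev$kind == "MEB", ]
  expect_gt(nrow(meb), 0)
  expect_true(all(meb$n_beats %in% 2:4))
  ect <- which(s2$label == "ectopic")
  m <- mean(s$rr_ms)
  expect_true(all(abs(s2$rr_ms[ect] - m) / m > 0.25))
})

test_that("ectopy event counts are Poisson with the stated rate", {
  s <- make_beat_series(test_profile(), phase_protocol("baseline", 600),
                        seed = 4)
  counts <- vapply(1:100, function(seed) {
    nrow(truth_events(inject_ectopy(s, seb_rate = 2, seed = seed)))
  }, numeric(1))
  # mean of 100 Poisson(20) draws: SE = sqrt(20/100)
  expect_lt(abs(mean(counts) - 20), 4 * sqrt(20 / 100))
})

test_that("overwhelming ectopy rates are rejected rather than overlapped", {
  s <- make_beat_series(test_profile(), phase_protocol("baseline", 30),
                        seed = 5)
  expect_error(inject_ectopy(s, seb_rate = 2000, seed = 1), "overlap")
})

test_that("ground-truth events agree exactly with label runs", {
  s <- make_beat_series(test_profile(), phase_protocol("baseline", 600),
                        seed = 6)
  s2 <- inject_ectopy(s, seb_rate = 2, meb_rate = 1, bigeminy = TRUE,
                      seed = 21)
  s2 <- inject_tdp(s2, n_episodes = 2, episode_beats = c(6, 9), seed = 22)
  truth <- truth_events(s2)
  found <- classify_runs(s2$label, s2$time_s)
  expect_equal(as.data.frame(found),
               as.data.frame(truth[order(truth$start_beat), names(found)]))
})

test_that("TdP injection enforces the five-beat minimum and records spans", {
  s <- make_beat_series(test_profile(), phase_protocol("baseline", 120),
                        seed = 7)
  expect_error(inject_tdp(s, 1, episode_beats = 4), "at least 5")
  s2 <- inject_tdp(s, 3, episode_beats = 8, seed = 2)
  ev <- truth_events(s2)
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$n_beats == 8))
  expect_true(tdp_inducible(classify_runs(s2$label, s2$time_s)))
  # a single long episode (> 10 s of beat time) is inducible on its own
  s3 <- inject_tdp(s, 1, episode_beats = 90, seed = 3)
  ev3 <- truth_events(s3)
  expect_gt(ev3$end_time_s - ev3$start_time_s, 10)
  expect_true(tdp_inducible(classify_runs(s3$label, s3$time_s)))
})

test_that("rendering is deterministic and places R peaks at fiducials", {
  s <- make_beat_series(test_profile(), phase_protocol("baseline", 20),
                        seed = 8)
  w1 <- render_waveform(s, fs_hz = 500, noise_sd_mv = 0.02, seed = 3)
  w2 <- render_waveform(s, fs_hz = 500, noise_sd_mv = 0.02, seed = 3)
  expect_identical(w1$mv, w2$mv)

  w <- render_waveform(s, fs_hz = 1000, noise_sd_mv = 0, seed = 1)
  fid <- waveform_fiducials(w)
  for (r in fid$r) {
    lo <- max(1, r - 3); hi <- min(nrow(w), r + 3)
    expect_equal(which.max(w$mv[lo:hi]) + lo - 1L, r)
  }
})

test_that("rendered TdP complexes alternate polarity across the episode", {
  s <- make_beat_series(test_profile(), phase_protocol("baseline", 60),
                        seed = 9)
  s2 <- inject_tdp(s, 1, episode_beats = 8, seed = 4)
  w <- render_waveform(s2, fs_hz = 1000, noise_sd_mv = 0, seed = 1)
  fid <- waveform_fiducials(w)
  tdp_idx <- which(s2$label == "tdp")
  peaks <- w$mv[fid$r[tdp_idx]]
  signs <- sign(peaks)
  expect_true(all(diff(signs) != 0)) # strict alternation
})

test_that("cohort responder status follows the configured propensity", {
  proto <- phase_protocol(c("baseline", "dofetilide_high"), c(30, 120))
  mk <- function(p) {
    pr <- test_profile(phases = c("baseline", "dofetilide_high"))
    pr$tdp_propensity <- p
    pr
  }
  coh0 <- generate_cohort(mk(0), n_per_group = 10, seed = 5, protocol = proto)
  expect_false(any(coh0$responder))
  coh <- generate_cohort(mk(0.8), n_per_group = 120, seed = 7,
                         protocol = proto)
  p_hat <- mean(coh$responder)
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / 120))
  # responders are inducible by construction
  ind <- vapply(which(coh$responder), function(i) {
    tdp_inducible(classify_runs(coh$series[[i]]$label,
                                coh$series[[i]]$time_s))
  }, logical(1))
  expect_true(all(ind))
})

test_that("cohort writing and reading round-trips beat tables and truth", {
  proto <- phase_protocol(c("baseline", "dofetilide_high"), c(30, 60))
  pr <- test_profile(phases = c("baseline", "dofetilide_high"))
  pr$tdp_propensity <- 1
  coh <- generate_cohort(pr, n_per_group = 2, seed = 11, protocol = proto)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$animal_id, coh$animal_id)
  expect_equal(back$truth_category, coh$truth_category)
  for (i in seq_len(nrow(coh))) {
    expect_equal(back$series[[i]]$rr_ms, coh$series[[i]]$rr_ms,
                 tolerance = 1e-8)
    expect_equal(as.data.frame(truth_events(back$series[[i]]))$kind,
                 as.data.frame(truth_events(coh$series[[i]]))$kind)
  }
})
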
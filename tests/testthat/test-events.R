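mk_times <- function(labels, rr_s = 0.4) cumsum(rep(rr_s, length(labels)))

test_that("run-length classification follows the event definitions", {
  lab <- c("normal", "ectopic", "normal")
  ep <- classify_runs(lab, mk_times(lab))
  expect_equal(ep$kind, "SEB")
  expect_equal(ep$n_beats, 1L)

  lab <- c("normal", rep("ectopic", 3), "normal")
  ep <- classify_runs(lab, mk_times(lab))
  expect_equal(ep$kind, "MEB")
  expect_equal(ep$n_beats, 3L)

  lab <- c("normal", rep("tdp", 5), "normal")
  ep <- classify_runs(lab, mk_times(lab))
  expect_equal(ep$kind, "TdP")
  expect_equal(ep$n_beats, 5L)

  expect_equal(nrow(classify_runs(rep("normal", 10), mk_times(rep("n", 10)))),
               0L)
  expect_error(classify_runs(c("normal", "weird"), c(0.4, 0.8)), "unknown")
})

test_that("bigeminy subsumes at least three alternating isolated ectopics", {
  lab <- c("normal", "ectopic", "normal", "ectopic", "normal", "ectopic",
           "normal")
  ep <- classify_runs(lab, mk_times(lab))
  expect_equal(ep$kind, "bigeminy")
  expect_equal(ep$n_beats, 3L)
  # two alternations stay SEBs
  lab2 <- c("normal", "ectopic", "normal", "ectopic", "normal")
  ep2 <- classify_runs(lab2, mk_times(lab2))
  expect_equal(ep2$kind, c("SEB", "SEB"))
})

test_that("each beat belongs to at most one episode", {
  set.seed(8)
  for (i in 1:20) {
    lab <- sample(c("normal", "ectopic", "tdp"), 80, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1))
    ep <- classify_runs(lab, mk_times(lab))
    if (nrow(ep) < 2) next
    spans <- mapply(seq, ep$start_beat, ep$end_beat, SIMPLIFY = FALSE)
    expect_false(any(duplicated(unlist(spans))))
  }
})

test_that("inducibility requires three episodes or one lasting over 10 s", {
  ep3 <- tibble::tibble(kind = "TdP", start_time_s = c(10, 50, 90),
                        end_time_s = c(12, 52, 92))
  expect_true(tdp_inducible(ep3))
  ep1 <- tibble::tibble(kind = "TdP", start_time_s = 10, end_time_s = 21)
  expect_true(tdp_inducible(ep1))
  ep_border <- tibble::tibble(kind = "TdP", start_time_s = c(10, 40),
                              end_time_s = c(20, 50)) # exactly 10.0 s each
  expect_false(tdp_inducible(ep_border))
  expect_false(tdp_inducible(ep_border[0, ]))
})

test_that("termination fires at 20 s of persistent TdP, else at protocol end", {
  proto <- phase_protocol()
  ep <- tibble::tibble(kind = "TdP", start_time_s = 2000, end_time_s = 2025)
  res <- termination_check(ep, proto)
  expect_true(res$early)
  expect_equal(res$time_s, 2020)
  ep19 <- tibble::tibble(kind = "TdP", start_time_s = 2000,
                         end_time_s = 2019)
  res19 <- termination_check(ep19, proto)
  expect_false(res19$early)
  expect_equal(res19$time_s, 3600)
  none <- termination_check(ep19[0, ], proto)
  expect_equal(none$time_s, 3600)
})

test_that("outcome categories and pre-TdP ectopy flags compose correctly", {
  expect_equal(outcome_category(classify_runs(rep("normal", 5),
                                              mk_times(rep("n", 5))))$category,
               "no_arrhythmia")

  lab_meb <- c("normal", rep("ectopic", 2), "normal")
  expect_equal(outcome_category(classify_runs(lab_meb,
                                              mk_times(lab_meb)))$category,
               "non_tdp")

  # inducible TdP with an SEB before onset: tdp category, seb flag set
  lab <- c("normal", "ectopic", rep("normal", 3),
           rep(c(rep("tdp", 5), "normal"), 3),
           "ectopic", "normal")
  out <- outcome_category(classify_runs(lab, mk_times(lab)), "a1")
  expect_equal(out$category, "tdp")
  expect_true(out$inducible)
  expect_true(out$seb_present)
  expect_equal(out$n_tdp, 3L)

  # ectopy only after the first TdP onset does not set the flags
  lab2 <- c(rep("normal", 2), rep(c(rep("tdp", 5), "normal"), 3),
            "ectopic", "normal")
  out2 <- outcome_category(classify_runs(lab2, mk_times(lab2)))
  expect_equal(out2$category, "tdp")
  expect_false(out2$seb_present)
})

test_that("incidence reproduces the published percentages half-up", {
  expect_equal(incidence(10, 12)$percent, 83L)
  expect_equal(incidence(2, 11)$percent, 18L)
  expect_equal(incidence(3, 14)$percent, 21L)
  expect_equal(incidence(7, 11)$percent, 64L)
  expect_error(incidence(1, 0), "empty")
  expect_error(incidence(5, 3), "between")
  out <- tibble::tibble(inducible = c(TRUE, TRUE, FALSE))
  expect_equal(incidence(out, function(d) d$inducible)$percent, 67L)
})

test_that("label-mode classification recovers generator truth exactly", {
  s <- make_beat_series(test_profile(), phase_protocol("baseline", 600),
                        seed = 10)
  s <- inject_ectopy(s, seb_rate = 1.5, meb_rate = 0.8, bigeminy = TRUE,
                     seed = 2)
  s <- inject_tdp(s, 3, episode_beats = c(6, 8, 12), seed = 3)
  truth <- truth_events(s)
  found <- classify_runs(s$label, s$time_s)
  expect_equal(event_prf(found, truth), 1)
  expect_equal(nrow(found), nrow(truth))
})

test_that("waveform-mode classification reaches F1 >= 0.95 at default noise", {
  s <- make_beat_series(test_profile(rr = 420, rr_sd = 8, jitter = 2),
                        phase_protocol("baseline", 300), seed = 12)
  s <- inject_ectopy(s, seb_rate = 2, meb_rate = 1, seed = 4)
  s <- inject_tdp(s, 2, episode_beats = c(7, 10), seed = 5)
  w <- render_waveform(s, fs_hz = 500, noise_sd_mv = 0.02, seed = 6)
  res <- classify_waveform(w)
  expect_gte(event_prf(res$episodes, truth_events(s), tol_s = 1), 0.95)
})
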
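#' Rabbit QT rate-correction constants
#'
#' The rabbit-specific linear QT correction referenced to RR = 300 ms:
#' QTc = QT - slope * (RR - 300). The generator uses its inverse
#' (QT = QTc + slope * (RR - 300)) so that generated QTc is stationary by
#' construction.
#'
#' @format Named numeric vector with elements `slope` (0.175, dimensionless)
#'   and `rr_ref_ms` (300 ms).
#' @export
qtc_rabbit_constants <- c(slope = 0.175, rr_ref_ms = 300)

new_beat_series <- function(time_s, rr_ms, qt_ms, label, phase,
                            protocol = NULL, events = NULL) {
  out <- tibble::tibble(
    time_s = time_s, rr_ms = rr_ms, qt_ms = qt_ms,
    label = label, phase = phase
  )
  attr(out, "protocol") <- protocol
  attr(out, "events") <- events %||%
    tibble::tibble(kind = character(), start_beat = integer(),
                   end_beat = integer(), n_beats = integer(),
                   start_time_s = numeric(), end_time_s = numeric())
  class(out) <- c("beat_series", class(out))
  out
}

# Recompute beat times from the RR sequence (first beat at rr[1]/1000) and
# refresh event times from beat indices.
rebuild_beat_series <- function(rr_ms, qt_ms, label, phase, protocol,
                                events = NULL) {
  time_s <- cumsum(rr_ms) / 1000
  events <- events %||%
    tibble::tibble(kind = character(), start_beat = integer(),
                   end_beat = integer(), n_beats = integer(),
                   start_time_s = numeric(), end_time_s = numeric())
  if (nrow(events) > 0) {
    events$start_time_s <- time_s[events$start_beat]
    events$end_time_s <- time_s[events$end_beat]
  }
  new_beat_series(time_s, rr_ms, qt_ms, label, phase, protocol, events)
}

#' Ground-truth events of a synthetic beat series
#'
#' @param series A `beat_series` created by the generator.
#' @return A tibble of injected events (kind, beat span, times).
#' @export
truth_events <- function(series) {
  attr(series, "events") %||%
    tibble::tibble(kind = character(), start_beat = integer(),
                   end_beat = integer(), n_beats = integer(),
                   start_time_s = numeric(), end_time_s = numeric())
}

#' Simulate a per-beat interval series
#'
#' Generates beat times, RR and QT intervals over the phases of `protocol`.
#' Within each phase, RR is drawn i.i.d. around the phase mean plus the
#' profile's sinusoidal modulations evaluated at the running beat time; the
#' per-beat QTc is the phase QTc target (derived from the phase QT and RR
#' means through the rabbit correction) plus independent Gaussian jitter of
#' scale `qtc_jitter_ms`, and QT is reconstructed as
#' QT = QTc + 0.175 * (RR - 300) so QT co-varies with RR.
#'
#' @param profile A [group_profile()].
#' @param protocol A [phase_protocol()]; its phases must match the profile's.
#' @param seed Integer seed; the series is deterministic given (profile,
#'   protocol, seed).
#' @param rr_offset_ms,qtc_offset_ms Per-animal offsets added to the phase
#'   RR and QTc means (used by [generate_cohort()] for between-animal spread).
#' @return A `beat_series` tibble: `time_s` (strictly increasing), `rr_ms`,
#'   `qt_ms`, `label` (all "normal"), `phase`.
#' @export
#' @examples
#' s <- make_beat_series(profile_yc(), phase_protocol(), seed = 1)
#' head(s)
make_beat_series <- function(profile, protocol = phase_protocol(), seed = 1,
                             rr_offset_ms = 0, qtc_offset_ms = 0) {
  stopifnot_msg(inherits(profile, "group_profile"),
                "`profile` must be a group_profile")
  stopifnot_msg(inherits(protocol, "phase_protocol"),
                "`protocol` must be a phase_protocol")
  missing_ph <- setdiff(protocol$phase, profile$phases)
  stopifnot_msg(length(missing_ph) == 0,
                "profile lacks parameters for phase(s): %s",
                paste(missing_ph, collapse = ", "))
  slope <- qtc_rabbit_constants[["slope"]]
  rr_ref <- qtc_rabbit_constants[["rr_ref_ms"]]

  set.seed(as.integer(seed %% 2147483629))
  rr_all <- numeric(0); qt_all <- numeric(0); phase_all <- character(0)
  t_cur <- 0
  for (i in seq_len(nrow(protocol))) {
    ph <- protocol$phase[i]
    rr_mu <- profile$rr_mean_ms[[ph]] + rr_offset_ms
    rr_sd <- profile$rr_sd_ms[[ph]]
    qt_mu <- profile$qt_mean_ms[[ph]]
    stopifnot_msg(qt_mu < rr_mu, "qt mean >= rr mean in phase '%s'", ph)
    qtc_mu <- qt_mu - slope * (profile$rr_mean_ms[[ph]] - rr_ref) +
      qtc_offset_ms
    phase_end <- protocol$end_s[i]
    n_guess <- ceiling(1000 * protocol$duration_s[i] / max(rr_mu - 3 * rr_sd, 60)) + 8
    rr_draw <- rnorm(n_guess, rr_mu, rr_sd)
    jit <- rnorm(n_guess, 0, profile$qtc_jitter_ms)
    k <- 0
    while (t_cur < phase_end) {
      k <- k + 1
      if (k > length(rr_draw)) { # top up in the rare undershoot case
        rr_draw <- c(rr_draw, rnorm(n_guess, rr_mu, rr_sd))
        jit <- c(jit, rnorm(n_guess, 0, profile$qtc_jitter_ms))
      }
      mod <- if (nrow(profile$rr_mod) > 0) {
        sum(profile$rr_mod$amp_ms * sin(2 * pi * profile$rr_mod$freq_hz * t_cur))
      } else 0
      rr <- rr_draw[k] + mod
      rr <- max(rr, 0.35 * rr_mu) # physiologic floor
      qtc <- qtc_mu + jit[k]
      qt <- qtc + slope * (rr - rr_ref)
      qt <- min(qt, 0.9 * rr) # enforce qt < rr even in extreme draws
      rr_all <- c(rr_all, rr); qt_all <- c(qt_all, qt)
      phase_all <- c(phase_all, ph)
      t_cur <- t_cur + rr / 1000
    }
  }
  rebuild_beat_series(rr_all, qt_all,
                      rep("normal", length(rr_all)), phase_all,
                      protocol,
                      events = NULL)
}

# Sample non-overlapping insertion slots (beat indices) within a phase.
# Returns integer positions or aborts when demand cannot be placed.
place_events <- function(eligible, n_events, run_len, taken) {
  pos <- integer(0)
  cand <- sample(eligible)
  for (j in seq_len(n_events)) {
    ok <- FALSE
    while (length(cand) > 0) {
      p <- cand[1]; cand <- cand[-1]
      if (all(abs(p - taken) > run_len + 3)) { ok <- TRUE; break }
    }
    if (!ok) {
      abort("ectopy/TdP rates too high: cannot place events without overlapping runs")
    }
    pos <- c(pos, p); taken <- c(taken, p)
  }
  list(pos = pos, taken = taken)
}

# Insert extra beats into a series. `insertions` is a tibble with columns
# after_beat (original index), rr_ms, qt_ms, label (list-columns of per-beat
# vectors), kind. Rebuilds times and appends ground truth.
insert_beats <- function(series, insertions) {
  o_rr <- series$rr_ms; o_qt <- series$qt_ms
  o_lab <- series$label; o_ph <- series$phase
  events <- truth_events(series)
  if (nrow(insertions) == 0) return(series)
  insertions <- insertions[order(insertions$after_beat), ]
  rr <- list(); qt <- list(); lab <- list(); ph <- list()
  new_events <- list()
  prev <- 0L; offset <- 0L
  for (i in seq_len(nrow(insertions))) {
    ab <- insertions$after_beat[i]
    idx <- seq.int(prev + 1L, ab)
    rr[[length(rr) + 1]] <- o_rr[idx]
    qt[[length(qt) + 1]] <- o_qt[idx]
    lab[[length(lab) + 1]] <- o_lab[idx]
    ph[[length(ph) + 1]] <- o_ph[idx]
    ins_rr <- insertions$rr_ms[[i]]
    n_ins <- length(ins_rr)
    rr[[length(rr) + 1]] <- ins_rr
    qt[[length(qt) + 1]] <- insertions$qt_ms[[i]]
    lab[[length(lab) + 1]] <- insertions$label[[i]]
    ph[[length(ph) + 1]] <- rep(o_ph[ab], n_ins)
    start_beat <- ab + offset + 1L
    ect <- which(insertions$label[[i]] != "normal")
    new_events[[length(new_events) + 1]] <- tibble::tibble(
      kind = insertions$kind[i],
      start_beat = start_beat + min(ect) - 1L,
      end_beat = start_beat + max(ect) - 1L,
      n_beats = length(ect),
      start_time_s = NA_real_, end_time_s = NA_real_
    )
    prev <- ab; offset <- offset + n_ins
  }
  if (prev < length(o_rr)) {
    idx <- seq.int(prev + 1L, length(o_rr))
    rr[[length(rr) + 1]] <- o_rr[idx]
    qt[[length(qt) + 1]] <- o_qt[idx]
    lab[[length(lab) + 1]] <- o_lab[idx]
    ph[[length(ph) + 1]] <- o_ph[idx]
  }
  # shift previously recorded events that sit after each insertion point;
  # comparisons run on the original indexing so multiple insertions compose
  if (nrow(events) > 0) {
    shift <- integer(nrow(events))
    for (i in seq_len(nrow(insertions))) {
      n_ins <- length(insertions$rr_ms[[i]])
      after <- events$start_beat > insertions$after_beat[i]
      shift[after] <- shift[after] + n_ins
    }
    events$start_beat <- events$start_beat + shift
    events$end_beat <- events$end_beat + shift
  }
  events <- dplyr::bind_rows(events, dplyr::bind_rows(new_events))
  events <- events[order(events$start_beat), ]
  rebuild_beat_series(unlist(rr), unlist(qt), unlist(lab), unlist(ph),
                      attr(series, "protocol"), events)
}

#' Inject ectopic beats into a beat series
#'
#' Adds single ectopic beats (SEB), multiple-ectopic-beat runs (MEB, run
#' length uniform on 2..4) and optionally one bigeminy episode. Event counts
#' per phase are Poisson with the stated per-minute rates. Inserted ectopic
#' RR intervals are 60-70% of the phase mean RR, i.e. they deviate by more
#' than 25% so the standard 20% ectopic-cleaning rule is guaranteed to flag
#' them. Ground truth for every inserted event is recorded and retrievable
#' with [truth_events()].
#'
#' @param series A `beat_series`.
#' @param seb_rate,meb_rate Events per minute; a scalar (applied to every
#'   phase) or a vector named by phase.
#' @param bigeminy Logical; insert one 4-couplet bigeminy episode in the last
#'   phase.
#' @param seed Integer seed.
#' @return The augmented `beat_series` (times rebuilt from the RR sequence).
#' @export
inject_ectopy <- function(series, seb_rate = 0, meb_rate = 0,
                          bigeminy = FALSE, seed = 1) {
  assert_beat_series(series)
  stopifnot_msg(all(seb_rate >= 0) && all(meb_rate >= 0),
                "ectopy rates must be non-negative")
  phases <- unique(series$phase)
  rate_by_phase <- function(r) {
    if (length(r) == 1L && is.null(names(r))) {
      stats::setNames(rep(r, length(phases)), phases)
    } else {
      out <- stats::setNames(rep(0, length(phases)), phases)
      out[intersect(names(r), phases)] <- r[intersect(names(r), phases)]
      out
    }
  }
  seb_rate <- rate_by_phase(seb_rate)
  meb_rate <- rate_by_phase(meb_rate)
  if (all(seb_rate == 0) && all(meb_rate == 0) && !bigeminy) return(series)

  set.seed(as.integer(seed %% 2147483629))
  ins <- list()
  taken <- integer(0)
  for (ph in phases) {
    idx <- which(series$phase == ph)
    if (length(idx) < 12) next
    dur_min <- (max(series$time_s[idx]) - min(series$time_s[idx])) / 60
    mean_rr <- mean(series$rr_ms[idx])
    eligible <- idx[idx > min(idx) + 2 & idx < max(idx) - 6]
    n_seb <- rpois(1, seb_rate[[ph]] * dur_min)
    n_meb <- rpois(1, meb_rate[[ph]] * dur_min)
    if (n_seb + n_meb == 0) next
    for (ev in seq_len(n_seb)) {
      pl <- place_events(eligible, 1, 1, taken); taken <- pl$taken
      ins[[length(ins) + 1]] <- tibble::tibble(
        after_beat = pl$pos, kind = "SEB",
        rr_ms = list(mean_rr * runif(1, 0.60, 0.70)),
        qt_ms = list(0.75 * series$qt_ms[pl$pos]),
        label = list("ectopic")
      )
    }
    for (ev in seq_len(n_meb)) {
      len <- sample(2:4, 1)
      pl <- place_events(eligible, 1, len, taken); taken <- pl$taken
      ins[[length(ins) + 1]] <- tibble::tibble(
        after_beat = pl$pos, kind = "MEB",
        rr_ms = list(mean_rr * runif(len, 0.60, 0.70)),
        qt_ms = list(rep(0.75 * series$qt_ms[pl$pos], len)),
        label = list(rep("ectopic", len))
      )
    }
  }
  if (bigeminy) {
    ph <- phases[length(phases)]
    idx <- which(series$phase == ph)
    stopifnot_msg(length(idx) >= 20,
                  "last phase too short for a bigeminy episode")
    mean_rr <- mean(series$rr_ms[idx])
    eligible <- idx[idx > min(idx) + 2 & idx < max(idx) - 12]
    pl <- place_events(eligible, 1, 8, taken); taken <- pl$taken
    n_couplets <- 4L
    rr <- as.vector(rbind(mean_rr * runif(n_couplets, 0.60, 0.70),
                          mean_rr * runif(n_couplets, 1.05, 1.15)))
    lab <- rep(c("ectopic", "normal"), n_couplets)
    ins[[length(ins) + 1]] <- tibble::tibble(
      after_beat = pl$pos, kind = "bigeminy",
      rr_ms = list(rr),
      qt_ms = list(rep(series$qt_ms[pl$pos], length(rr)) *
                     rep(c(0.75, 1), n_couplets)),
      label = list(lab)
    )
  }
  if (length(ins) == 0) return(series)
  insert_beats(series, dplyr::bind_rows(ins))
}

#' Inject TdP episodes into a beat series
#'
#' Inserts contiguous runs labelled `tdp` (short, irregular RR, QT undefined)
#' into the last phase. TdP requires at least five consecutive undulating
#' complexes, hence `episode_beats >= 5`. Episode spans are recorded in the
#' ground truth.
#'
#' @param series A `beat_series`.
#' @param n_episodes Number of episodes (0 returns the series unchanged).
#' @param episode_beats Beats per episode (scalar or vector of length
#'   `n_episodes`); each must be >= 5.
#' @param seed Integer seed.
#' @param phase Phase receiving the episodes; default the last phase.
#' @return The augmented `beat_series`.
#' @export
inject_tdp <- function(series, n_episodes, episode_beats = 10, seed = 1,
                       phase = NULL) {
  assert_beat_series(series)
  if (n_episodes == 0) return(series)
  episode_beats <- rep_len(episode_beats, n_episodes)
  stopifnot_msg(all(episode_beats >= 5),
                "TdP episodes need at least 5 beats (got %d)",
                min(episode_beats))
  ph <- phase %||% series$phase[nrow(series)]
  idx <- which(series$phase == ph)
  stopifnot_msg(length(idx) > 0, "phase '%s' not present in series", ph)
  mean_rr <- mean(series$rr_ms[idx])
  eligible <- idx[idx > min(idx) + 2 & idx < max(idx) - 6]

  set.seed(as.integer(seed %% 2147483629))
  ins <- list(); taken <- integer(0)
  for (e in seq_len(n_episodes)) {
    len <- episode_beats[e]
    pl <- place_events(eligible, 1, len, taken); taken <- pl$taken
    rr <- mean_rr * runif(len, 0.30, 0.45) # fast, irregular
    ins[[length(ins) + 1]] <- tibble::tibble(
      after_beat = pl$pos, kind = "TdP",
      rr_ms = list(rr),
      qt_ms = list(rep(NA_real_, len)),
      label = list(rep("tdp", len))
    )
  }
  insert_beats(series, dplyr::bind_rows(ins))
}
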
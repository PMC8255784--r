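#' Simulate a cohort of animals
#'
#' Draws `n_per_group` animals from each [group_profile()]. Each animal gets
#' a reproducible sub-seed derived from (`seed`, animal index), a per-animal
#' offset on the RR and QTc means (half the phase SD, the between-animal
#' share of the spread), ectopy injected at the profile's per-phase rates,
#' and — with probability `tdp_propensity` — TdP responder status. Responders
#' receive at least three TdP episodes in the high-dose phase (so they
#' satisfy the inducibility rule) and an ectopy-rate boost, mirroring the
#' higher ectopic burden observed in susceptible animals.
#'
#' @param profiles A list of [group_profile()]s (or a single profile).
#' @param n_per_group Integer scalar or vector (one entry per profile).
#' @param seed Integer master seed.
#' @param protocol A [phase_protocol()].
#' @param responder_rate_boost Multiplier on ectopy rates for responders.
#' @param between_sd_frac Fraction of the phase SD used as the SD of the
#'   per-animal mean offset.
#' @return A tibble (class `tdp_cohort`) with one row per animal: `animal_id`,
#'   `group`, `responder`, `amp_jitter`, `truth_category`, `series`
#'   (list-column of `beat_series`).
#' @export
#' @examples
#' coh <- generate_cohort(list(profile_yc()), n_per_group = 2, seed = 1,
#'                        protocol = phase_protocol(durations_s = c(60, 60, 60, 60)))
generate_cohort <- function(profiles, n_per_group, seed = 1,
                            protocol = phase_protocol(),
                            responder_rate_boost = 3,
                            between_sd_frac = 0.5) {
  if (inherits(profiles, "group_profile")) profiles <- list(profiles)
  stopifnot_msg(length(profiles) > 0, "`profiles` must not be empty")
  stopifnot_msg(all(n_per_group >= 1), "`n_per_group` must be >= 1")
  n_per_group <- rep_len(n_per_group, length(profiles))

  rows <- list()
  animal <- 0L
  for (g in seq_along(profiles)) {
    pr <- profiles[[g]]
    for (a in seq_len(n_per_group[g])) {
      animal <- animal + 1L
      sub <- derive_seed(seed, animal)
      set.seed(sub)
      responder <- runif(1) < pr$tdp_propensity
      rr_off <- rnorm(1, 0, between_sd_frac * pr$rr_sd_ms[[1]])
      qtc_off <- rnorm(1, 0, between_sd_frac * pr$qt_sd_ms[[1]])
      boost <- if (responder) responder_rate_boost else 1
      s <- make_beat_series(pr, protocol, seed = derive_seed(sub, 1),
                            rr_offset_ms = rr_off, qtc_offset_ms = qtc_off)
      s <- inject_ectopy(s,
                         seb_rate = pr$seb_rate * boost,
                         meb_rate = pr$meb_rate * boost,
                         bigeminy = pr$bigeminy,
                         seed = derive_seed(sub, 2))
      if (responder) {
        set.seed(derive_seed(sub, 3))
        n_ep <- 3L + rpois(1, 1)
        s <- inject_tdp(s, n_episodes = n_ep,
                        episode_beats = sample(8:20, n_ep, replace = TRUE),
                        seed = derive_seed(sub, 4))
      }
      ev <- truth_events(s)
      category <- if (responder) "tdp"
                  else if (nrow(ev) > 0) "non_tdp"
                  else "no_arrhythmia"
      rows[[animal]] <- tibble::tibble(
        animal_id = sprintf("%s-%02d", pr$name, a),
        group = pr$name,
        responder = responder,
        amp_jitter = if (category == "no_arrhythmia") 0 else pr$amp_jitter_prone,
        truth_category = category,
        series = list(s)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tdp_cohort", class(out))
  out
}

#' Write a cohort to disk
#'
#' Writes one beat-table CSV per animal (`<id>_beats.csv`: `time_s`, `rr_ms`,
#' `qt_ms`, `label`, `phase`), one ground-truth event CSV per animal
#' (`<id>_truth.csv`), and a JSON manifest (`manifest.json`) holding the
#' animal table and the protocol. Ground truth is kept separate from the
#' "observed" beat tables.
#'
#' @param cohort A `tdp_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$animal_id[i]
    s <- cohort$series[[i]]
    utils::write.csv(as.data.frame(s)[, c("time_s", "rr_ms", "qt_ms",
                                          "label", "phase")],
                     file.path(dir, paste0(id, "_beats.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(truth_events(s)),
                     file.path(dir, paste0(id, "_truth.csv")),
                     row.names = FALSE)
  }
  proto <- attr(cohort$series[[1]], "protocol")
  manifest <- list(
    animals = as.data.frame(cohort[, c("animal_id", "group", "responder",
                                       "amp_jitter", "truth_category")]),
    protocol = as.data.frame(proto)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json` and per-animal CSVs.
#' @return A `tdp_cohort` tibble.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  proto <- phase_protocol(manifest$protocol$phase,
                          manifest$protocol$duration_s)
  animals <- tibble::as_tibble(manifest$animals)
  animals$series <- lapply(animals$animal_id, function(id) {
    b <- utils::read.csv(file.path(dir, paste0(id, "_beats.csv")))
    tr <- utils::read.csv(file.path(dir, paste0(id, "_truth.csv")))
    new_beat_series(b$time_s, b$rr_ms, b$qt_ms, b$label, b$phase,
                    protocol = proto, events = tibble::as_tibble(tr))
  })
  class(animals) <- c("tdp_cohort", class(animals))
  animals
}
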
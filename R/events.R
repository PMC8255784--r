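#' Classify arrhythmia episodes from beat labels
#'
#' Partitions maximal runs of non-normal labels into episodes:
#' a single ectopic label is an SEB, a run of 2-4 ectopics an MEB, a run of
#' >= 5 contiguous `tdp` labels a TdP episode, and >= 3 isolated ectopics
#' each separated by exactly one normal beat form one bigeminy episode that
#' subsumes its SEBs. Runs of >= 5 plain `ectopic` labels are reported as TdP
#' (a ventricular run beyond the MEB definition); `tdp` runs shorter than 5
#' fall back to the ectopic rules. Every beat belongs to at most one episode.
#'
#' @param labels Character vector of beat labels (`normal`, `ectopic`, `tdp`).
#' @param times_s Beat times, same length.
#' @return A tibble of episodes: `kind` (`SEB`, `MEB`, `bigeminy`, `TdP`),
#'   `start_beat`, `end_beat`, `n_beats` (ectopic/TdP beats in the episode),
#'   `start_time_s`, `end_time_s`.
#' @export
#' @examples
#' classify_runs(c("normal", "ectopic", "normal"), c(0, 0.4, 0.8))
classify_runs <- function(labels, times_s) {
  stopifnot_msg(length(labels) == length(times_s),
                "labels and times must align")
  bad <- setdiff(unique(labels), beat_labels)
  stopifnot_msg(length(bad) == 0, "unknown label(s): %s",
                paste(bad, collapse = ", "))
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ep <- list()
  seb_pos <- integer(0) # isolated-ectopic run starts, bigeminy candidates
  for (i in seq_along(r$values)) {
    v <- r$values[i]; len <- r$lengths[i]
    if (v == "normal") next
    kind <- if (v == "tdp" || len >= 5) {
      if (len >= 5) "TdP" else if (len == 1) "SEB" else "MEB"
    } else if (len == 1) "SEB" else "MEB"
    ep[[length(ep) + 1]] <- tibble::tibble(
      kind = kind, start_beat = starts[i], end_beat = ends[i],
      n_beats = len,
      start_time_s = times_s[starts[i]], end_time_s = times_s[ends[i]]
    )
    if (kind == "SEB") seb_pos <- c(seb_pos, starts[i])
  }
  if (length(ep) == 0) {
    return(tibble::tibble(kind = character(), start_beat = integer(),
                          end_beat = integer(), n_beats = integer(),
                          start_time_s = numeric(), end_time_s = numeric()))
  }
  out <- dplyr::bind_rows(ep)
  # bigeminy: >= 3 isolated ectopics at stride 2 (one normal in between)
  if (length(seb_pos) >= 3) {
    seb_pos <- sort(seb_pos)
    grp <- cumsum(c(TRUE, diff(seb_pos) != 2L))
    for (g in unique(grp)) {
      members <- seb_pos[grp == g]
      if (length(members) >= 3) {
        drop <- out$kind == "SEB" & out$start_beat %in% members
        out <- out[!drop, ]
        out <- dplyr::bind_rows(out, tibble::tibble(
          kind = "bigeminy",
          start_beat = min(members), end_beat = max(members),
          n_beats = length(members),
          start_time_s = times_s[min(members)],
          end_time_s = times_s[max(members)]
        ))
      }
    }
  }
  out[order(out$start_beat), ]
}

#' TdP inducibility rule
#'
#' An animal is TdP inducible when at least three TdP episodes occurred or
#' when any single episode lasted more than 10 s (strictly; an episode of
#' exactly 10.0 s does not qualify).
#'
#' @param episodes Episode tibble from [classify_runs()].
#' @param min_episodes Episode-count criterion (default 3).
#' @param duration_s Duration criterion in seconds (default 10, strict `>`).
#' @return Logical flag.
#' @export
tdp_inducible <- function(episodes, min_episodes = 3, duration_s = 10) {
  tdp <- episodes[episodes$kind == "TdP", ]
  if (nrow(tdp) == 0) return(FALSE)
  nrow(tdp) >= min_episodes ||
    any(tdp$end_time_s - tdp$start_time_s > duration_s)
}

#' Early-termination check
#'
#' The protocol terminates at the first moment a single TdP episode has
#' persisted for 20 s (non-strict: exactly 20 s terminates), otherwise at the
#' end of the final protocol phase.
#'
#' @param episodes Episode tibble.
#' @param protocol A [phase_protocol()].
#' @param persist_s Persistence criterion (default 20 s, `>=`).
#' @return A list: `time_s` (termination time) and `early` (logical).
#' @export
termination_check <- function(episodes, protocol, persist_s = 20) {
  tdp <- episodes[episodes$kind == "TdP", ]
  if (nrow(tdp) > 0) {
    dur <- tdp$end_time_s - tdp$start_time_s
    hit <- which(dur >= persist_s)
    if (length(hit) > 0) {
      t0 <- min(tdp$start_time_s[hit] + persist_s)
      return(list(time_s = t0, early = TRUE))
    }
  }
  list(time_s = max(protocol$end_s), early = FALSE)
}

#' Per-animal outcome category
#'
#' Categorizes an animal from its classified episodes: `tdp` when the
#' inducibility rule fires, `non_tdp` when any non-TdP episode occurred
#' without inducible TdP, `no_arrhythmia` otherwise. SEB/MEB presence flags
#' are evaluated only on episodes starting before the first TdP onset
#' (the ectopy burden "prior to TdP").
#'
#' @param episodes Episode tibble from [classify_runs()].
#' @param animal_id Optional identifier carried into the result.
#' @return A one-row tibble of class `animal_outcome`: `animal_id`,
#'   `category`, `inducible`, `n_tdp`, `seb_present`, `meb_present`,
#'   `bigeminy_present`, `n_episodes`.
#' @export
outcome_category <- function(episodes, animal_id = NA_character_) {
  inducible <- tdp_inducible(episodes)
  tdp <- episodes[episodes$kind == "TdP", ]
  first_tdp <- if (nrow(tdp) > 0) min(tdp$start_time_s) else Inf
  pre <- episodes[episodes$start_time_s < first_tdp, ]
  category <- if (inducible) "tdp"
              else if (nrow(episodes) > 0) "non_tdp"
              else "no_arrhythmia"
  out <- tibble::tibble(
    animal_id = animal_id,
    category = category,
    inducible = inducible,
    n_tdp = nrow(tdp),
    seb_present = any(pre$kind == "SEB"),
    meb_present = any(pre$kind == "MEB"),
    bigeminy_present = any(pre$kind == "bigeminy"),
    n_episodes = nrow(episodes)
  )
  class(out) <- c("animal_outcome", class(out))
  out
}

#' Incidence with half-up integer percent
#'
#' Either `incidence(k, n)` with printed counts, or
#' `incidence(outcomes, predicate)` where `predicate` is a function applied
#' to each row of an outcome tibble.
#'
#' @param x Number of positives `k`, or an outcome tibble.
#' @param n Denominator (when `x` is a count), or a predicate function
#'   (when `x` is a tibble) taking the outcome tibble and returning a logical
#'   vector.
#' @return A tibble `k`, `n`, `percent` (integer, rounded half-up).
#' @export
#' @examples
#' incidence(10, 12) # 83%
incidence <- function(x, n) {
  if (is.data.frame(x)) {
    stopifnot_msg(is.function(n), "`n` must be a predicate function")
    hits <- n(x)
    k <- sum(hits); n <- nrow(x)
  } else {
    k <- x
  }
  stopifnot_msg(n >= 1, "empty cohort")
  stopifnot_msg(k >= 0 && k <= n, "`k` must be between 0 and `n`")
  tibble::tibble(k = as.integer(k), n = as.integer(n),
                 percent = as.integer(round_half_up(100 * k / n)))
}
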
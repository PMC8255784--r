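#' Pipeline run configuration
#'
#' One serializable object holding every tunable of the four-stage pipeline
#' (simulate, analyze, stratify, report). Stock group profiles are referenced
#' by name so the whole configuration round-trips through JSON
#' ([write_run_config()] / [read_run_config()]) unchanged.
#'
#' @param seed Master seed.
#' @param groups Stock profile names among `"YC"`, `"AC"`, `"CH"`.
#' @param n_per_group Animals per group (recycled; default the 12/11/14
#'   design).
#' @param protocol_durations_s Named durations of the four phases.
#' @param stv_n_diffs STV differences per window.
#' @param entropy_segment_s Baseline seconds analyzed for entropy.
#' @param entropy_fs_hz Rendering rate for the entropy segment.
#' @param aape_threshold,iein_threshold Quadrant thresholds.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       groups = c("YC", "AC", "CH"),
                       n_per_group = c(12, 11, 14),
                       protocol_durations_s = c(baseline = 600,
                                                methoxamine = 600,
                                                dofetilide_low = 1200,
                                                dofetilide_high = 1200),
                       stv_n_diffs = 30,
                       entropy_segment_s = 30,
                       entropy_fs_hz = 500,
                       aape_threshold = 1.975,
                       iein_threshold = 670) {
  stopifnot_msg(all(groups %in% c("YC", "AC", "CH")),
                "`groups` must be stock profile names (YC, AC, CH)")
  structure(list(seed = as.integer(seed), groups = groups,
                 n_per_group = rep_len(as.integer(n_per_group),
                                       length(groups)),
                 protocol_durations_s = protocol_durations_s,
                 stv_n_diffs = as.integer(stv_n_diffs),
                 entropy_segment_s = entropy_segment_s,
                 entropy_fs_hz = entropy_fs_hz,
                 aape_threshold = aape_threshold,
                 iein_threshold = iein_threshold),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  # named atomic vectors must become objects, not nameless arrays
  x$protocol_durations_s <- as.list(x$protocol_durations_s)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(seed = x$seed, groups = x$groups, n_per_group = x$n_per_group,
             protocol_durations_s = unlist(x$protocol_durations_s),
             stv_n_diffs = x$stv_n_diffs,
             entropy_segment_s = x$entropy_segment_s,
             entropy_fs_hz = x$entropy_fs_hz,
             aape_threshold = x$aape_threshold,
             iein_threshold = x$iein_threshold)
}

config_profiles <- function(config) {
  stock <- list(YC = profile_yc, AC = profile_ac, CH = profile_ch)
  lapply(config$groups, function(g) stock[[g]]())
}

config_protocol <- function(config) {
  phase_protocol(names(config$protocol_durations_s),
                 as.numeric(config$protocol_durations_s))
}

#' Simulate a cohort from a run configuration
#'
#' @param config A [run_config()].
#' @param dir Optional directory; when given, the cohort is also written via
#'   [write_cohort()].
#' @return A `tdp_cohort`.
#' @export
cmd_simulate <- function(config = run_config(), dir = NULL) {
  cohort <- generate_cohort(config_profiles(config),
                            n_per_group = config$n_per_group,
                            seed = config$seed,
                            protocol = config_protocol(config))
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Analyze a cohort: intervals, STV, HRV, entropy, episodes
#'
#' Runs the full per-animal analysis chain on a simulated (or loaded) cohort:
#' phase interval means and QTc via [qtc_rabbit()], STV of the final window
#' of the high-dose phase via [stv()], Lomb-Scargle HRV of the last 5 min of
#' baseline via [hrv_analysis()], baseline waveform entropy via
#' [entropy_for_animal()] (the baseline segment is rendered at
#' `config$entropy_fs_hz` with the animal's amplitude jitter), and episode
#' classification plus outcome via [classify_runs()] / [outcome_category()].
#' Animals whose analysis fails at some stage keep `NA` metrics and an entry
#' in the `exclusions` attribute rather than aborting the run.
#'
#' @param cohort A `tdp_cohort`.
#' @param config A [run_config()].
#' @return A tibble (one row per animal) of metrics, with the per-animal
#'   episode tibbles in the `episodes` list-column.
#' @export
cmd_analyze <- function(cohort, config = run_config()) {
  exclusions <- list()
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    s <- cohort$series[[i]]
    id <- cohort$animal_id[i]
    normal <- s[s$label == "normal", ]
    qtc <- qtc_rabbit(normal$qt_ms, normal$rr_ms)
    hd <- normal$phase == normal$phase[nrow(normal)]
    stv_hd <- tryCatch(stv(qtc[hd], n_diffs = config$stv_n_diffs),
                       error = function(e) NA_real_)
    hrv <- tryCatch(hrv_analysis(s), error = function(e) {
      exclusions[[id]] <<- conditionMessage(e)
      tibble::tibble(lf = NA_real_, hf = NA_real_, lf_hf = NA_real_)
    })
    ent <- tryCatch({
      base <- s[s$phase == s$phase[1], ]
      seg_end <- min(config$entropy_segment_s, max(base$time_s))
      wf <- render_waveform(base[base$time_s <= seg_end + 1, ],
                            fs_hz = config$entropy_fs_hz,
                            seed = derive_seed(config$seed, i),
                            amp_jitter = cohort$amp_jitter[i])
      entropy_for_animal(wf, segment_s = c(0, seg_end),
                         min_seconds = min(20, seg_end))
    }, error = function(e) {
      exclusions[[id]] <<- conditionMessage(e)
      tibble::tibble(aape = NA_real_, iein_sigma = NA_real_,
                     excluded = TRUE, reason = conditionMessage(e))
    })
    episodes <- classify_runs(s$label, s$time_s)
    outcome <- outcome_category(episodes, animal_id = id)
    tibble::tibble(
      animal_id = id, group = cohort$group[i],
      truth_category = cohort$truth_category[i],
      rr_baseline_ms = mean(normal$rr_ms[normal$phase == normal$phase[1]]),
      qtc_hd_ms = mean(qtc[hd]),
      stv_hd_ms = stv_hd,
      lf = hrv$lf[1], hf = hrv$hf[1], lf_hf = hrv$lf_hf[1],
      aape = ent$aape[1], iein_sigma = ent$iein_sigma[1],
      entropy_excluded = isTRUE(ent$excluded[1]),
      category = outcome$category, inducible = outcome$inducible,
      seb_present = outcome$seb_present, meb_present = outcome$meb_present,
      episodes = list(episodes)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- exclusions
  out
}

#' Stratify an analyzed cohort and assemble the report blocks
#'
#' Produces the four result blocks of a run: (1) the per-group, per-phase
#' interval summary, (2) TdP and any-arrhythmia incidences with pairwise
#' proportion tests, (3) the outcome regrouping (no arrhythmia / non-TdP /
#' TdP) with SEB and MEB confusion tables against TdP outcome, and (4) the
#' entropy quadrant table with low-risk flags.
#'
#' @param metrics Output of [cmd_analyze()].
#' @param cohort The `tdp_cohort` the metrics came from (for the interval
#'   summary).
#' @param config A [run_config()].
#' @return A list of class `tdp_report`.
#' @export
cmd_stratify <- function(metrics, cohort, config = run_config()) {
  groups <- unique(metrics$group)
  inc <- purrr::map_dfr(groups, function(g) {
    m <- metrics[metrics$group == g, ]
    dplyr::bind_rows(
      dplyr::mutate(incidence(sum(m$inducible), nrow(m)),
                    group = g, endpoint = "tdp"),
      dplyr::mutate(incidence(sum(m$category != "no_arrhythmia"), nrow(m)),
                    group = g, endpoint = "any_arrhythmia")
    )
  })
  prop_tests <- NULL
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    prop_tests <- purrr::map_dfr(pairs, function(pr) {
      a <- inc[inc$group == pr[1] & inc$endpoint == "tdp", ]
      b <- inc[inc$group == pr[2] & inc$endpoint == "tdp", ]
      res <- two_sample_proportion_test(a$k, a$n, b$k, b$n)
      dplyr::mutate(tidy(res), group1 = pr[1], group2 = pr[2])
    })
  }
  confusion <- purrr::map_dfr(c("seb_present", "meb_present"), function(flag) {
    pos <- metrics$category == "tdp"
    f <- metrics[[flag]]
    dplyr::mutate(
      sensitivity_specificity(tp = sum(f & pos), fp = sum(f & !pos),
                              tn = sum(!f & !pos), fn = sum(!f & pos)),
      marker = sub("_present", "", flag)
    )
  })
  thr <- quadrant_thresholds(config$aape_threshold, config$iein_threshold)
  quadrant <- metrics[, c("animal_id", "group", "category", "aape",
                          "iein_sigma", "entropy_excluded")]
  quadrant$low_risk <- quadrant_low_risk(quadrant$aape, quadrant$iein_sigma,
                                         thr)
  quadrant$low_risk[quadrant$entropy_excluded] <- NA
  structure(list(
    summary = phase_summary(cohort),
    incidence = inc,
    prop_tests = prop_tests,
    outcomes = dplyr::count(metrics, .data$group, .data$category),
    confusion = confusion,
    quadrant = quadrant,
    thresholds = thr
  ), class = "tdp_report")
}

#' Render a report
#'
#' @param report A `tdp_report` from [cmd_stratify()].
#' @param format `"md"` (markdown text) or `"json"`.
#' @param path Optional file to write.
#' @return The report text, invisibly when written to `path`.
#' @export
cmd_report <- function(report, format = c("md", "json"), path = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    txt <- jsonlite::toJSON(report[c("summary", "incidence", "prop_tests",
                                     "outcomes", "confusion", "quadrant")],
                            dataframe = "rows", auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, na = "null")
  } else {
    fmt_tbl <- function(df) {
      paste(utils::capture.output(print(as.data.frame(df), row.names = FALSE,
                                        digits = 4)),
            collapse = "\n")
    }
    txt <- paste0(
      "# Cohort report\n\n## Interval summary\n\n", fmt_tbl(report$summary),
      "\n\n## Incidence\n\n", fmt_tbl(report$incidence),
      if (!is.null(report$prop_tests)) {
        paste0("\n\n## Proportion tests (TdP incidence)\n\n",
               fmt_tbl(report$prop_tests))
      } else "",
      "\n\n## Outcome regrouping\n\n", fmt_tbl(report$outcomes),
      "\n\n## SEB/MEB confusion vs TdP outcome\n\n", fmt_tbl(report$confusion),
      "\n\n## Entropy quadrant\n\n", fmt_tbl(report$quadrant), "\n"
    )
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
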
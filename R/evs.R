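#' Item fixated at a time point
#'
#' Returns the AOI of the fixation whose `[start_t, end_t)` interval contains
#' `t`. When `t` falls between fixations (during a saccade or track loss),
#' the most recent preceding fixation with an AOI carries forward. Before
#' any AOI-bearing fixation the gaze state is unresolvable (`NA`).
#'
#' @param fixations AOI-annotated, time-ordered fixation tibble (column
#'   `aoi`, as produced by [assign_fixations()]; off-array fixations have
#'   `aoi = NA` and are skipped by the carry-forward rule).
#' @param t Time point(s), seconds (vectorised).
#' @return Integer serial index per time point, `NA` where unresolvable.
#' @export
fixated_item_at <- function(fixations, t) {
  if (!"aoi" %in% names(fixations)) {
    stop("fixations must be AOI-annotated (see assign_fixations)", call. = FALSE)
  }
  fx <- fixations[!is.na(fixations$aoi), ]
  out <- rep(NA_integer_, length(t))
  if (!nrow(fx)) return(out)
  # index of last fixation starting at or before t
  idx <- findInterval(t, fx$start_t)
  hit <- idx >= 1L
  out[hit] <- fx$aoi[idx[hit]]
  out
}

#' Eye-voice span at one vocal onset
#'
#' The signed number of items the currently fixated item leads the item being
#' named at the onset of its articulation:
#' `evs_items = serial_fixated - serial_spoken`.
#'
#' @param fixations AOI-annotated fixation tibble.
#' @param event One row of a `voice_track` events tibble (or a list with
#'   `serial_index` and `onset_t`).
#' @param retained Optional logical mask over serial indices (positional
#'   exclusion); onsets of masked-out items yield no sample.
#' @return One-row tibble (`serial_spoken`, `serial_fixated`, `evs_items`)
#'   or `NULL` when the event is an omission, position-excluded, or the
#'   fixated item is unresolvable.
#' @export
evs_at_onset <- function(fixations, event, retained = NULL) {
  if (is.na(event$onset_t)) return(NULL)
  spoken <- as.integer(event$serial_index)
  if (!is.null(retained) && !retained[spoken + 1L]) return(NULL)
  fixated <- fixated_item_at(fixations, event$onset_t)
  if (is.na(fixated)) return(NULL)
  tibble::tibble(serial_spoken = spoken,
                 serial_fixated = as.integer(fixated),
                 evs_items = as.integer(fixated) - spoken)
}

#' Per-onset eye-voice span table for a run
#'
#' @inheritParams evs_at_onset
#' @param track A `voice_track`.
#' @return Tibble with one row per eligible onset (`onset_t`,
#'   `serial_spoken`, `serial_fixated`, `evs_items`).
#' @export
evs_samples <- function(fixations, track, retained = NULL) {
  ev <- track$events
  rows <- purrr::map(seq_len(nrow(ev)), function(i) {
    s <- evs_at_onset(fixations, ev[i, ], retained = retained)
    if (is.null(s)) return(NULL)
    s$onset_t <- ev$onset_t[i]
    s
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(onset_t = numeric(), serial_spoken = integer(),
                          serial_fixated = integer(), evs_items = integer()))
  }
  out[c("onset_t", "serial_spoken", "serial_fixated", "evs_items")]
}

#' Mean eye-voice span of a run
#'
#' Arithmetic mean of the per-onset signed spans over all eligible onsets
#' (articulated, position-retained, with resolvable gaze state).
#'
#' @inheritParams evs_samples
#' @return List with `mean_evs_items` (`NA` with a warning when no onset is
#'   eligible), `n_onsets`, and the per-onset `samples` tibble.
#' @export
run_evs <- function(fixations, track, retained = NULL) {
  samples <- evs_samples(fixations, track, retained = retained)
  if (!nrow(samples)) {
    warning("run EVS undefined: no eligible vocal onsets; run should be flagged")
    return(list(mean_evs_items = NA_real_, n_onsets = 0L, samples = samples))
  }
  list(mean_evs_items = mean(samples$evs_items),
       n_onsets = nrow(samples),
       samples = samples)
}
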
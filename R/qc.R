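#' Run-level quality-control parameters
#'
#' Defaults implement the standard exclusion rules for serial-naming gaze
#' runs: exclude runs with more than 35% track loss, runs containing a
#' fixation-free period longer than 10 s, and runs whose fixation count
#' falls outside 15-50 (symbolic: letter/number) or 20-55 (non-symbolic:
#' color/object); eye movements on the first two and last four items of
#' each array are excluded from analysis.
#'
#' @param max_track_loss_frac Maximum tolerated invalid-binocular-sample
#'   fraction (strictly greater fails).
#' @param max_no_fixation_gap_s Maximum tolerated fixation-free interval in
#'   seconds (strictly greater fails).
#' @param fixation_bounds Named list of inclusive `[min, max]` fixation-count
#'   bounds per condition.
#' @param exclude_first_items,exclude_last_items Positional exclusion counts.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(max_track_loss_frac = 0.35,
                      max_no_fixation_gap_s = 10,
                      fixation_bounds = list(symbolic = c(15, 50),
                                             non_symbolic = c(20, 55)),
                      exclude_first_items = 2L,
                      exclude_last_items = 4L) {
  if (max_track_loss_frac < 0 || max_track_loss_frac > 1) {
    stop("max_track_loss_frac must lie in [0, 1]", call. = FALSE)
  }
  if (!all(c("symbolic", "non_symbolic") %in% names(fixation_bounds)) ||
      !all(vapply(fixation_bounds, function(b)
        length(b) == 2 && b[1] <= b[2], logical(1)))) {
    stop("fixation_bounds must give ordered [min, max] for both conditions",
         call. = FALSE)
  }
  structure(list(max_track_loss_frac = max_track_loss_frac,
                 max_no_fixation_gap_s = max_no_fixation_gap_s,
                 fixation_bounds = fixation_bounds,
                 exclude_first_items = as.integer(exclude_first_items),
                 exclude_last_items = as.integer(exclude_last_items)),
            class = "qc_params")
}

#' Positional exclusion mask
#'
#' Eye movements associated with the first `exclude_first_items` and last
#' `exclude_last_items` items of an array are excluded from analysis; for a
#' 36-item array with defaults, serial indices 2..31 (30 items) remain.
#'
#' @param n_items Number of items in the array.
#' @param params A [qc_params()].
#' @return Logical vector of length `n_items`; `TRUE` = retained. Index i
#'   corresponds to serial index i - 1.
#' @export
positional_exclusion_mask <- function(n_items = 36L, params = qc_params()) {
  first <- params$exclude_first_items
  last <- params$exclude_last_items
  if (n_items <= first + last) {
    stop("array too small for positional exclusion (n_items <= first + last)",
         call. = FALSE)
  }
  mask <- rep(TRUE, n_items)
  if (first > 0) mask[seq_len(first)] <- FALSE
  if (last > 0) mask[n_items - seq_len(last) + 1L] <- FALSE
  mask
}

# Longest fixation-free interval of a run, including the stretches before
# the first and after the last fixation; the whole trace duration when no
# fixation was detected.
max_fixation_free_gap <- function(trace, fixations) {
  t0 <- min(trace$samples$t)
  t1 <- max(trace$samples$t)
  if (!nrow(fixations)) return(t1 - t0)
  gaps <- c(fixations$start_t[1] - t0,
            fixations$start_t[-1] - fixations$end_t[-nrow(fixations)],
            t1 - fixations$end_t[nrow(fixations)])
  max(c(0, gaps))
}

#' Evaluate run-level quality control
#'
#' Applies all exclusion rules and accumulates every failing reason (rules
#' do not short-circuit): `track_loss` when the invalid-binocular-sample
#' fraction exceeds `max_track_loss_frac`; `fixation_gap` when any
#' fixation-free interval exceeds `max_no_fixation_gap_s`; `fixation_count`
#' when the number of detected fixations falls outside the condition's
#' inclusive bounds.
#'
#' @param trace A `gaze_trace`.
#' @param fixations Fixation tibble from [ivt_classify()].
#' @param run_spec A [run_spec()] (its condition selects the bounds).
#' @param params A [qc_params()].
#' @return List with `qc_pass` (flag) and `qc_reasons` (character vector,
#'   empty iff passing).
#' @export
evaluate_run_qc <- function(trace, fixations, run_spec, params = qc_params()) {
  reasons <- character()
  loss <- track_loss_fraction(trace)
  if (loss > params$max_track_loss_frac + .ranevs_eps) {
    reasons <- c(reasons, "track_loss")
  }
  gap <- max_fixation_free_gap(trace, fixations)
  if (gap > params$max_no_fixation_gap_s + .ranevs_eps) {
    reasons <- c(reasons, "fixation_gap")
  }
  bounds <- params$fixation_bounds[[run_spec$condition]]
  nfix <- nrow(fixations)
  if (nfix < bounds[1] || nfix > bounds[2]) {
    reasons <- c(reasons, "fixation_count")
  }
  list(qc_pass = length(reasons) == 0L, qc_reasons = reasons)
}

#' Score one run end to end
#'
#' Runs the full per-run pipeline: I-VT fixation detection, AOI assignment
#' with positional exclusion, eye-voice span, scanpath metrics, naming
#' metrics, and quality control. Positional exclusion applies to the
#' eye-movement metrics and EVS onset eligibility, but not to naming time or
#' errors, which are defined over all 36 items.
#'
#' @param trace A `gaze_trace`.
#' @param track A `voice_track` for the same run.
#' @param array The run's `stimulus_array`.
#' @param geometry A [screen_geometry()].
#' @param ivt An [ivt_params()].
#' @param qc A [qc_params()].
#' @return One-row tibble of run metrics (class columns: identification,
#'   naming, eye movement, QC verdict with `;`-joined reasons).
#' @export
score_run <- function(trace, track, array, geometry = screen_geometry(),
                      ivt = ivt_params(), qc = qc_params()) {
  rs <- trace$run_spec
  retained <- positional_exclusion_mask(36L, qc)
  fixations <- tryCatch(ivt_classify(trace, geometry, ivt), error = function(e) NULL)
  if (is.null(fixations)) {
    return(tibble::tibble(
      participant_id = rs$participant_id, stimulus_type = rs$stimulus_type,
      run_index = rs$run_index, condition = rs$condition,
      naming_time_s = suppressWarnings(naming_time(track)),
      n_errors = count_errors(track),
      mean_evs_items = NA_real_, n_evs_onsets = 0L,
      total_fixations = NA_integer_, perseverations = NA_integer_,
      regressions = NA_integer_, refixations = NA_integer_,
      off_array_fixations = NA_integer_, track_loss_frac = track_loss_fraction(trace),
      qc_pass = FALSE, qc_reasons = "classification_error"
    ))
  }
  visits <- assign_fixations(fixations, array, retained = retained)
  evs <- suppressWarnings(run_evs(visits$fixations, track, retained = retained))
  verdict <- evaluate_run_qc(trace, fixations, rs, qc)
  reasons <- verdict$qc_reasons
  if (evs$n_onsets == 0L) reasons <- c(reasons, "no_evs_onsets")
  pers <- count_perseverations(visits)
  regr <- count_regressions(visits)
  tibble::tibble(
    participant_id = rs$participant_id, stimulus_type = rs$stimulus_type,
    run_index = rs$run_index, condition = rs$condition,
    naming_time_s = suppressWarnings(naming_time(track)),
    n_errors = count_errors(track),
    mean_evs_items = evs$mean_evs_items, n_evs_onsets = evs$n_onsets,
    total_fixations = count_total_fixations(visits),
    perseverations = pers, regressions = regr, refixations = pers + regr,
    off_array_fixations = visits$n_off_array,
    track_loss_frac = track_loss_fraction(trace),
    qc_pass = length(reasons) == 0L,
    qc_reasons = paste(reasons, collapse = ";")
  )
}

.ranevs_metric_cols <- c("naming_time_s", "n_errors", "mean_evs_items",
                         "total_fixations", "perseverations", "regressions",
                         "refixations")

#' Aggregate passing runs into condition summaries
#'
#' Two-stage mean: metrics are first averaged over the (up to two) runs of
#' each stimulus type, then over the two stimulus types within each
#' condition (symbolic = numbers + letters, non-symbolic = colors +
#' objects). Only QC-passing runs contribute; a participant with no passing
#' run in a condition yields no summary row. Missing runs are averaged over
#' what survives rather than dropping the participant.
#'
#' @param run_metrics Tibble of [score_run()] rows (possibly many runs and
#'   participants).
#' @return Tibble with one row per participant x condition and one mean per
#'   metric.
#' @export
aggregate_conditions <- function(run_metrics) {
  passing <- dplyr::filter(run_metrics, .data$qc_pass)
  extra <- intersect(c("diagnosis", "culture", "sex", "age", "iq",
                       "ados_severity"),
                     names(passing))
  by_type <- passing |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("participant_id", extra, "condition", "stimulus_type")))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(.ranevs_metric_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  by_type |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("participant_id", extra, "condition")))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(.ranevs_metric_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}

#' Per-group run exclusion accounting
#'
#' Tallies excluded and included runs per group (any combination of grouping
#' columns present in the table, e.g. diagnosis x culture).
#'
#' @param run_metrics Tibble of [score_run()] rows.
#' @param by Character vector of grouping columns (default
#'   `c("diagnosis", "culture")` intersected with available columns).
#' @return Tibble with `n_runs`, `n_excluded`, `n_included`,
#'   `frac_excluded` per group.
#' @export
exclusion_accounting <- function(run_metrics,
                                 by = c("diagnosis", "culture")) {
  by <- intersect(by, names(run_metrics))
  run_metrics |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      n_excluded = sum(!.data$qc_pass),
      n_included = sum(.data$qc_pass),
      frac_excluded = mean(!.data$qc_pass),
      .groups = "drop"
    )
}

#' Write a metric table as tidy delimited text
#'
#' Deterministic CSV serialization (fixed column order and formatting), so
#' identical inputs yield byte-identical files.
#'
#' @param metrics Tibble (run metrics or condition summaries).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(metrics, path) {
  readr::write_csv(metrics, path, progress = FALSE)
  invisible(path)
}
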
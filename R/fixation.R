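#' I-VT fixation classifier parameters
#'
#' Defaults follow the standard strict-binocular velocity-threshold settings
#' used for serial-naming gaze data: 35 deg/s velocity threshold, candidate
#' fixations merged when separated by at most 100 ms and 0.5 deg, and a
#' 100 ms minimum duration for unique fixations.
#'
#' @param velocity_threshold_deg_s Angular velocity threshold (deg/s). A
#'   sample is a fixation sample iff its velocity is strictly below this.
#' @param merge_max_gap_ms Maximum time gap between consecutive candidate
#'   fixations that may merge (ms).
#' @param merge_max_angle_deg Maximum centroid separation for merging (deg).
#' @param min_fixation_ms Minimum duration of a retained fixation (ms).
#' @return An object of class `ivt_params`.
#' @export
ivt_params <- function(velocity_threshold_deg_s = 35,
                       merge_max_gap_ms = 100,
                       merge_max_angle_deg = 0.5,
                       min_fixation_ms = 100) {
  vals <- c(velocity_threshold_deg_s, merge_max_gap_ms,
            merge_max_angle_deg, min_fixation_ms)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all ivt_params must be strictly positive", call. = FALSE)
  }
  structure(list(velocity_threshold_deg_s = velocity_threshold_deg_s,
                 merge_max_gap_ms = merge_max_gap_ms,
                 merge_max_angle_deg = merge_max_angle_deg,
                 min_fixation_ms = min_fixation_ms),
            class = "ivt_params")
}

# Per-sample angular velocity (deg/s). Central difference over the (i-1, i+1)
# window when both neighbours carry valid binocular points; one-sided where
# only one neighbour is valid; NA (unclassifiable) when the sample itself or
# both neighbours are invalid. Invalid samples therefore break velocity
# windows rather than being interpolated across.
sample_velocities <- function(bp, geometry) {
  n <- nrow(bp)
  v <- rep(NA_real_, n)
  if (n < 2) return(v)
  val <- bp$valid
  x <- bp$x; y <- bp$y; t <- bp$t
  prev_ok <- c(FALSE, val[-n])
  next_ok <- c(val[-1], FALSE)
  both <- val & prev_ok & next_ok
  if (any(both)) {
    i <- which(both)
    v[i] <- angular_distance(x[i - 1], y[i - 1], x[i + 1], y[i + 1], geometry) /
      (t[i + 1] - t[i - 1])
  }
  fwd <- val & !prev_ok & next_ok
  if (any(fwd)) {
    i <- which(fwd)
    v[i] <- angular_distance(x[i], y[i], x[i + 1], y[i + 1], geometry) /
      (t[i + 1] - t[i])
  }
  bwd <- val & prev_ok & !next_ok
  if (any(bwd)) {
    i <- which(bwd)
    v[i] <- angular_distance(x[i - 1], y[i - 1], x[i], y[i], geometry) /
      (t[i] - t[i - 1])
  }
  v
}

#' Velocity-threshold (I-VT) fixation classification
#'
#' Classifies each valid binocular sample as fixation (velocity strictly
#' below threshold) or saccade, groups consecutive fixation samples into
#' candidates, merges candidates separated by at most `merge_max_gap_ms` AND
#' at most `merge_max_angle_deg` between centroids (gap samples never
#' contribute to the merged centroid), and discards candidates shorter than
#' `min_fixation_ms`. A fixation's end time is its last member sample plus
#' one sample period, so an n-sample fixation at a uniform rate has duration
#' n periods.
#'
#' @param trace A [gaze_trace()].
#' @param geometry A [screen_geometry()].
#' @param params An [ivt_params()].
#' @return Tibble of fixations: `start_t`, `end_t`, `duration`,
#'   `centroid_x_px`, `centroid_y_px`, `n_samples`; time-ordered and
#'   non-overlapping.
#' @export
ivt_classify <- function(trace, geometry, params = ivt_params()) {
  bp <- binocular_points(trace)
  if (sum(bp$valid) < 2) {
    stop("gaze classification requires at least 2 valid binocular samples",
         call. = FALSE)
  }
  period <- median(diff(bp$t))
  vel <- sample_velocities(bp, geometry)
  is_fix <- bp$valid & !is.na(vel) &
    (vel < params$velocity_threshold_deg_s - .ranevs_eps)

  runs <- rle(is_fix)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  if (!length(keep)) return(empty_fixations())

  cands <- lapply(keep, function(k) seq.int(starts[k], ends[k]))

  centroid <- function(idx) c(mean(bp$x[idx]), mean(bp$y[idx]))
  merged <- list()
  cur <- cands[[1]]
  cur_c <- centroid(cur)
  for (cand in cands[-1]) {
    gap_s <- bp$t[cand[1]] - (bp$t[tail(cur, 1)] + period)
    cc <- centroid(cand)
    ang <- angular_distance(cur_c[1], cur_c[2], cc[1], cc[2], geometry)
    if (gap_s * 1000 <= params$merge_max_gap_ms + .ranevs_eps &&
        ang <= params$merge_max_angle_deg + .ranevs_eps) {
      cur <- c(cur, cand)
      cur_c <- centroid(cur)
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- cand
      cur_c <- cc
    }
  }
  merged[[length(merged) + 1L]] <- cur

  fix <- purrr::map_dfr(merged, function(idx) {
    tibble::tibble(
      start_t = bp$t[idx[1]],
      end_t = bp$t[tail(idx, 1)] + period,
      centroid_x_px = mean(bp$x[idx]),
      centroid_y_px = mean(bp$y[idx]),
      n_samples = length(idx)
    )
  })
  fix$duration <- fix$end_t - fix$start_t
  fix <- fix[fix$duration * 1000 >= params$min_fixation_ms - .ranevs_eps, ]
  fix <- fix[c("start_t", "end_t", "duration",
               "centroid_x_px", "centroid_y_px", "n_samples")]
  tibble::as_tibble(fix)
}

empty_fixations <- function() {
  tibble::tibble(start_t = numeric(), end_t = numeric(), duration = numeric(),
                 centroid_x_px = numeric(), centroid_y_px = numeric(),
                 n_samples = integer())
}

#' Export a fixation table for audit
#'
#' @param fixations Tibble from [ivt_classify()] (optionally AOI-annotated).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixation_table <- function(fixations, path) {
  readr::write_csv(fixations, path, progress = FALSE)
  invisible(path)
}
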
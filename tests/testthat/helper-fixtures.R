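# Programmatic fixtures shared across test files.

test_geometry <- function() screen_geometry()

test_array <- function(type = "number", run = 1L) {
  build_array_layout(type, run, test_geometry())
}

# Pixel x-coordinate at a given visual angle from screen center.
px_at_angle_x <- function(deg, geo = test_geometry()) {
  geo$width_px / 2 + angle_to_px_offset(deg, geo, "x")
}

# Build a gaze trace from a segment script: data frame with columns
# t0, t1, x, y. Samples at `rate` Hz on [min(t0), max(t1)); rows of
# `invalidate` (sample indices) are marked invalid. Positions are constant
# within a segment.
segment_trace <- function(segments, rate = 60, invalidate = integer(),
                          rs = run_spec("T", "number", 1)) {
  period <- 1 / rate
  t <- seq(min(segments$t0), max(segments$t1) - period / 2, by = period)
  seg <- findInterval(t, segments$t0)
  x <- segments$x[seg]
  y <- segments$y[seg]
  valid <- rep(TRUE, length(t))
  valid[invalidate] <- FALSE
  gaze_trace(tibble::tibble(
    t = t,
    lx = ifelse(valid, x, NA_real_), ly = ifelse(valid, y, NA_real_),
    lvalid = valid,
    rx = ifelse(valid, x, NA_real_), ry = ifelse(valid, y, NA_real_),
    rvalid = valid
  ), rs, nominal_rate_hz = rate)
}

# Stationary trace at one point for a given duration.
stationary_trace <- function(duration_s, x = 640, y = 512, rate = 60, ...) {
  segment_trace(data.frame(t0 = 0, t1 = duration_s, x = x, y = y),
                rate = rate, ...)
}

# A minimal voice track of clean serial events.
serial_track <- function(n = 36, item_s = 0.4, pause_s = 0.05,
                         rs = run_spec("T", "number", 1)) {
  onsets <- (item_s + pause_s) * (seq_len(n) - 1)
  voice_track(tibble::tibble(
    serial_index = seq_len(n) - 1L,
    onset_t = onsets, offset_t = onsets + item_s,
    label = as.character(seq_len(n) - 1L), error_tags = ""
  ), rs)
}

# Fixation tibble built directly from (start, end, x, y) rows.
fixation_table <- function(start, end, x, y) {
  tibble::tibble(start_t = start, end_t = end, duration = end - start,
                 centroid_x_px = x, centroid_y_px = y,
                 n_samples = as.integer(round((end - start) * 60)))
}
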
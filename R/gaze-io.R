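#' Construct a gaze trace
#'
#' A time-ordered table of binocular gaze samples for one run. Timestamps are
#' seconds from run onset so gaze-voice alignment is translation-free.
#' Invalid samples are represented by an explicit validity flag per eye;
#' coordinates of invalid eyes are `NA`, never a sentinel number.
#'
#' @param samples Tibble/data frame with columns `t`, `lx`, `ly`, `lvalid`,
#'   `rx`, `ry`, `rvalid`.
#' @param run_spec A [run_spec()].
#' @param nominal_rate_hz Nominal sampling rate (metadata; default 60).
#' @return An object of class `gaze_trace`.
#' @export
gaze_trace <- function(samples, run_spec, nominal_rate_hz = 60) {
  cols <- c("t", "lx", "ly", "lvalid", "rx", "ry", "rvalid")
  missing_cols <- setdiff(cols, names(samples))
  if (length(missing_cols)) {
    stop("gaze samples missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)[cols]
  samples$lvalid <- as.logical(samples$lvalid)
  samples$rvalid <- as.logical(samples$rvalid)
  if (any(!is.finite(samples$t))) stop("timestamps must be finite", call. = FALSE)
  ord <- order(samples$t)
  samples <- samples[ord, ]
  if (any(diff(samples$t) <= 0)) {
    stop("duplicate or non-increasing timestamps in gaze table", call. = FALSE)
  }
  for (eye in c("l", "r")) {
    v <- samples[[paste0(eye, "valid")]]
    bad <- v & (!is.finite(samples[[paste0(eye, "x")]]) |
                  !is.finite(samples[[paste0(eye, "y")]]))
    if (any(bad)) {
      stop("valid ", eye, "-eye samples with non-finite coordinates", call. = FALSE)
    }
  }
  if (!is.finite(nominal_rate_hz) || nominal_rate_hz <= 0) {
    stop("nominal_rate_hz must be positive", call. = FALSE)
  }
  structure(list(run_spec = run_spec, samples = samples,
                 nominal_rate_hz = nominal_rate_hz),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> %d samples, %.1f s, nominal %g Hz, track loss %.1f%%\n",
              nrow(x$samples), diff(range(x$samples$t)), x$nominal_rate_hz,
              100 * track_loss_fraction(x)))
  invisible(x)
}

#' Read a gaze sample table
#'
#' Reads a delimited text gaze export (CSV/TSV, header mandatory) into a
#' [gaze_trace()]. Column names in the file can be remapped via `col_map`.
#'
#' @param path File path.
#' @param run_spec A [run_spec()].
#' @param nominal_rate_hz Nominal sampling rate (default 60).
#' @param col_map Named character vector mapping the canonical names
#'   (`t`, `lx`, `ly`, `lvalid`, `rx`, `ry`, `rvalid`) to the file's columns.
#' @return A `gaze_trace`.
#' @export
read_gaze_table <- function(path, run_spec, nominal_rate_hz = 60,
                            col_map = NULL) {
  raw <- readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                           progress = FALSE)
  canonical <- c("t", "lx", "ly", "lvalid", "rx", "ry", "rvalid")
  if (!is.null(col_map)) {
    missing_map <- setdiff(canonical, names(col_map))
    if (length(missing_map)) {
      stop("col_map must name all of: ", paste(canonical, collapse = ", "),
           call. = FALSE)
    }
    missing_cols <- setdiff(unname(col_map[canonical]), names(raw))
    if (length(missing_cols)) {
      stop("gaze table missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    raw <- stats::setNames(raw[unname(col_map[canonical])], canonical)
  }
  gaze_trace(raw, run_spec, nominal_rate_hz = nominal_rate_hz)
}

#' Write a gaze trace to delimited text
#'
#' Round-trips losslessly through [read_gaze_table()]: invalid eyes are
#' written as empty fields, validity as 0/1.
#'
#' @param trace A `gaze_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(trace, path) {
  out <- trace$samples
  out$lvalid <- as.integer(out$lvalid)
  out$rvalid <- as.integer(out$rvalid)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Strict binocular average of gaze samples
#'
#' The cyclopean gaze point is the mean of the two eyes and exists only when
#' BOTH eyes are valid; a sample with one tracked eye is treated as invalid
#' (strict averaging).
#'
#' @param samples A `gaze_trace` or its `samples` tibble.
#' @return Tibble with columns `t`, `x`, `y`, `valid`; `x`/`y` are `NA`
#'   where `valid` is `FALSE`.
#' @export
binocular_points <- function(samples) {
  if (inherits(samples, "gaze_trace")) samples <- samples$samples
  valid <- samples$lvalid & samples$rvalid
  tibble::tibble(
    t = samples$t,
    x = ifelse(valid, (samples$lx + samples$rx) / 2, NA_real_),
    y = ifelse(valid, (samples$ly + samples$ry) / 2, NA_real_),
    valid = valid
  )
}

#' Fraction of samples without a valid binocular point
#'
#' @param trace A `gaze_trace`.
#' @return Proportion in `[0, 1]`.
#' @export
track_loss_fraction <- function(trace) {
  bp <- binocular_points(trace)
  mean(!bp$valid)
}

#' Angular distance between two screen points
#'
#' Visual angle subtended at the eye between two on-screen pixel positions,
#' by planar trigonometry: each point maps to a 3-D gaze vector from an eye
#' positioned on the normal through the screen center at the viewing
#' distance, and the angle between the vectors is returned in degrees.
#' Vectorised over points.
#'
#' @param x1,y1,x2,y2 Pixel coordinates of the two points (vectors recycle).
#' @param geometry A [screen_geometry()].
#' @return Angle(s) in degrees; symmetric, non-negative, zero iff equal.
#' @export
angular_distance <- function(x1, y1, x2, y2, geometry) {
  if (geometry$viewing_distance_cm <= 0) {
    stop("viewing distance must be positive", call. = FALSE)
  }
  px <- geometry$width_cm / geometry$width_px   # cm per pixel, x
  py <- geometry$height_cm / geometry$height_px # cm per pixel, y
  cx <- geometry$width_px / 2
  cy <- geometry$height_px / 2
  d <- geometry$viewing_distance_cm
  a1x <- (x1 - cx) * px; a1y <- (y1 - cy) * py
  a2x <- (x2 - cx) * px; a2y <- (y2 - cy) * py
  dot <- a1x * a2x + a1y * a2y + d^2
  crx <- a1y * d - d * a2y
  cry <- d * a2x - a1x * d
  crz <- a1x * a2y - a1y * a2x
  atan2(sqrt(crx^2 + cry^2 + crz^2), dot) * 180 / pi
}

#' Pixel offset subtending a given visual angle
#'
#' Inverse of [angular_distance()] along one screen axis through the screen
#' center: the pixel offset from center whose gaze vector makes `angle_deg`
#' with the screen normal. Used to construct stimuli and synthetic gaze at
#' exact angular positions.
#'
#' @param angle_deg Angle(s) from the central normal, degrees.
#' @param geometry A [screen_geometry()].
#' @param axis `"x"` or `"y"`.
#' @return Pixel offset(s) from screen center along the axis.
#' @export
angle_to_px_offset <- function(angle_deg, geometry, axis = c("x", "y")) {
  axis <- match.arg(axis)
  d <- geometry$viewing_distance_cm
  pitch <- if (axis == "x") geometry$width_cm / geometry$width_px
           else geometry$height_cm / geometry$height_px
  tan(angle_deg * pi / 180) * d / pitch
}

#' Approximate pixels per degree at screen center
#'
#' Small-angle conversion factor used for injecting angular noise in pixels.
#'
#' @param geometry A [screen_geometry()].
#' @return Pixels per degree (horizontal axis, at center).
#' @export
px_per_degree <- function(geometry) {
  angle_to_px_offset(1, geometry, axis = "x")
}
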
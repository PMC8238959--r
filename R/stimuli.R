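#' Screen geometry of the eye-tracking display
#'
#' Physical and pixel dimensions of the stimulus display plus the viewing
#' distance, used to convert pixel displacements to visual angle. Defaults
#' describe a 1280 x 1024 px, 5:4 21-inch panel viewed from 57 cm (the
#' midpoint of a typical 50-60 cm free-viewing range).
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param width_cm,height_cm Physical panel size in centimetres. The pixel
#'   and physical aspect ratios must agree within 5% (square-pixel check).
#' @param viewing_distance_cm Eye-to-screen distance in centimetres.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1280, height_px = 1024,
                            width_cm = 41.6, height_cm = 33.3,
                            viewing_distance_cm = 57) {
  vals <- c(width_px, height_px, width_cm, height_cm, viewing_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be finite and strictly positive",
         call. = FALSE)
  }
  aspect_px <- width_px / height_px
  aspect_cm <- width_cm / height_cm
  if (abs(aspect_px / aspect_cm - 1) > 0.05) {
    stop("pixel and physical aspect ratios differ by more than 5% ",
         "(non-square pixels are not supported)", call. = FALSE)
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         width_cm = width_cm, height_cm = height_cm,
         viewing_distance_cm = viewing_distance_cm),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.1f x %.1f cm, viewed at %.1f cm\n",
              x$width_px, x$height_px, x$width_cm, x$height_cm,
              x$viewing_distance_cm))
  invisible(x)
}

.stimulus_types <- c("color", "object", "number", "letter")

#' Condition of a stimulus type
#'
#' Number and letter runs form the symbolic condition; color and object runs
#' the non-symbolic condition.
#'
#' @param stimulus_type One of `"color"`, `"object"`, `"number"`, `"letter"`.
#' @return `"symbolic"` or `"non_symbolic"`.
#' @export
stimulus_condition <- function(stimulus_type) {
  stimulus_type <- match.arg(stimulus_type, .stimulus_types, several.ok = TRUE)
  ifelse(stimulus_type %in% c("number", "letter"), "symbolic", "non_symbolic")
}

#' Identify one RAN run
#'
#' @param participant_id Participant identifier (coerced to character).
#' @param stimulus_type One of `"color"`, `"object"`, `"number"`, `"letter"`.
#' @param run_index Run number within stimulus type, 1 or 2.
#' @return An object of class `run_spec` with the derived `condition`.
#' @export
run_spec <- function(participant_id, stimulus_type, run_index = 1L) {
  stimulus_type <- match.arg(stimulus_type, .stimulus_types)
  run_index <- as.integer(run_index)
  if (!run_index %in% c(1L, 2L)) stop("run_index must be 1 or 2", call. = FALSE)
  structure(
    list(participant_id = as.character(participant_id),
         stimulus_type = stimulus_type,
         run_index = run_index,
         condition = stimulus_condition(stimulus_type)),
    class = "run_spec"
  )
}

#' Build a RAN stimulus array with its AOI tiling
#'
#' Lays out `n_rows * n_cols = 36` items on a uniform grid and tiles the
#' region between item centers with axis-aligned AOI rectangles. Boundaries
#' between adjacent items fall at the midpoint of their centers; edge AOIs
#' extend outward by the same half-spacing, so gaze beyond that margin is
#' off-array. Serial indices are 0-based and enumerate items left-to-right
#' within a row and top-to-bottom across rows (the naming order).
#'
#' Coordinates are screen pixels, origin at the top-left corner, y increasing
#' downward. AOI rectangles are half-open (`[left, right) x [top, bottom)`),
#' so every in-grid point belongs to exactly one AOI.
#'
#' @param stimulus_type One of `"color"`, `"object"`, `"number"`, `"letter"`.
#' @param run_index Run number, 1 or 2.
#' @param screen A [screen_geometry()].
#' @param n_rows,n_cols Grid shape; must multiply to 36. The default 4 x 9
#'   mirrors standard serial-naming arrays built from rows of nine symbols.
#' @param labels Optional character vector of 36 item labels in serial order.
#' @return An object of class `stimulus_array` with tibbles `items`
#'   (serial_index, row, col, label, center_x_px, center_y_px) and `aois`
#'   (serial_index, left, right, top, bottom), plus the grid edge vectors.
#' @export
build_array_layout <- function(stimulus_type, run_index = 1L,
                               screen = screen_geometry(),
                               n_rows = 4L, n_cols = 9L, labels = NULL) {
  stimulus_type <- match.arg(stimulus_type, .stimulus_types)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows * n_cols != 36L) {
    stop("grid must contain exactly 36 items (n_rows * n_cols = 36)",
         call. = FALSE)
  }
  spacing_x <- screen$width_px / (n_cols + 1)
  spacing_y <- screen$height_px / (n_rows + 1)
  centers_x <- spacing_x * seq_len(n_cols)
  centers_y <- spacing_y * seq_len(n_rows)
  col_edges <- c(centers_x - spacing_x / 2, centers_x[n_cols] + spacing_x / 2)
  row_edges <- c(centers_y - spacing_y / 2, centers_y[n_rows] + spacing_y / 2)
  if (col_edges[1] < 0 || tail(col_edges, 1) > screen$width_px ||
      row_edges[1] < 0 || tail(row_edges, 1) > screen$height_px) {
    stop("grid with AOI margins does not fit within the screen", call. = FALSE)
  }
  grid <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  serial <- grid$row * n_cols + grid$col
  if (is.null(labels)) labels <- sprintf("%s%02d", substr(stimulus_type, 1, 1), serial)
  if (length(labels) != 36L) stop("labels must have length 36", call. = FALSE)
  items <- tibble::tibble(
    serial_index = serial,
    row = grid$row, col = grid$col,
    label = as.character(labels),
    center_x_px = centers_x[grid$col + 1L],
    center_y_px = centers_y[grid$row + 1L]
  )
  aois <- tibble::tibble(
    serial_index = serial,
    left = col_edges[grid$col + 1L], right = col_edges[grid$col + 2L],
    top = row_edges[grid$row + 1L], bottom = row_edges[grid$row + 2L]
  )
  structure(
    list(stimulus_type = stimulus_type, run_index = as.integer(run_index),
         n_rows = n_rows, n_cols = n_cols,
         items = items, aois = aois,
         col_edges = col_edges, row_edges = row_edges),
    class = "stimulus_array"
  )
}

#' @export
print.stimulus_array <- function(x, ...) {
  cat(sprintf("<stimulus_array> %s run %d: %d x %d grid, 36 items/AOIs\n",
              x$stimulus_type, x$run_index, x$n_rows, x$n_cols))
  invisible(x)
}

#' Locate the AOI containing a point
#'
#' Vectorised over points. A point on a shared boundary resolves to the AOI
#' whose half-open rectangle contains it (left/top edges inclusive,
#' right/bottom exclusive). Points outside the tiling return `NA`.
#'
#' @param array A [build_array_layout()] result.
#' @param x_px,y_px Point coordinates in screen pixels.
#' @return Integer vector of 0-based serial indices, `NA` where off-array.
#' @export
aoi_at_point <- function(array, x_px, y_px) {
  stopifnot(inherits(array, "stimulus_array"))
  ci <- findInterval(x_px, array$col_edges, left.open = FALSE)
  ri <- findInterval(y_px, array$row_edges, left.open = FALSE)
  inside <- ci >= 1L & ci <= array$n_cols & ri >= 1L & ri <= array$n_rows &
    x_px < tail(array$col_edges, 1) & y_px < tail(array$row_edges, 1)
  out <- rep(NA_integer_, length(x_px))
  out[inside] <- (ri[inside] - 1L) * array$n_cols + (ci[inside] - 1L)
  out
}

#' Serialize an array layout to JSON
#'
#' @param array A `stimulus_array`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_array_layout <- function(array, path) {
  doc <- list(
    stimulus_type = array$stimulus_type, run_index = array$run_index,
    n_rows = array$n_rows, n_cols = array$n_cols,
    items = array$items, aois = array$aois,
    col_edges = array$col_edges, row_edges = array$row_edges
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an array layout from JSON
#'
#' @param path Path written by [write_array_layout()].
#' @return A `stimulus_array`.
#' @export
read_array_layout <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(stimulus_type = doc$stimulus_type, run_index = as.integer(doc$run_index),
         n_rows = as.integer(doc$n_rows), n_cols = as.integer(doc$n_cols),
         items = tibble::as_tibble(doc$items),
         aois = tibble::as_tibble(doc$aois),
         col_edges = as.numeric(doc$col_edges),
         row_edges = as.numeric(doc$row_edges)),
    class = "stimulus_array"
  )
}
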
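#' Error tag vocabulary for vocal events
#' @export
voice_error_tags <- c("repetition", "omission", "substitution", "self_correction")

#' Construct a voice track
#'
#' A time-ordered table of per-item articulation intervals with error
#' annotations for one run. Omitted items are kept as events without an
#' interval (`NA` onset/offset, tagged `omission`) so item alignment with
#' the gaze stream stays in register.
#'
#' @param events Tibble with columns `serial_index` (0-based intended item),
#'   `onset_t`, `offset_t` (seconds, `NA` for omissions), `label`
#'   (produced token), `error_tags` (`;`-separated subset of
#'   [voice_error_tags], `""` for clean events).
#' @param run_spec A [run_spec()].
#' @return An object of class `voice_track`.
#' @export
voice_track <- function(events, run_spec) {
  cols <- c("serial_index", "onset_t", "offset_t", "label", "error_tags")
  missing_cols <- setdiff(cols, names(events))
  if (length(missing_cols)) {
    stop("vocal events missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  events <- tibble::as_tibble(events)[cols]
  events$serial_index <- as.integer(events$serial_index)
  events$label <- as.character(events$label)
  events$error_tags <- ifelse(is.na(events$error_tags), "",
                              as.character(events$error_tags))
  if (any(events$serial_index < 0L | events$serial_index > 35L)) {
    stop("serial_index must lie in 0..35", call. = FALSE)
  }
  tags <- strsplit(events$error_tags, ";", fixed = TRUE)
  bad <- !vapply(tags, function(x) all(x %in% voice_error_tags), logical(1))
  if (any(bad)) {
    stop("unknown error tag(s) in events: ",
         paste(unique(unlist(tags[bad])), collapse = ", "), call. = FALSE)
  }
  has_int <- !is.na(events$onset_t)
  if (any(has_int & (is.na(events$offset_t) |
                     events$offset_t <= events$onset_t))) {
    stop("events with an onset must satisfy offset_t > onset_t", call. = FALSE)
  }
  is_omission <- vapply(tags, function(x) "omission" %in% x, logical(1))
  if (any(!has_int & !is_omission)) {
    stop("events without an interval must be tagged as omissions", call. = FALSE)
  }
  is_rep <- grepl("repetition", events$error_tags, fixed = TRUE)
  dup <- duplicated(events$serial_index[!is_rep])
  if (any(dup)) {
    stop("multiple non-repetition events for item(s) ",
         paste(unique(events$serial_index[!is_rep][dup]), collapse = ", "),
         call. = FALSE)
  }
  # time-order by onset; interval-less omissions sort by serial position
  o_key <- ifelse(has_int, events$onset_t, NA_real_)
  events <- events[order(o_key, events$serial_index, na.last = TRUE), ]
  structure(list(run_spec = run_spec, events = events), class = "voice_track")
}

#' @export
print.voice_track <- function(x, ...) {
  cat(sprintf("<voice_track> %d events, %d error tags, naming time %.2f s\n",
              nrow(x$events), count_errors(x), naming_time(x)))
  invisible(x)
}

#' Read vocal events from a table or Praat TextGrid
#'
#' `format = "table"` expects delimited text with the `voice_track` columns.
#' `format = "textgrid"` parses the interval tier named `"word"` of a Praat
#' long- or short-format TextGrid: non-empty intervals are mapped to serial
#' items in order of occurrence, and a label may carry error annotations
#' after a `#` separator (e.g. `"red#substitution;self_correction"`).
#' Omissions cannot be represented on a TextGrid tier and are supported by
#' the table format only.
#'
#' @param path File path.
#' @param run_spec A [run_spec()].
#' @param format `"auto"` (by extension), `"table"`, or `"textgrid"`.
#' @return A `voice_track`.
#' @export
read_vocal_events <- function(path, run_spec,
                              format = c("auto", "table", "textgrid")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.textgrid$", tolower(path))) "textgrid" else "table"
  }
  if (format == "table") {
    ev <- readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                            progress = FALSE)
    return(voice_track(ev, run_spec))
  }
  iv <- parse_textgrid_word_tier(path)
  spoken <- iv[nzchar(iv$label), ]
  parts <- strsplit(spoken$label, "#", fixed = TRUE)
  voice_track(tibble::tibble(
    serial_index = seq_len(nrow(spoken)) - 1L,
    onset_t = spoken$xmin,
    offset_t = spoken$xmax,
    label = vapply(parts, `[`, character(1), 1),
    error_tags = vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                        character(1))
  ), run_spec)
}

# Minimal Praat TextGrid parser: extracts (xmin, xmax, label) for every
# interval on the tier named "word". Handles the verbose long format
# ("intervals [k]:" blocks) and tolerates CRLF endings.
parse_textgrid_word_tier <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(gsub("\r$", "", lines))
  tier_starts <- grep("^item\\s*\\[\\d+\\]", lines)
  if (!length(tier_starts)) stop("not a long-format TextGrid: no item blocks",
                                 call. = FALSE)
  tier_ends <- c(tier_starts[-1] - 1L, length(lines))
  get_field <- function(block, field) {
    hit <- grep(paste0("^", field, "\\s*="), block, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^", field, "\\s*=\\s*"), "", hit[1])
  }
  unquote <- function(x) gsub("^\"|\"$", "", x)
  for (k in seq_along(tier_starts)) {
    block <- lines[tier_starts[k]:tier_ends[k]]
    if (!identical(unquote(get_field(block, "name")), "word")) next
    if (!grepl("IntervalTier", get_field(block, "class"))) {
      stop("tier 'word' is not an IntervalTier", call. = FALSE)
    }
    iv_starts <- grep("^intervals\\s*\\[\\d+\\]", block)
    if (!length(iv_starts)) {
      return(tibble::tibble(xmin = numeric(), xmax = numeric(),
                            label = character()))
    }
    iv_ends <- c(iv_starts[-1] - 1L, length(block))
    out <- purrr::map_dfr(seq_along(iv_starts), function(j) {
      b <- block[iv_starts[j]:iv_ends[j]]
      tibble::tibble(
        xmin = as.numeric(get_field(b, "xmin")),
        xmax = as.numeric(get_field(b, "xmax")),
        label = unquote(get_field(b, "text"))
      )
    })
    return(out)
  }
  stop("TextGrid has no interval tier named 'word'", call. = FALSE)
}

#' Write vocal events to delimited text
#'
#' Round-trips losslessly through [read_vocal_events()] (table format).
#'
#' @param track A `voice_track`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vocal_events <- function(track, path) {
  readr::write_csv(track$events, path, progress = FALSE)
  invisible(path)
}

#' Naming time of a run
#'
#' Time used to articulate all items of a run including errors: the offset
#' of the last articulation minus the onset of the first. Internal pauses
#' are included; omitted items contribute no boundary.
#'
#' @param track A `voice_track`.
#' @return Duration in seconds; `NA` (with a warning) for a track with no
#'   articulated intervals.
#' @export
naming_time <- function(track) {
  ev <- track$events[!is.na(track$events$onset_t), ]
  if (!nrow(ev)) {
    warning("naming_time undefined: no articulated events; run should be flagged")
    return(NA_real_)
  }
  max(ev$offset_t) - min(ev$onset_t)
}

#' Total error count of a run
#'
#' Sums all error annotations across events: repetitions, omissions,
#' substitutions, and self-corrections each count once per tag, so an event
#' carrying two tags contributes two.
#'
#' @param track A `voice_track`.
#' @return Non-negative integer count.
#' @export
count_errors <- function(track) {
  tags <- strsplit(track$events$error_tags, ";", fixed = TRUE)
  sum(lengths(tags))
}
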
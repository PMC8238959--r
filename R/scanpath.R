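#' Assign fixations to AOIs and build the visit sequence
#'
#' Annotates each fixation with the AOI containing its centroid. The visit
#' sequence keeps, in time order, fixations that land on an AOI within the
#' retained item range; off-array fixations are dropped from the sequence
#' but tallied, as are fixations on position-excluded items. Dropped
#' fixations do not break a perseveration block: blocks are defined on the
#' filtered sequence.
#'
#' @param fixations Time-ordered fixation tibble from [ivt_classify()].
#' @param array A `stimulus_array`.
#' @param retained Optional logical mask over serial indices 0..35 (see
#'   [positional_exclusion_mask()]); `NULL` retains all items.
#' @return An object of class `aoi_visit_sequence`: list with `entries`
#'   (tibble `fixation_idx`, `serial_index`), `fixations` (input annotated
#'   with an `aoi` column), `n_off_array`, `n_position_excluded`.
#' @export
assign_fixations <- function(fixations, array, retained = NULL) {
  aoi <- aoi_at_point(array, fixations$centroid_x_px, fixations$centroid_y_px)
  fixations$aoi <- aoi
  on_array <- !is.na(aoi)
  keep <- on_array
  n_pos <- 0L
  if (!is.null(retained)) {
    in_range <- on_array & retained[aoi + 1L]
    n_pos <- sum(on_array & !in_range)
    keep <- in_range
  }
  structure(
    list(entries = tibble::tibble(fixation_idx = which(keep),
                                  serial_index = aoi[keep]),
         fixations = fixations,
         n_off_array = sum(!on_array),
         n_position_excluded = n_pos),
    class = "aoi_visit_sequence"
  )
}

#' @export
print.aoi_visit_sequence <- function(x, ...) {
  cat(sprintf("<aoi_visit_sequence> %d entries (%d off-array, %d position-excluded)\n",
              nrow(x$entries), x$n_off_array, x$n_position_excluded))
  invisible(x)
}

seq_indices <- function(seq) {
  if (inherits(seq, "aoi_visit_sequence")) seq$entries$serial_index
  else as.integer(seq)
}

#' Total fixation count of a run
#'
#' Number of retained-item fixations before any pooling of consecutive
#' same-AOI fixations (the raw count).
#'
#' @param seq An `aoi_visit_sequence` (or a bare integer AOI sequence).
#' @return Non-negative integer.
#' @export
count_total_fixations <- function(seq) {
  length(seq_indices(seq))
}

#' Perseveration count
#'
#' Consecutively repeated fixations within the same item: each maximal block
#' of m consecutive same-AOI entries contributes m - 1.
#'
#' @inheritParams count_total_fixations
#' @return Non-negative integer.
#' @export
count_perseverations <- function(seq) {
  s <- seq_indices(seq)
  if (length(s) < 2) return(0L)
  sum(s[-1] == s[-length(s)])
}

#' Regression count
#'
#' Backward eye movements towards previously-visited items: transitions
#' whose target has a strictly lower serial index than the source AND was
#' fixated earlier in the sequence. A backward saccade to a never-visited
#' item counts as neither regression nor perseveration.
#'
#' @inheritParams count_total_fixations
#' @return Non-negative integer.
#' @export
count_regressions <- function(seq) {
  s <- seq_indices(seq)
  n <- length(s)
  if (n < 2) return(0L)
  count <- 0L
  seen <- logical(36L + max(s, 0L) + 1L)
  seen[s[1] + 1L] <- TRUE
  for (i in 2:n) {
    if (s[i] < s[i - 1] && seen[s[i] + 1L]) count <- count + 1L
    seen[s[i] + 1L] <- TRUE
  }
  count
}

#' Refixation count
#'
#' Perseverations plus regressions.
#'
#' @inheritParams count_total_fixations
#' @return Non-negative integer.
#' @export
count_refixations <- function(seq) {
  count_perseverations(seq) + count_regressions(seq)
}
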
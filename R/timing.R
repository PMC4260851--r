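#' Relative phase of a footfall within its bracketing beat interval
#'
#' The relative phase expresses where a footfall lands inside the interval
#' between the preceding and succeeding musical beat, scaled to degrees:
#' `phi_360 = 360 * (footfall_time - prev_beat_time) / (next_beat_time - prev_beat_time)`.
#' A footfall exactly on a beat has phase 0 degrees; a footfall exactly
#' between two beats (anti-phase, offbeat) has phase 180 degrees. For display
#' the phase is mapped to the signed scale `(-180, 180]`, where a negative
#' angle means the footfall preceded the beat and a positive angle means it
#' followed the beat.
#'
#' @param footfall_time Footfall time in seconds.
#' @param prev_beat_time Time of the preceding beat (seconds). Must satisfy
#'   `prev_beat_time <= footfall_time < next_beat_time`.
#' @param next_beat_time Time of the succeeding beat (seconds).
#' @return A one-row tibble with columns `phi_360` (degrees in `[0, 360)`),
#'   `phi_display` (degrees in `(-180, 180]`), `footfall_time`,
#'   `prev_beat_time`, `next_beat_time`. Inputs are vectorised; one row per
#'   footfall.
#' @examples
#' relative_phase(10.1, 10.0, 10.5) # phi_360 = 72
#' @export
relative_phase <- function(footfall_time, prev_beat_time, next_beat_time) {
  if (any(prev_beat_time >= next_beat_time)) {
    abort("invalid beat interval: prev_beat_time must be < next_beat_time",
          class = "gaitsync_invalid_interval")
  }
  if (any(footfall_time < prev_beat_time | footfall_time >= next_beat_time)) {
    abort(paste0("footfall must lie in [prev_beat_time, next_beat_time): ",
                 "a footfall exactly on a beat belongs to the interval it opens"),
          class = "gaitsync_invalid_interval")
  }
  phi <- 360 * (footfall_time - prev_beat_time) / (next_beat_time - prev_beat_time)
  tibble::tibble(
    phi_360 = phi,
    phi_display = to_display(phi),
    footfall_time = footfall_time,
    prev_beat_time = prev_beat_time,
    next_beat_time = next_beat_time
  )
}

#' Map a phase on \code{[0, 360)} to the signed display scale \code{(-180, 180]}
#'
#' The anti-phase boundary maps to +180 (single canonical value), so the
#' display scale is the half-open interval `(-180, 180]`.
#'
#' @param phi_360 Phase in degrees, in `[0, 360)`. Vectorised.
#' @return Phase in degrees in `(-180, 180]`, congruent to `phi_360` mod 360.
#' @examples
#' to_display(270) # -90
#' @export
to_display <- function(phi_360) {
  x <- wrap_360(phi_360)
  ifelse(x > 180, x - 360, x)
}

#' Per-step relative phase of a footfall log against a beat log
#'
#' Computes one relative-phase sample for every valid footfall bracketed by two
#' beats. Footfalls before the first beat or at/after the last beat yield no
#' sample; footfalls flagged invalid are skipped. Left and right steps are
#' treated identically: the phase is per step, not per gait cycle.
#'
#' @param footfalls A data frame with at least a `time_s` column; optional
#'   `valid` (logical or 0/1, default all valid) and `participant_id` columns.
#'   Must be sorted by time.
#' @param beats A data frame with at least a `time_s` column, sorted by time;
#'   optional `song_id` column (carried onto the sample via the preceding
#'   beat).
#' @return A tibble with one row per bracketed valid footfall: columns
#'   `participant_id` (if present), `time_s`, `phi_360`, `phi_display`,
#'   `prev_beat_time`, `next_beat_time`, and `song_id` (if present). Phases
#'   are only computed within a song: intervals whose two bracketing beats
#'   belong to different songs are skipped.
#' @examples
#' ff <- tibble::tibble(time_s = c(10.1, 10.6))
#' bb <- tibble::tibble(time_s = c(10, 10.5, 11))
#' phase_series(ff, bb)$phi_display # 72 72
#' @export
phase_series <- function(footfalls, beats) {
  stopifnot(is.data.frame(footfalls), is.data.frame(beats))
  empty <- tibble::tibble(
    time_s = double(), phi_360 = double(), phi_display = double(),
    prev_beat_time = double(), next_beat_time = double()
  )
  if (nrow(beats) < 2 || nrow(footfalls) == 0) {
    return(empty)
  }
  ft <- footfalls$time_s
  ok <- if ("valid" %in% names(footfalls)) as.logical(footfalls$valid) else rep(TRUE, length(ft))
  if (is.unsorted(ft[ok], strictly = FALSE)) {
    abort("footfall times must be sorted", class = "gaitsync_unsorted")
  }
  bt <- beats$time_s
  if (is.unsorted(bt, strictly = TRUE)) {
    abort("beat times must be strictly increasing", class = "gaitsync_unsorted")
  }
  # index of the beat interval owning each footfall: prev <= t < next
  idx <- findInterval(ft, bt)
  keep <- ok & idx >= 1 & idx < length(bt)
  if ("song_id" %in% names(beats)) {
    same_song <- beats$song_id[pmax(idx, 1)] == beats$song_id[pmin(idx + 1, length(bt))]
    keep <- keep & same_song
  }
  if (!any(keep)) {
    return(empty)
  }
  idx <- idx[keep]
  out <- relative_phase(ft[keep], bt[idx], bt[idx + 1])
  out <- dplyr::rename(out, time_s = "footfall_time")
  if ("participant_id" %in% names(footfalls)) {
    out <- tibble::add_column(out,
      participant_id = footfalls$participant_id[keep], .before = 1)
  }
  if ("song_id" %in% names(beats)) {
    out$song_id <- beats$song_id[idx]
  }
  out
}

#' Read and write the event-log CSV dialects
#'
#' Footfall logs have columns `participant_id`, `time_s`, `valid` (0/1);
#' beat logs have columns `song_id`, `beat_index`, `time_s`; phase logs have
#' columns `participant_id`, `time_s`, `phi_display_deg`, `song_id`.
#'
#' @param path File path.
#' @return `read_*` return tibbles; `write_*` return `path` invisibly.
#' @name event_io
NULL

#' @rdname event_io
#' @export
read_footfalls <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    time_s = readr::col_double(),
    valid = readr::col_integer()
  ))
}

#' @rdname event_io
#' @param footfalls Tibble with `participant_id`, `time_s`, `valid`.
#' @export
write_footfalls <- function(footfalls, path) {
  out <- dplyr::mutate(footfalls, valid = as.integer(.data$valid))
  readr::write_csv(out[c("participant_id", "time_s", "valid")], path)
  invisible(path)
}

#' @rdname event_io
#' @export
read_beats <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    song_id = readr::col_character(),
    beat_index = readr::col_integer(),
    time_s = readr::col_double()
  ))
}

#' @rdname event_io
#' @param beats Tibble with `song_id`, `beat_index`, `time_s`.
#' @export
write_beats <- function(beats, path) {
  readr::write_csv(beats[c("song_id", "beat_index", "time_s")], path)
  invisible(path)
}

#' @rdname event_io
#' @param phases Tibble as returned by [phase_series()] with a
#'   `participant_id` column.
#' @export
write_phases <- function(phases, path) {
  out <- tibble::tibble(
    participant_id = if ("participant_id" %in% names(phases)) phases$participant_id else NA_character_,
    time_s = phases$time_s,
    phi_display_deg = phases$phi_display,
    song_id = if ("song_id" %in% names(phases)) phases$song_id else NA_character_
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname event_io
#' @export
read_phases <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    time_s = readr::col_double(),
    phi_display_deg = readr::col_double(),
    song_id = readr::col_character()
  ))
}
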
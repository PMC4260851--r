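# Playback state: the timing contract of a tempo-stretching player. A song's
# nominal beat grid is replayed on the wall clock with each remaining
# inter-beat interval scaled by 1/tempo_modifier. Changing the modifier
# affects only beats not yet emitted; past beats are never rescheduled.
# Mutable state lives in an environment of class "playback".

#' Start playing a song
#'
#' Creates a playback whose beats are scheduled on the wall clock. With
#' `skip_to_first_beat = TRUE` the song is skipped so that its first beat
#' falls exactly at `wall_time` (used for phase-aligned song starts);
#' otherwise the song's leading silence (grid offset before the first beat)
#' is played, scaled by the modifier.
#'
#' @param song A one-row `song_library` tibble (e.g. from [nearest_song()]).
#' @param wall_time Start time in seconds on the simulation clock.
#' @param skip_to_first_beat Logical (default TRUE).
#' @param tempo_modifier Initial modifier (clamped to `clamp`).
#' @param clamp Length-2 allowed modifier range (default `c(0.9, 1.1)`: a
#'   20% total tempo adjustment range).
#' @param quantise When TRUE the modifier is additionally snapped to the
#'   discrete pre-rendered steps `{0.97, 0.98, ..., 1.03}`, emulating players
#'   without a continuous time-stretcher.
#' @return An environment of class `playback`.
#' @export
start_song <- function(song, wall_time, skip_to_first_beat = TRUE,
                       tempo_modifier = 1, clamp = c(0.9, 1.1),
                       quantise = FALSE) {
  stopifnot(nrow(song) == 1)
  iv <- song_intervals(song)
  pb <- new.env(parent = emptyenv())
  pb$song_id <- song$song_id
  pb$bpm <- song$bpm
  pb$intervals <- iv$intervals
  pb$n_beats <- length(iv$intervals) + 1L
  pb$clamp <- clamp
  pb$quantise <- quantise
  pb$tempo_modifier <- 1
  pb$last_request_in_range <- TRUE
  pb$emitted_times <- numeric(pb$n_beats)
  pb$emitted_count <- 0L
  pb$start_wall_time <- wall_time
  pb$first_beat_time <- if (skip_to_first_beat) wall_time else wall_time + iv$first_offset / tempo_modifier
  class(pb) <- "playback"
  set_tempo_modifier(pb, tempo_modifier)
  pb
}

#' Request a tempo modifier
#'
#' Stores the request clamped to the playback's allowed range and records
#' whether the unclamped request was in range — the strategy layer uses the
#' flag for its song-change debounce. In quantised mode the clamped value is
#' further snapped to the nearest available 1% step in `[0.97, 1.03]`.
#'
#' @param playback A `playback` environment.
#' @param modifier Requested modifier (> 0, dimensionless ratio).
#' @return The playback, invisibly; inspect `playback$tempo_modifier` and
#'   `playback$last_request_in_range`.
#' @export
set_tempo_modifier <- function(playback, modifier) {
  stopifnot(modifier > 0)
  playback$last_request_in_range <-
    modifier >= playback$clamp[1] && modifier <= playback$clamp[2]
  m <- min(max(modifier, playback$clamp[1]), playback$clamp[2])
  if (playback$quantise) {
    m <- min(max(round(m, 2), 0.97), 1.03)
  }
  playback$tempo_modifier <- m
  invisible(playback)
}

# scheduled time of the next unemitted beat (NA once the song has ended),
# always computed from the last emitted beat under the current modifier
peek_next_beat <- function(playback) {
  k <- playback$emitted_count
  if (k >= playback$n_beats) return(NA_real_)
  if (k == 0L) return(playback$first_beat_time)
  playback$emitted_times[k] + playback$intervals[k] / playback$tempo_modifier
}

# emit all beats scheduled at or before `until`; returns number emitted
advance_playback <- function(playback, until) {
  emitted <- 0L
  repeat {
    t_next <- peek_next_beat(playback)
    if (is.na(t_next) || t_next > until) break
    playback$emitted_count <- playback$emitted_count + 1L
    playback$emitted_times[playback$emitted_count] <- t_next
    emitted <- emitted + 1L
  }
  emitted
}

playback_finished <- function(playback) playback$emitted_count >= playback$n_beats

#' Beats already emitted by a playback
#'
#' @param playback A `playback` environment.
#' @return A tibble with `song_id`, `beat_index` (0-based, consecutive),
#'   `time_s`.
#' @export
emitted_beats <- function(playback) {
  k <- playback$emitted_count
  tibble::tibble(
    song_id = rep(playback$song_id, k),
    beat_index = seq_len(k) - 1L,
    time_s = playback$emitted_times[seq_len(k)]
  )
}

#' Preview the future beat schedule
#'
#' Computes the beats not yet emitted, out to `horizon` seconds past the
#' last emitted beat (or the scheduled first beat), under the current
#' modifier: the remaining nominal inter-beat intervals are scaled by
#' `1 / tempo_modifier`. Purely a preview — nothing is emitted.
#'
#' @param playback A `playback` environment.
#' @param horizon Look-ahead in seconds.
#' @return A tibble with `song_id`, `beat_index`, `time_s`.
#' @export
next_beats <- function(playback, horizon) {
  k <- playback$emitted_count
  if (k >= playback$n_beats) {
    return(tibble::tibble(song_id = character(), beat_index = integer(),
                          time_s = double()))
  }
  t0 <- peek_next_beat(playback)
  rest <- playback$intervals[seq_len(playback$n_beats - 1L)][seq(k + 1, length.out = playback$n_beats - k - 1L)]
  times <- c(t0, t0 + cumsum(rest / playback$tempo_modifier))
  ref <- if (k == 0L) t0 else playback$emitted_times[k]
  keep <- times <= ref + horizon
  tibble::tibble(
    song_id = rep(playback$song_id, sum(keep)),
    beat_index = (seq_along(times) + k - 1L)[keep],
    time_s = times[keep]
  )
}

#' @export
print.playback <- function(x, ...) {
  cat(sprintf("<playback> song %s (%.1f bpm), modifier %.3f, %d/%d beats emitted\n",
              x$song_id, x$bpm, x$tempo_modifier, x$emitted_count, x$n_beats))
  invisible(x)
}
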
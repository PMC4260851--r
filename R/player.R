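# The adaptive player as a per-step state machine. Four controllers share one
# event loop; they differ in how the tempo modifier is driven and how song
# changes are phased:
#   1 period-adaptive, phase-random: modifier tracks SPM/BPM every step; song
#     changes (tempo stretch out of range for > 5 s, or song end) start at a
#     random phase.
#   2 period-fixed, phase-random: the modifier is set once per song; nothing
#     is adapted mid-song.
#   3 period-adaptive, phase-aligned start: as 1, but new songs are queued
#     and started, skipped to their first beat, at the wall time where the
#     walker's predicted phase equals the configured start phase (0 or 180).
#   4 period- and phase-adaptive: as 3 (start phase 0), plus a +-0.03
#     modifier nudge whenever the current step's phase leaves the +-30 degree
#     synchronisation band.

#' Strategy configuration
#'
#' @param strategy Which controller: 1, 2, 3 or 4.
#' @param start_phase_deg Song-start phase for strategy 3 (0 or 180); strategy
#'   4 uses it too (default 0).
#' @param band_deg Half-width of the allowed synchronisation range for the
#'   strategy-4 nudge (default 30 degrees).
#' @param nudge Additive tempo-modifier increment applied (at most once per
#'   detected step) when the phase leaves the band (default 0.03).
#' @param clamp Allowed modifier range (default `c(0.9, 1.1)`).
#' @param debounce_s Seconds an out-of-range tempo request must persist before
#'   a song change is triggered (default 5).
#' @param avg_window_steps Cadence averaging window in steps (default 5).
#' @param harmonic_margin Relative margin of the harmonic step-acceptance rule
#'   (default 0.2).
#' @param quantise Snap modifiers to 1% steps in `[0.97, 1.03]` (discrete
#'   pre-rendered versions instead of a continuous stretcher).
#' @param exclude_played Songs already played are excluded from reselection
#'   (default TRUE).
#' @return A list of class `strategy_config`.
#' @export
strategy_config <- function(strategy = 1, start_phase_deg = 0, band_deg = 30,
                            nudge = 0.03, clamp = c(0.9, 1.1), debounce_s = 5,
                            avg_window_steps = 5, harmonic_margin = 0.2,
                            quantise = FALSE, exclude_played = TRUE) {
  stopifnot(strategy %in% 1:4, start_phase_deg %in% c(0, 180),
            band_deg > 0, band_deg < 180, nudge > 0,
            length(clamp) == 2, all(clamp > 0), clamp[1] < clamp[2])
  structure(
    list(strategy = as.integer(strategy), start_phase_deg = start_phase_deg,
         band_deg = band_deg, nudge = nudge, clamp = clamp,
         debounce_s = debounce_s, avg_window_steps = avg_window_steps,
         harmonic_margin = harmonic_margin, quantise = quantise,
         exclude_played = exclude_played),
    class = "strategy_config"
  )
}

#' Create the controller state for a trial
#'
#' @param library A `song_library`.
#' @param cfg A [strategy_config()].
#' @return An environment of class `strategy_state`. Fields of interest:
#'   `playback` (current [start_song()] playback or NULL), `estimate`
#'   (the [new_gait_estimate()]), `out_of_range_since`, `queued`, `delta`
#'   (music tempo minus instantaneous, non-averaged, gait tempo in
#'   beats/steps per minute), and the accumulated `beat log` / `trace`
#'   retrievable with [controller_results()].
#' @export
new_strategy_state <- function(library, cfg = strategy_config()) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$library <- library
  st$playback <- NULL
  st$estimate <- new_gait_estimate(cfg$avg_window_steps, cfg$harmonic_margin)
  st$last_step_time <- NA_real_
  st$out_of_range_since <- NA_real_
  st$queued <- NULL
  st$played <- character(0)
  st$delta <- NA_real_
  st$override_phi <- NULL
  st$finished_beats <- list()
  st$step_count <- 0L
  st$cap <- 2048L
  st$tr_time <- numeric(2048L)
  st$tr_spm <- numeric(2048L)
  st$tr_base <- numeric(2048L)
  st$tr_nudge <- numeric(2048L)
  st$tr_final <- numeric(2048L)
  st$tr_phi <- numeric(2048L)
  st$tr_delta <- numeric(2048L)
  st$tr_song <- character(2048L)
  st$tr_event <- character(2048L)
  class(st) <- "strategy_state"
  st
}

trace_grow <- function(st) {
  new_cap <- st$cap * 2L
  for (f in c("tr_time", "tr_spm", "tr_base", "tr_nudge", "tr_final",
              "tr_phi", "tr_delta")) {
    st[[f]] <- c(st[[f]], numeric(st$cap))
  }
  st$tr_song <- c(st$tr_song, character(st$cap))
  st$tr_event <- c(st$tr_event, character(st$cap))
  st$cap <- new_cap
}

archive_playback <- function(st) {
  if (!is.null(st$playback) && st$playback$emitted_count > 0) {
    st$finished_beats[[length(st$finished_beats) + 1L]] <- emitted_beats(st$playback)
  }
}

# phase of a footfall at time t against the currently heard schedule:
# preceding emitted beat and succeeding scheduled beat of the same playback
player_phase <- function(st, t) {
  pb <- st$playback
  if (is.null(pb) || pb$emitted_count == 0L) return(NA_real_)
  t_prev <- pb$emitted_times[pb$emitted_count]
  t_next <- peek_next_beat(pb)
  if (is.na(t_next) || t < t_prev || t >= t_next) return(NA_real_)
  to_display(360 * (t - t_prev) / (t_next - t_prev))
}

start_random_phase <- function(st, song, t, modifier) {
  # "a new song then begins at a random time between footsteps": the first
  # beat lands uniformly within one beat period after the triggering step
  m <- min(max(modifier, st$cfg$clamp[1]), st$cfg$clamp[2])
  t_beat <- 60 / (song$bpm * m)
  offset <- runif(1) * t_beat
  st$playback <- start_song(song, t + offset, skip_to_first_beat = TRUE,
                            tempo_modifier = modifier, clamp = st$cfg$clamp,
                            quantise = st$cfg$quantise)
  st$played <- c(st$played, song$song_id)
}

queue_aligned <- function(st, song, modifier) {
  # scheduled at the next accepted step, from that step's inter-step interval
  st$queued <- list(song = song, modifier = modifier, start_time = NA_real_)
}

schedule_queued <- function(st, t) {
  q <- st$queued
  t_step <- st$estimate$last_interval
  if (is.null(q) || is.na(t_step)) return(invisible(NULL))
  m <- min(max(q$modifier, st$cfg$clamp[1]), st$cfg$clamp[2])
  t_beat <- 60 / (q$song$bpm * m)
  start <- t + t_step
  if (st$cfg$start_phase_deg == 180) {
    start <- start - t_beat / 2
  }
  st$queued$start_time <- start
  invisible(NULL)
}

choose_song <- function(st, target_spm) {
  excl <- if (st$cfg$exclude_played) st$played else character(0)
  # never strand the player: if everything has been played, reopen the library
  if (nrow(st$library) - length(excl) <= 0) excl <- character(0)
  nearest_song(st$library, target_spm, exclude = excl)
}

# song change triggered mid-song or at song end; phase handling per strategy
change_song <- function(st, t, spm) {
  song <- choose_song(st, spm)
  modifier <- spm / song$bpm
  if (st$cfg$strategy %in% c(1L, 2L)) {
    archive_playback(st)
    start_random_phase(st, song, t, modifier)
  } else {
    queue_aligned(st, song, modifier)
    schedule_queued(st, t)
  }
}

#' Advance the controller by one detected footfall
#'
#' The shared per-step loop: switch to a queued song if its scheduled start
#' has passed, advance the beat schedule to the footfall, update the cadence
#' estimate (harmonic acceptance), then apply the configured strategy's
#' tempo/song actions, and append a trace row.
#'
#' @param state A `strategy_state` environment.
#' @param footfall_time Time of the detected footfall (seconds).
#' @param now Wall time (defaults to the footfall time; the loop is
#'   event-driven).
#' @return The state, invisibly.
#' @export
strategy_step <- function(state, footfall_time, now = footfall_time) {
  st <- state
  t <- footfall_time
  cfg <- st$cfg
  event <- "none"

  # 1. queued song whose start time has been reached takes over the playback
  if (!is.null(st$queued) && !is.na(st$queued$start_time) &&
      st$queued$start_time <= t) {
    q <- st$queued
    if (!is.null(st$playback)) {
      advance_playback(st$playback, min(t, q$start_time))
      archive_playback(st)
    }
    st$playback <- start_song(q$song, q$start_time, skip_to_first_beat = TRUE,
                              tempo_modifier = q$modifier, clamp = cfg$clamp,
                              quantise = cfg$quantise)
    st$played <- c(st$played, q$song$song_id)
    st$queued <- NULL
    st$out_of_range_since <- NA_real_
    event <- "queued_start"
  }

  # 2. play out beats up to this footfall under the current modifier
  if (!is.null(st$playback)) advance_playback(st$playback, t)

  # 3. cadence estimate
  accepted <- TRUE
  if (!is.na(st$last_step_time)) {
    st$estimate <- update_gait_estimate(st$estimate, t, st$last_step_time)
    accepted <- st$estimate$accepted
    if (accepted) st$last_step_time <- t
  } else {
    st$last_step_time <- t
    accepted <- FALSE # no interval yet: nothing for the controller to act on
  }
  spm <- st$estimate$spm

  phi <- player_phase(st, t)
  if (!is.null(st$override_phi)) {
    phi <- st$override_phi
    st$override_phi <- NULL
  }
  base <- NA_real_
  nudge_term <- 0

  if (st$estimate$valid && identical(st$estimate$accepted, FALSE)) {
    event <- "rejected_step"
  }

  if (accepted && !is.na(spm)) {
    # 4. first song of the trial
    if (is.null(st$playback) && is.null(st$queued)) {
      song <- choose_song(st, spm)
      modifier <- spm / song$bpm
      if (cfg$strategy %in% c(1L, 2L)) {
        start_random_phase(st, song, t, modifier)
        event <- "song_change"
      } else {
        queue_aligned(st, song, modifier)
        schedule_queued(st, t)
        event <- "queued_start_pending"
      }
    } else if (!is.null(st$playback) && playback_finished(st$playback) &&
               is.null(st$queued)) {
      # 5. song ended naturally
      change_song(st, t, spm)
      event <- "song_change"
    } else if (!is.null(st$playback)) {
      # 6. per-step tempo control
      if (cfg$strategy != 2L) {
        base <- spm / st$playback$bpm
        in_range <- base >= cfg$clamp[1] && base <= cfg$clamp[2]
        if (cfg$strategy == 4L && !is.na(phi)) {
          # a step lagging the beat (phi > 0) needs the next beats delayed:
          # lower the tempo so the beat drifts back onto the footfall, and
          # vice versa; the per-step phase velocity is 360*(Tstep/Tbeat - 1)
          # degrees, so the nudge drives |phi| down by ~10.8 degrees per step
          if (phi > cfg$band_deg) nudge_term <- -cfg$nudge
          else if (phi < -cfg$band_deg) nudge_term <- cfg$nudge
        }
        set_tempo_modifier(st$playback, max(base + nudge_term, 1e-6))
        # debounced song change on persistent out-of-range stretch
        if (!in_range) {
          if (is.na(st$out_of_range_since)) {
            st$out_of_range_since <- now
          } else if (now - st$out_of_range_since > cfg$debounce_s &&
                     is.null(st$queued)) {
            change_song(st, t, spm)
            st$out_of_range_since <- NA_real_
            event <- "song_change"
          }
        } else {
          st$out_of_range_since <- NA_real_
        }
      }
      # queued song waiting for its schedule (e.g. first song of a 3/4 trial)
      if (!is.null(st$queued) && is.na(st$queued$start_time)) {
        schedule_queued(st, t)
      }
    }
    if (!is.null(st$playback)) {
      st$delta <- st$playback$bpm * st$playback$tempo_modifier - 60 / st$estimate$last_interval
    }
  }

  # 7. trace
  st$step_count <- st$step_count + 1L
  if (st$step_count > st$cap) trace_grow(st)
  i <- st$step_count
  st$tr_time[i] <- t
  st$tr_spm[i] <- if (is.na(spm)) NA_real_ else spm
  st$tr_base[i] <- base
  st$tr_nudge[i] <- nudge_term
  st$tr_final[i] <- if (is.null(st$playback)) NA_real_ else st$playback$tempo_modifier
  st$tr_phi[i] <- phi
  st$tr_delta[i] <- st$delta
  st$tr_song[i] <- if (is.null(st$playback)) NA_character_ else st$playback$song_id
  st$tr_event[i] <- event
  invisible(st)
}

#' Single-step entry points of the four controllers
#'
#' Thin wrappers over [strategy_step()] that assert which controller the
#' state was configured with. `step_strategy4` additionally accepts the
#' current step's display phase for callers that compute it externally; when
#' omitted the controller's own phase estimate (preceding emitted beat,
#' succeeding scheduled beat) is used.
#'
#' @param state A `strategy_state` configured for the matching strategy.
#' @param footfall_time,now See [strategy_step()].
#' @param phi_display Optional externally supplied phase for strategy 4.
#' @return The state, invisibly.
#' @name step_strategies
NULL

#' @rdname step_strategies
#' @export
step_strategy1 <- function(state, footfall_time, now = footfall_time) {
  stopifnot(state$cfg$strategy == 1L)
  strategy_step(state, footfall_time, now)
}

#' @rdname step_strategies
#' @export
step_strategy2 <- function(state, footfall_time, now = footfall_time) {
  stopifnot(state$cfg$strategy == 2L)
  strategy_step(state, footfall_time, now)
}

#' @rdname step_strategies
#' @export
step_strategy3 <- function(state, footfall_time, now = footfall_time) {
  stopifnot(state$cfg$strategy == 3L)
  strategy_step(state, footfall_time, now)
}

#' @rdname step_strategies
#' @export
step_strategy4 <- function(state, footfall_time, phi_display = NULL,
                           now = footfall_time) {
  stopifnot(state$cfg$strategy == 4L)
  if (!is.null(phi_display)) {
    # honour an externally measured phase for this one step
    state$override_phi <- phi_display
  }
  strategy_step(state, footfall_time, now)
}

#' Collect the logs of a finished controller run
#'
#' @param state A `strategy_state` after the last step.
#' @param finalize Emit the beat that brackets the final footfalls so every
#'   phase sample is re-derivable from the beat log (default TRUE).
#' @return A list with `beats` (tibble `song_id`, `beat_index`, `time_s`),
#'   `trace` (tibble `step_index`, `time_s`, `spm`, `base_modifier`, `nudge`,
#'   `final_modifier`, `phi_display`, `delta`, `song_id`, `event`).
#' @export
controller_results <- function(state, finalize = TRUE) {
  st <- state
  if (finalize && !is.null(st$playback) && !playback_finished(st$playback)) {
    # emit exactly one more beat: the "succeeding beat" of the last steps
    t_next <- peek_next_beat(st$playback)
    if (!is.na(t_next)) advance_playback(st$playback, t_next)
  }
  archive_playback(st)
  st$playback <- NULL
  n <- st$step_count
  idx <- seq_len(n)
  trace <- tibble::tibble(
    step_index = idx,
    time_s = st$tr_time[idx],
    spm = st$tr_spm[idx],
    base_modifier = st$tr_base[idx],
    nudge = st$tr_nudge[idx],
    final_modifier = st$tr_final[idx],
    phi_display = st$tr_phi[idx],
    delta = st$tr_delta[idx],
    song_id = st$tr_song[idx],
    event = st$tr_event[idx]
  )
  beats <- dplyr::bind_rows(st$finished_beats)
  if (nrow(beats) == 0) {
    beats <- tibble::tibble(song_id = character(), beat_index = integer(),
                            time_s = double())
  }
  list(beats = beats, trace = trace)
}

#' Replay a footfall stream through a strategy
#'
#' The open-loop driver: feeds an existing (recorded or simulated) footfall
#' log through the configured controller and returns the full beat schedule,
#' the per-step relative phases, and the controller trace. Invalid footfalls
#' are skipped. Phases are computed from the emitted logs via
#' [phase_series()], so they are exactly re-derivable from the returned
#' `beats` and the input footfalls.
#'
#' @param library A `song_library`.
#' @param footfalls Tibble with `time_s` (sorted) and optional `valid`,
#'   `participant_id` columns.
#' @param cfg A [strategy_config()].
#' @return A list with `beats`, `phases`, `trace` (see
#'   [controller_results()]; `phases` as in [phase_series()]).
#' @export
run_controller <- function(library, footfalls, cfg = strategy_config()) {
  if (nrow(library) == 0) {
    abort("empty song library", class = "gaitsync_selection")
  }
  st <- new_strategy_state(library, cfg)
  ok <- if ("valid" %in% names(footfalls)) as.logical(footfalls$valid) else rep(TRUE, nrow(footfalls))
  times <- footfalls$time_s[ok]
  for (t in times) strategy_step(st, t)
  res <- controller_results(st)
  res$phases <- phase_series(footfalls, res$beats)
  res
}
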
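# Synthetic walker: a stochastic cadence generator with an attractor-based
# entrainment response to the heard beat. The walker is a discrete per-step
# phase-correction map, not a continuous-time ODE: footfalls are the only
# actionable instants, and the map reproduces the coupled-oscillator (HKB)
# fixed-point structure — a stable in-phase attractor at 0 degrees and, when
# the second harmonic coupling is strong enough (2*coupling_b > coupling_a),
# a weaker locally stable anti-phase attractor at 180 degrees with a smaller
# basin.

#' Walker parameters
#'
#' The (n+1)-th inter-step interval is
#' `60/base_spm / detuning + noise - correction`, with
#' `correction = (coupling_a * sin(phi) + coupling_b * sin(2 * phi)) * T_beat / (2 * pi)`
#' seconds, where `phi` is the walker's current relative phase to the heard
#' beats and `T_beat` the current beat period. With zero couplings the walker
#' ignores the music entirely.
#'
#' @param base_spm Intrinsic cadence, steps per minute (> 0).
#' @param noise_sd Step-interval standard deviation in seconds (>= 0).
#'   Default 0.015 s, about 3% of a walking step period — mid-range for the
#'   step-to-step variability of healthy natural walking.
#' @param coupling_a Gain of the in-phase attractor term (`sin phi`), >= 0.
#' @param coupling_b Gain of the anti-phase attractor term (`sin 2 phi`), >= 0.
#' @param detuning Ratio of intrinsic to nominal tempo (around 1); values
#'   above 1 make the walker faster than its `base_spm`.
#' @param noise_type `"white"` (independent Gaussian perturbations, the
#'   default) or `"pink"` (long-memory perturbations with a 1/f-like
#'   spectrum, synthesised spectrally, matching the serial structure of real
#'   gait timing more closely).
#' @param participant_id Label carried into the footfall log.
#' @return A list of class `walker_params`.
#' @export
walker_params <- function(base_spm = 115, noise_sd = 0.015, coupling_a = 0.2,
                          coupling_b = 0.12, detuning = 1,
                          noise_type = c("white", "pink"),
                          participant_id = "walker") {
  stopifnot(base_spm > 0, noise_sd >= 0, coupling_a >= 0, coupling_b >= 0,
            detuning > 0)
  structure(
    list(base_spm = base_spm, noise_sd = noise_sd, coupling_a = coupling_a,
         coupling_b = coupling_b, detuning = detuning,
         noise_type = match.arg(noise_type),
         participant_id = participant_id),
    class = "walker_params"
  )
}

# long-memory step-interval noise: random-phase spectral synthesis with a
# 1/f power spectrum, rescaled to the requested standard deviation
pink_noise <- function(n, sd) {
  if (n < 4 || sd == 0) return(rnorm(n, 0, sd))
  m <- 2^ceiling(log2(n))
  half <- m / 2
  amp <- c(0, 1 / sqrt(seq_len(half - 1)), 1 / sqrt(half))
  phase <- runif(half + 1, 0, 2 * pi)
  spec <- c(amp * exp(1i * phase), Conj(rev((amp * exp(1i * phase))[2:half])))
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  (x - mean(x)) / stats::sd(x) * sd
}

#' Scenario events disturbing a walk
#'
#' @param time Event times in seconds (within the trial duration).
#' @param kind One of `"pause"` (a gap of `magnitude` seconds plus a random
#'   fraction of a step period, randomising the walker's phase),
#'   `"cadence_jump"` (adds `magnitude` steps per minute to the intrinsic
#'   cadence from then on) or `"missed_step"` (the next footfall occurs but
#'   is not detected: logged invalid, hidden from the controller).
#' @param magnitude Kind-specific magnitude.
#' @return A tibble with columns `time`, `kind`, `magnitude`.
#' @export
scenario_events <- function(time, kind, magnitude = 0) {
  stopifnot(all(kind %in% c("pause", "cadence_jump", "missed_step")))
  tibble::tibble(time = time, kind = kind,
                 magnitude = rep_len(magnitude, length(time)))
}

#' Simulate a closed-loop walk
#'
#' Generates footfalls step by step. After every step the `player_callback`
#' is invoked with the footfall time, so the loop is genuinely closed: the
#' player may reschedule beats in response to each step. The callback must
#' return the bracketing heard beats for the step — `c(prev_beat_time,
#' next_beat_time)` — or `NULL` while no music is playing; the walker's
#' phase-correction map acts on the phase within that interval.
#'
#' @param walker A [walker_params()].
#' @param player_callback `function(footfall_time)` returning `NULL` or the
#'   numeric pair `c(prev, next)` with `prev <= footfall_time < next`. See
#'   [strategy_player_callback()] for the bridge to a controller state.
#' @param duration Trial duration in seconds (> 0); the first step falls one
#'   intrinsic period after time 0 and steps at exactly `duration` are kept.
#' @param scenario Optional [scenario_events()] tibble.
#' @return A footfall tibble: `participant_id`, `time_s`, `valid` (logical).
#' @examples
#' w <- walker_params(base_spm = 120, noise_sd = 0, coupling_a = 0)
#' ff <- simulate_walk(w, function(t) NULL, duration = 60)
#' nrow(ff) # 120
#' @export
simulate_walk <- function(walker, player_callback, duration, scenario = NULL) {
  stopifnot(duration > 0)
  t_intr <- 60 / walker$base_spm / walker$detuning
  base_spm <- walker$base_spm
  cap <- as.integer(ceiling(duration / t_intr * 2)) + 16L
  times <- numeric(cap)
  valid <- logical(cap)
  n <- 0L
  t <- t_intr
  last_prev <- -Inf
  sc <- if (is.null(scenario) || nrow(scenario) == 0) NULL else scenario[order(scenario$time), ]
  sc_i <- 1L
  miss_next <- FALSE
  eps <- 1e-9
  pink <- !is.null(walker$noise_type) && walker$noise_type == "pink"
  if (pink) noise_buf <- pink_noise(cap, walker$noise_sd)
  noise_i <- 0L
  while (t <= duration + eps) {
    # scenario events that have come due before this step
    while (!is.null(sc) && sc_i <= nrow(sc) && sc$time[sc_i] <= t) {
      ev <- sc[sc_i, ]
      sc_i <- sc_i + 1L
      if (ev$kind == "pause") {
        t <- t + ev$magnitude + runif(1) * t_intr
        if (t > duration + eps) break
      } else if (ev$kind == "cadence_jump") {
        base_spm <- base_spm + ev$magnitude
        t_intr <- 60 / base_spm / walker$detuning
      } else if (ev$kind == "missed_step") {
        miss_next <- TRUE
      }
    }
    if (t > duration + eps) break
    n <- n + 1L
    if (n > cap) {
      times <- c(times, numeric(cap)); valid <- c(valid, logical(cap))
      cap <- 2L * cap
    }
    times[n] <- t
    valid[n] <- !miss_next
    correction <- 0
    if (!miss_next) {
      beats <- player_callback(t)
      if (!is.null(beats)) {
        if (length(beats) != 2 || beats[2] <= beats[1] || beats[1] < last_prev - eps) {
          abort("player callback returned a non-monotone beat schedule",
                class = "gaitsync_simulation")
        }
        last_prev <- beats[1]
        if (t >= beats[1] - eps && t < beats[2]) {
          t_beat <- beats[2] - beats[1]
          phi <- 2 * pi * (t - beats[1]) / t_beat
          correction <- (walker$coupling_a * sin(phi) +
                           walker$coupling_b * sin(2 * phi)) * t_beat / (2 * pi)
        }
      }
    }
    miss_next <- FALSE
    noise_i <- noise_i + 1L
    eta <- if (pink) {
      if (noise_i > length(noise_buf)) {
        noise_buf <- c(noise_buf, pink_noise(length(noise_buf), walker$noise_sd))
      }
      noise_buf[noise_i]
    } else {
      rnorm(1, 0, walker$noise_sd)
    }
    interval <- t_intr + eta - correction
    interval <- max(interval, 0.25 * t_intr) # a step can only be so short
    t <- t + interval
  }
  idx <- seq_len(n)
  tibble::tibble(participant_id = rep(walker$participant_id, n),
                 time_s = times[idx], valid = valid[idx])
}

#' Bridge a controller state into a walker callback
#'
#' Returns the `player_callback` closing the loop between
#' [simulate_walk()] and a [new_strategy_state()]: each footfall is (after
#' optional sensor quantisation) fed to [strategy_step()], and the bracketing
#' heard beats are returned to the walker.
#'
#' @param state A `strategy_state`.
#' @param sensor Optional [sensor_params()]; when given, the controller sees
#'   footfall times quantised to the sensor tick while the walker keeps the
#'   true times.
#' @return `function(t)` suitable for [simulate_walk()].
#' @export
strategy_player_callback <- function(state, sensor = NULL) {
  rate <- if (is.null(sensor)) NA_real_ else sensor$sample_rate
  function(t) {
    td <- if (is.na(rate)) t else ceiling(t * rate - 1e-9) / rate
    strategy_step(state, td)
    pb <- state$playback
    if (is.null(pb) || pb$emitted_count == 0L) return(NULL)
    t_next <- peek_next_beat(pb)
    if (is.na(t_next)) return(NULL)
    c(pb$emitted_times[pb$emitted_count], t_next)
  }
}

#' Sensor parameters
#'
#' @param sample_rate Sampling rate in Hz (default 100, i.e. 10 ms ticks).
#' @return A list of class `sensor_params`.
#' @export
sensor_params <- function(sample_rate = 100) {
  stopifnot(sample_rate > 0)
  structure(list(sample_rate = sample_rate), class = "sensor_params")
}

#' Quantise event times to the sensor grid
#'
#' A sampled sensor cannot report an event before it happens, so every event
#' time is moved up to the next sample tick (events already on a tick stay
#' put). The per-event error is strictly below one sample period — at 100 Hz
#' a mean error of about 5 ms and 10 ms maximum — and ordering is never
#' disturbed.
#'
#' @param events A tibble with a `time_s` column (e.g. a footfall log).
#' @param sensor A [sensor_params()].
#' @return The tibble with `time_s` replaced by the quantised times.
#' @export
quantise_events <- function(events, sensor = sensor_params()) {
  rate <- sensor$sample_rate
  dplyr::mutate(events, time_s = ceiling(.data$time_s * rate - 1e-9) / rate)
}

#' Generate a cohort of walkers
#'
#' Reproducible draws spanning the given parameter ranges, one derived
#' sub-seed per participant so cohorts are extensible without perturbing
#' earlier participants. A configurable fraction of the cohort are
#' non-entrainers (both couplings zero): people who do not synchronise to
#' auditory stimuli exist in every population.
#'
#' @param n_participants Cohort size (>= 1).
#' @param param_ranges Named list of length-2 inclusive ranges for any of
#'   `base_spm`, `noise_sd`, `coupling_a`, `coupling_b`, `detuning`; missing
#'   entries use the defaults shown.
#' @param seed Integer master seed.
#' @param nonentrainer_fraction Fraction of participants with zero couplings
#'   (default 0.2); the count is `round(fraction * n)` and always the last
#'   participants of the cohort.
#' @return A tibble with one row per participant: `participant_id`,
#'   `base_spm`, `noise_sd`, `coupling_a`, `coupling_b`, `detuning`,
#'   `entrainer`, `sub_seed`.
#' @export
make_cohort <- function(n_participants, param_ranges = list(), seed = 1,
                        nonentrainer_fraction = 0.2) {
  stopifnot(n_participants >= 1)
  rng <- list(base_spm = c(110, 125), noise_sd = c(0.01, 0.02),
              coupling_a = c(0.15, 0.3), coupling_b = c(0.08, 0.18),
              detuning = c(0.99, 1.01))
  for (nm in names(param_ranges)) {
    stopifnot(nm %in% names(rng), length(param_ranges[[nm]]) == 2,
              param_ranges[[nm]][1] <= param_ranges[[nm]][2])
    rng[[nm]] <- param_ranges[[nm]]
  }
  n_non <- round(nonentrainer_fraction * n_participants)
  rows <- purrr::map(seq_len(n_participants), function(i) {
    draws <- withr::with_seed(derive_seed(seed, i), {
      purrr::map_dbl(rng, function(r) runif(1, r[1], r[2]))
    })
    entrainer <- i <= n_participants - n_non
    tibble::tibble(
      participant_id = sprintf("p%03d", i),
      base_spm = draws[["base_spm"]],
      noise_sd = draws[["noise_sd"]],
      coupling_a = if (entrainer) draws[["coupling_a"]] else 0,
      coupling_b = if (entrainer) draws[["coupling_b"]] else 0,
      detuning = draws[["detuning"]],
      entrainer = entrainer,
      sub_seed = derive_seed(seed, i)
    )
  })
  dplyr::bind_rows(rows)
}

# documented counter scheme: one sub-seed per (master, counter) pair, kept
# inside the 32-bit signed integer range
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 1000003 + as.double(counter) * 7919) %% 2147483647)
}

#' Turn a cohort row into walker parameters
#'
#' @param cohort_row One row of [make_cohort()].
#' @return A [walker_params()].
#' @export
cohort_walker <- function(cohort_row) {
  walker_params(base_spm = cohort_row$base_spm,
                noise_sd = cohort_row$noise_sd,
                coupling_a = cohort_row$coupling_a,
                coupling_b = cohort_row$coupling_b,
                detuning = cohort_row$detuning,
                participant_id = cohort_row$participant_id)
}
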
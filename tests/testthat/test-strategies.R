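one_song_library <- function(bpm = 120, duration_s = 300) {
  song_library("only", bpm, duration_s = duration_s)
}

test_that("period-adaptive control sets the modifier to SPM over BPM", {
  ff <- periodic_footfalls(spm = 126, duration = 30)
  res <- run_controller(one_song_library(120), ff, strategy_config(strategy = 1))
  tr <- res$trace
  settled <- tr[tr$time_s > 5 & !is.na(tr$base_modifier), ]
  expect_equal(unique(round(settled$base_modifier, 10)), 1.05)
  expect_equal(unique(round(settled$final_modifier, 10)), 1.05)
})

test_that("a matched cadence leaves the tempo untouched and the song playing", {
  ff <- periodic_footfalls(spm = 120, duration = 60)
  res <- run_controller(one_song_library(120), ff, strategy_config(strategy = 1))
  tr <- res$trace
  expect_equal(unique(round(tr$final_modifier[!is.na(tr$final_modifier)], 10)), 1)
  expect_false(any(tr$event == "song_change" & tr$step_index > 5))
})

test_that("a persistent out-of-range stretch triggers a debounced song change", {
  lib <- song_library(c("s100", "s120", "s140"), c(100, 120, 140), duration_s = 600)
  # walk at 120 for 20 s, then jump to 140 spm (ratio 140/120 = 1.17 > 1.1)
  t1 <- seq(0.5, 20, by = 0.5)
  t2 <- seq(20 + 60 / 140, 40, by = 60 / 140)
  ff <- tibble::tibble(time_s = c(t1, t2))
  res <- run_controller(lib, ff, strategy_config(strategy = 1))
  tr <- res$trace
  changes <- tr[tr$event == "song_change" & tr$time_s > 20, ]
  expect_gte(nrow(changes), 1)
  # the change happens only after the 5 s debounce, onto the nearest tempo
  expect_gt(changes$time_s[1], 25)
  expect_equal(changes$song_id[1], "s140")
})

test_that("period-fixed control changes tempo only at song boundaries", {
  lib <- song_library(c("a", "b", "c"), c(120, 118, 122), duration_s = 60)
  # cadence drifts smoothly from 115 to 125 spm across two songs
  times <- c(0)
  spm <- 115
  while (tail(times, 1) < 150) {
    spm <- min(125, spm + 0.05)
    times <- c(times, tail(times, 1) + 60 / spm)
  }
  ff <- tibble::tibble(time_s = times[-1])
  res <- run_controller(lib, ff, strategy_config(strategy = 2))
  tr <- res$trace[!is.na(res$trace$song_id), ]
  per_song <- tapply(round(tr$final_modifier, 12), tr$song_id,
                     function(x) length(unique(x)))
  expect_true(all(per_song == 1))
  expect_gte(length(per_song), 2)
})

test_that("phase-aligned starts land the first beat on the predicted footfall", {
  # noise-free coupling-free 120-SPM walker with a 120-bpm song: the queued
  # song starts on the next predicted step, so every phase is zero
  ff <- periodic_footfalls(spm = 120, duration = 120)
  res <- run_controller(one_song_library(120), ff,
                        strategy_config(strategy = 3, start_phase_deg = 0))
  expect_gt(nrow(res$phases), 200)
  expect_true(all(abs(res$phases$phi_display) < 1e-6))
  first_beat <- res$beats$time_s[1]
  expect_true(any(abs(ff$time_s - first_beat) < 1e-9))
})

test_that("a 180-degree start bisects the predicted footfalls with beats", {
  ff <- periodic_footfalls(spm = 120, duration = 120)
  res <- run_controller(one_song_library(120), ff,
                        strategy_config(strategy = 3, start_phase_deg = 180))
  expect_gt(nrow(res$phases), 200)
  expect_true(all(abs(res$phases$phi_360 - 180) < 1e-6))
})

test_that("the band nudge moves the tempo toward phase zero, at most once per step", {
  lib <- one_song_library(120)
  st <- new_strategy_state(lib, strategy_config(strategy = 4))
  for (t in seq(0.5, 10, by = 0.5)) strategy_step(st, t)
  expect_false(is.null(st$playback))
  base <- st$estimate$spm / st$playback$bpm
  # lagging step (phase +45): the beats must be delayed to catch the walker,
  # so the modifier drops by the nudge
  step_strategy4(st, 10.5, phi_display = 45)
  expect_equal(st$tr_nudge[st$step_count], -0.03)
  expect_equal(st$playback$tempo_modifier, base - 0.03, tolerance = 1e-9)
  # leading step: nudge up
  step_strategy4(st, 11.0, phi_display = -45)
  expect_equal(st$tr_nudge[st$step_count], 0.03)
  # inside the band: no nudge
  step_strategy4(st, 11.5, phi_display = 10)
  expect_equal(st$tr_nudge[st$step_count], 0)
  expect_equal(st$playback$tempo_modifier, base, tolerance = 1e-9)
})

test_that("traced modifiers always respect the clamp and the nudge grammar", {
  withr::with_seed(21, {
    w <- walker_params(base_spm = 118, noise_sd = 0.03)
    cfg <- experiment_config(strategy = 4, library = tiny_library(),
                             duration_s = 180)
    tr <- run_trial(cfg, w, seed = 33)$trace
    ok <- !is.na(tr$final_modifier)
    expect_true(all(tr$final_modifier[ok] >= 0.9 - 1e-12))
    expect_true(all(tr$final_modifier[ok] <= 1.1 + 1e-12))
    expect_true(all(tr$nudge %in% c(0, -0.03, 0.03)))
    # whenever the step's phase sat inside the band, no nudge was applied
    inband <- ok & !is.na(tr$phi_display) & abs(tr$phi_display) <= 30
    expect_true(all(tr$nudge[inband] == 0))
  })
})

test_that("erroneous intervals are ignored by the controller", {
  times <- seq(0.5, 30, by = 0.5)
  times <- sort(c(times, 15.3)) # a glitch 0.3 s after a step: 0.3/0.5 harmonicity fails
  res <- run_controller(one_song_library(120), tibble::tibble(time_s = times),
                        strategy_config(strategy = 1))
  tr <- res$trace
  rejected <- tr[tr$event == "rejected_step", ]
  expect_gte(nrow(rejected), 1)
  expect_equal(rejected$time_s[1], 15.3)
  # the modifier did not move in response to the glitch
  i <- rejected$step_index[1]
  expect_equal(tr$final_modifier[i], tr$final_modifier[i - 1])
})

test_that("a walker detuned from the fixed music period drifts unboundedly, but the nudging controller recaptures it", {
  # a noise-free walker whose cadence detunes 2% above the music after the
  # song tempo has been fixed: under period-fixed alignment the phase sweeps
  # the whole circle, while the period- and phase-adaptive controller pulls
  # every excursion back inside the band (less effort to keep than to find)
  w <- walker_params(base_spm = 120, noise_sd = 0, coupling_a = 0,
                     coupling_b = 0)
  jump <- scenario_events(15, "cadence_jump", 0.02 * 120)
  lib <- one_song_library(120, duration_s = 240)
  cfg2 <- experiment_config(strategy = 2, library = lib, duration_s = 200,
                            sensor = NULL)
  tr2 <- run_trial(cfg2, w, seed = 9, scenario = jump)
  late2 <- tr2$phases[tr2$phases$time_s > 20, ]
  expect_lt(mean_resultant(late2$phi_display)$R, 0.2)
  expect_gt(diff(range(late2$phi_360)), 300)
  cfg4 <- experiment_config(strategy = 4, library = lib, duration_s = 200,
                            sensor = NULL)
  tr4 <- run_trial(cfg4, w, seed = 9, scenario = jump)
  phi4 <- tr4$phases$phi_display[tr4$phases$time_s > 20]
  expect_gt(mean(abs(phi4) <= 30), 0.9)
  # every excursion beyond the band ends within a few steps
  out <- rle(abs(phi4) > 30)
  expect_lt(max(c(0, out$lengths[out$values])), 12)
})
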
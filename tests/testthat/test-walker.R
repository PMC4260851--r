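test_that("a noiseless uncoupled walker steps with metronomic regularity", {
  w <- walker_params(base_spm = 120, noise_sd = 0, coupling_a = 0, coupling_b = 0)
  ff <- simulate_walk(w, function(t) NULL, duration = 60)
  expect_equal(nrow(ff), 120)
  expect_equal(unique(round(diff(ff$time_s), 12)), 0.5)
  expect_true(all(ff$valid))
})

# phase of each footfall against a fixed isochronous grid
phases_against_grid <- function(ff, bpm, first_beat) {
  t_beat <- 60 / bpm
  to_display(((ff$time_s - first_beat) %% t_beat) / t_beat * 360)
}

test_that("in-phase coupling pulls the phase monotonically to zero", {
  # start 40 degrees late relative to a fixed 120-bpm grid
  first_beat <- 0.5 - 40 / 360 * 0.5
  w <- walker_params(base_spm = 120, noise_sd = 0, coupling_a = 0.2, coupling_b = 0)
  ff <- simulate_walk(w, fixed_beat_callback(120, first_beat), duration = 60)
  phi <- abs(phases_against_grid(ff, 120, first_beat))
  expect_equal(phi[1], 40, tolerance = 0.5)
  expect_true(all(diff(phi) <= 1e-6))
  expect_lt(tail(phi, 1), 0.5)
})

test_that("the anti-phase fixed point is stable only inside its smaller basin", {
  # 2b > a: locally stable anti-phase; basin boundary at acos(-a/(2b)) = 109.5
  run_from <- function(phi0, a, b) {
    first_beat <- 0.5 - phi0 / 360 * 0.5
    w <- walker_params(base_spm = 120, noise_sd = 0, coupling_a = a, coupling_b = b)
    ff <- simulate_walk(w, fixed_beat_callback(120, first_beat), duration = 120)
    tail(phases_against_grid(ff, 120, first_beat), 1)
  }
  expect_lt(abs(run_from(100, 0.1, 0.15)), 1)        # inside the 0 basin
  expect_gt(abs(run_from(120, 0.1, 0.15)), 179)      # inside the 180 basin
  # with a > 0 and no second harmonic, 180 is unstable
  expect_lt(abs(run_from(175, 0.2, 0)), 1)
})

test_that("an uncoupled noisy walker drifts to near-uniform phase", {
  # phase of an uncoupled walker against a fixed beat is a wrapped random
  # walk; pooled over 20 independent 10-minute walks the resultant shrinks
  # toward uniformity (a single walk's time-average R stays ~0.2 because the
  # walk decorrelates only every ~30 steps)
  phis <- unlist(lapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      w <- walker_params(base_spm = 115, noise_sd = 0.02,
                         coupling_a = 0, coupling_b = 0)
      ff <- simulate_walk(w, fixed_beat_callback(115, 0), duration = 600)
      phases_against_grid(ff, 115, 0)
    })
  }))
  expect_lt(mean_resultant(phis)$R, 0.15)
})

test_that("a non-monotone beat schedule from the callback is a simulation error", {
  bad <- function(t) c(t + 0.5, t + 0.2)
  w <- walker_params(base_spm = 120, noise_sd = 0)
  expect_error(simulate_walk(w, bad, duration = 10), class = "gaitsync_simulation")
})

test_that("scenario events perturb the walk as specified", {
  withr::with_seed(3, {
    w <- walker_params(base_spm = 120, noise_sd = 0, coupling_a = 0)
    sc <- scenario_events(c(10, 30, 50), c("pause", "cadence_jump", "missed_step"),
                          c(4, 12, 0))
    ff <- simulate_walk(w, function(t) NULL, duration = 60, scenario = sc)
    gaps <- diff(ff$time_s)
    expect_gt(max(gaps[ff$time_s[-1] < 20]), 4)        # the pause gap
    late <- gaps[ff$time_s[-1] > 35 & ff$time_s[-1] < 48]
    expect_equal(unique(round(late, 10)), 60 / 132)    # cadence 120 + 12
    expect_equal(sum(!ff$valid), 1)                    # one missed detection
  })
})

test_that("cohort generation is reproducible, range-respecting and extensible", {
  a <- make_cohort(10, seed = 7)
  b <- make_cohort(10, seed = 7)
  expect_identical(a, b)
  c3 <- make_cohort(10, seed = 7, nonentrainer_fraction = 0.3)
  expect_equal(sum(c3$coupling_a == 0 & c3$coupling_b == 0), 3)
  ranged <- make_cohort(25, param_ranges = list(base_spm = c(110, 120)), seed = 1)
  expect_true(all(ranged$base_spm >= 110 & ranged$base_spm <= 120))
  # later participants never perturb earlier draws
  big <- make_cohort(15, seed = 7)
  expect_equal(big$base_spm[1:10], a$base_spm[1:10])
})

test_that("long-memory noise mode produces positively correlated intervals", {
  withr::with_seed(6, {
    wp <- walker_params(base_spm = 120, noise_sd = 0.02, coupling_a = 0,
                        coupling_b = 0, noise_type = "pink")
    ww <- walker_params(base_spm = 120, noise_sd = 0.02, coupling_a = 0,
                        coupling_b = 0, noise_type = "white")
    iv_p <- diff(simulate_walk(wp, function(t) NULL, 600)$time_s)
    iv_w <- diff(simulate_walk(ww, function(t) NULL, 600)$time_s)
    ac <- function(x) cor(x[-1], x[-length(x)])
    expect_gt(ac(iv_p), 0.2)       # long memory
    expect_lt(abs(ac(iv_w)), 0.1)  # independent
    expect_equal(sd(iv_p), 0.02, tolerance = 0.3)
  })
})
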
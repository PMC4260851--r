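test_that("mean resultant vector matches hand-computed phasor sums", {
  expect_equal(mean_resultant(c(0, 0, 0)), list(mean_deg = 0, R = 1))
  unif <- mean_resultant(c(0, 90, 180, 270))
  expect_true(is.na(unif$mean_deg))
  expect_equal(unif$R, 0, tolerance = 1e-12)
  two <- mean_resultant(c(0, 90))
  expect_equal(two$mean_deg, 45)
  expect_equal(two$R, sqrt(2) / 2)
  expect_error(mean_resultant(numeric(0)), class = "gaitsync_empty_sample")
})

test_that("variance and angular deviation are exact functions of R", {
  expect_equal(circ_variance(0.17), 0.83)
  expect_equal(circ_variance(1), 0)
  expect_equal(circ_variance(0.92), 0.08)
  expect_equal(angular_deviation(0.92), sqrt(2 * 0.08))
  expect_equal(round(angular_deviation(0.92), 1), 0.4)
  expect_equal(angular_deviation(1), 0)
  expect_equal(round(angular_deviation(0.73), 2), 0.73)
  expect_error(circ_variance(1.2), class = "gaitsync_domain")
  expect_error(angular_deviation(-0.1), class = "gaitsync_domain")
})

test_that("skewness vanishes for symmetric samples and kurtosis peaks at 1", {
  expect_equal(circ_skew_kurt(c(-20, 0, 20))$b, 0, tolerance = 1e-12)
  expect_equal(circ_skew_kurt(c(0, 0, 0))$k, 1)
})

test_that("all eight summary fields match closed forms on a two-atom sample", {
  # 0.8 point mass at 0 plus 0.2 point mass at 90, n = 1000 by construction
  angles <- c(rep(0, 800), rep(90, 200))
  s <- phase_summary(angles)
  C <- 0.8 + 0.2 * cos(pi / 2)
  S <- 0.2 * sin(pi / 2)
  R <- sqrt(C^2 + S^2)
  mean_rad <- atan2(S, C)
  expect_equal(s$n, 1000)
  expect_equal(s$mean_angle_deg, mean_rad * 180 / pi)
  expect_equal(s$R, R)
  expect_equal(s$V, 1 - R)
  expect_equal(s$s, sqrt(2 * (1 - R)))
  expect_equal(s$b, 0.8 * sin(2 * (0 - mean_rad)) + 0.2 * sin(2 * (pi / 2 - mean_rad)))
  expect_equal(s$k, 0.8 * cos(2 * (0 - mean_rad)) + 0.2 * cos(2 * (pi / 2 - mean_rad)))
  # confidence limits from the closed-form dispersion formula, on each side
  expect_true(s$ci95_low_deg < s$mean_angle_deg)
  expect_true(s$ci95_high_deg > s$mean_angle_deg)
})

test_that("summaries are rotation-equivariant", {
  withr::with_seed(5, {
    base_angles <- rnorm(200, 20, 30)
    s0 <- phase_summary(base_angles)
    for (rot in c(30, -120, 215)) {
      s1 <- phase_summary(base_angles + rot)
      expect_equal(s1$R, s0$R, tolerance = 1e-12)
      expect_equal(s1$V, s0$V, tolerance = 1e-12)
      expect_equal(s1$b, s0$b, tolerance = 1e-9)
      expect_equal(s1$k, s0$k, tolerance = 1e-9)
      expect_equal(to_display((s1$mean_angle_deg - rot) %% 360),
                   s0$mean_angle_deg, tolerance = 1e-9)
      expect_equal(to_display((s1$ci95_low_deg - rot) %% 360),
                   s0$ci95_low_deg, tolerance = 1e-9)
      r0 <- rayleigh_test(base_angles)
      r1 <- rayleigh_test(base_angles + rot)
      expect_equal(r1$statistic, r0$statistic, tolerance = 1e-12)
      expect_equal(hodges_ajne_test(base_angles + rot)$statistic,
                   hodges_ajne_test(base_angles)$statistic)
    }
  })
})

test_that("Rayleigh test separates locking from uniformity", {
  expect_lt(rayleigh_test(rep(42, 50))$p_value, 1e-6)
  grid <- seq(0, 360, length.out = 101)[1:100]
  rg <- rayleigh_test(grid)
  expect_equal(rg$statistic, 0, tolerance = 1e-20)
  expect_gt(rg$p_value, 0.99)
  expect_error(rayleigh_test(c(1, 2)), class = "gaitsync_insufficient_sample")
})

test_that("Hodges-Ajne statistic equals the brute-force half-circle scan", {
  withr::with_seed(8, {
    for (rep in 1:40) {
      n <- sample(9:80, 1)
      a <- switch(sample(3, 1),
                  runif(n, 0, 360),
                  rnorm(n, 0, 45),
                  c(rnorm(ceiling(0.7 * n), 0, 20), rnorm(floor(0.3 * n), 180, 20)))
      expect_equal(hodges_ajne_test(a)$statistic, brute_hodges_m(a))
    }
  })
})

test_that("Hodges-Ajne rejects concentrated and dominant-mode samples", {
  withr::with_seed(9, {
    half <- runif(30, 0, 170) # all inside one half-circle: m = 0
    ht <- hodges_ajne_test(half)
    expect_equal(ht$statistic, 0)
    expect_lt(ht$p_value, 1e-4)
    # the unbalanced bimodal shape seen under period-adaptive phase-random
    # alignment: dominant mode at 0, minor mode at 180
    mix <- c(rnorm(80, 0, 25), rnorm(20, 180, 15))
    expect_lt(hodges_ajne_test(mix)$p_value, 0.01)
    # an exact grid sits at the degenerate m ~ n/2 corner where the
    # large-n approximation loses accuracy; it must still not be rejected
    grid <- seq(0, 360, length.out = 101)[1:100]
    expect_gt(hodges_ajne_test(grid)$p_value, 0.05)
  })
  expect_error(hodges_ajne_test(runif(5, 0, 360)),
               class = "gaitsync_insufficient_sample")
})

test_that("Watson U2 distinguishes identical from separated samples", {
  withr::with_seed(10, {
    a <- rnorm(50, 0, 10)
    same <- watson_u2_two_sample(a, a)
    expect_lt(same$statistic, 0.02)
    expect_gt(same$p_value, 0.5)
    b <- rnorm(50, 180, 10)
    expect_lt(watson_u2_two_sample(a, b)$p_value, 0.001)
  })
  expect_error(watson_u2_two_sample(numeric(0), 1:3),
               class = "gaitsync_empty_sample")
})

test_that("Watson U2 p-value agrees with a permutation oracle", {
  withr::with_seed(12, {
    # overlapping but shifted samples: p in a mid range where agreement matters
    a <- rnorm(30, 0, 60)
    b <- rnorm(30, 40, 60)
    obs <- watson_u2_two_sample(a, b)
    pooled <- c(a, b)
    perm <- replicate(4000, {
      idx <- sample(60, 30)
      gaitsync:::watson_u2_stat(pooled[idx], pooled[-idx])
    })
    p_perm <- mean(perm >= obs$statistic)
    expect_lt(abs(obs$p_value - p_perm), 0.03)
  })
})

test_that("mean-direction confidence interval matches a bootstrap oracle", {
  withr::with_seed(13, {
    angles <- rnorm(1000, 25, 30)
    ci <- mean_ci95(angles)
    boot_means <- replicate(4000, {
      mean_resultant(sample(angles, replace = TRUE))$mean_deg
    })
    q <- unname(stats::quantile(boot_means, c(0.025, 0.975)))
    expect_lt(abs(ci$low_deg - q[1]), 0.5)
    expect_lt(abs(ci$high_deg - q[2]), 0.5)
    # degenerate sample: zero width
    exact <- mean_ci95(rep(77, 20))
    expect_equal(exact$low_deg, exact$high_deg)
  })
})

test_that("participant classification counts Rayleigh-significant walkers", {
  locked <- list(p1 = rep(0, 60) + rnorm(60, 0, 3), p2 = rnorm(60, 10, 4))
  expect_equal(participant_sync_fraction(locked)$fraction, 1)
  withr::with_seed(14, {
    mixed <- c(
      purrr::map(1:7, ~ rnorm(300, 0, 15)),
      purrr::map(1:3, ~ runif(300, 0, 360))
    )
    names(mixed) <- sprintf("p%02d", 1:10)
    frac <- participant_sync_fraction(mixed)$fraction
    expect_gte(frac, 0.7)
    expect_lte(frac, 0.9)
  })
})

test_that("angular histogram conserves counts over display-scale bins", {
  withr::with_seed(15, {
    a <- runif(321, -180, 180)
    h <- angular_histogram(a, 20)
    expect_equal(sum(h$count), 321)
  })
  single <- angular_histogram(rep(0, 10), 20)
  expect_equal(sum(single$count > 0), 1)
  expect_equal(single$count[single$bin_low_deg == 0], 10)
  grid <- seq(-180, 180, length.out = 361)[1:360]
  expect_true(all(angular_histogram(grid, 20)$count == 20))
  expect_error(angular_histogram(1:5, 25), class = "gaitsync_domain")
})

test_that("tidy and glance produce one-row tibbles for test objects", {
  td <- tidy(rayleigh_test(rnorm(30, 0, 20)))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("test", "statistic", "p.value", "n", "n2"))
})

test_that("standardised moments vanish for symmetry and are rotation-invariant", {
  withr::with_seed(16, {
    sym <- c(-40, -10, 0, 10, 40)
    expect_equal(circ_skew_kurt_std(sym)$b0, 0, tolerance = 1e-9)
    skewed <- c(rnorm(300, 0, 15), rnorm(100, 60, 10))
    s0 <- circ_skew_kurt_std(skewed)
    s1 <- circ_skew_kurt_std(skewed + 100)
    expect_equal(s1$b0, s0$b0, tolerance = 1e-9)
    expect_equal(s1$k0, s0$k0, tolerance = 1e-9)
    expect_gt(abs(s0$b0), 0.1)
  })
})
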
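# Circular statistics for relative-phase samples. Angles are degrees at every
# interface and radians internally. Conventions follow the second
# trigonometric-moment definitions of the CircStat toolbox (Berens 2009):
# skewness b = mean sin of twice the mean-centred angles, kurtosis k = mean
# cos of twice the mean-centred angles.

#' Mean resultant vector of a circular sample
#'
#' Averages the unit phasors of the angles. The resultant length `R` lies in
#' `[0, 1]`: 1 if and only if all angles coincide (strict phase locking), 0
#' for perfectly balanced (e.g. uniform) samples. The mean angle is the
#' direction of the resultant and is undefined when `R = 0`.
#'
#' @param angles_deg Numeric vector of angles in degrees (any wrap).
#' @return A list with `mean_deg` (in `(-180, 180]`, `NA` when undefined) and
#'   `R`.
#' @examples
#' mean_resultant(c(0, 90)) # mean 45, R = sqrt(2)/2
#' @export
mean_resultant <- function(angles_deg) {
  if (length(angles_deg) < 1) {
    abort("empty angle sample", class = "gaitsync_empty_sample")
  }
  a <- deg2rad(angles_deg)
  C <- mean(cos(a))
  S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  mean_deg <- if (R < sqrt(.Machine$double.eps)) NA_real_ else to_display(wrap_360(rad2deg(atan2(S, C))))
  list(mean_deg = mean_deg, R = R)
}

#' Circular variance from a resultant length
#'
#' `V = 1 - R`: the complement of the mean resultant vector length, 0 under
#' strict phase locking and 1 under perfect dispersion.
#'
#' @param R Mean resultant vector length in `[0, 1]`.
#' @return Circular variance in `[0, 1]`.
#' @export
circ_variance <- function(R) {
  if (any(R < 0 | R > 1)) {
    abort("R must lie in [0, 1]", class = "gaitsync_domain")
  }
  1 - R
}

#' Angular deviation from a resultant length
#'
#' `s = sqrt(2 * (1 - R))`, in radians: the circular analogue of the standard
#' deviation (dispersion around the mean direction). Ranges from 0 (strict
#' phase locking) to `sqrt(2)`.
#'
#' @inheritParams circ_variance
#' @return Angular deviation in radians.
#' @export
angular_deviation <- function(R) {
  if (any(R < 0 | R > 1)) {
    abort("R must lie in [0, 1]", class = "gaitsync_domain")
  }
  sqrt(2 * (1 - R))
}

#' Circular skewness and kurtosis
#'
#' Second trigonometric moments about the sample mean direction: skewness
#' `b = mean(sin(2 * (theta - mean)))` measures asymmetry around the mean,
#' kurtosis `k = mean(cos(2 * (theta - mean)))` measures peakedness (1 for a
#' point mass).
#'
#' @param angles_deg Numeric vector of angles in degrees, `n >= 2`, with a
#'   defined mean direction (`R > 0`).
#' @return A list with elements `b` and `k` (both `NA` with a warning when the
#'   mean direction is undefined).
#' @export
circ_skew_kurt <- function(angles_deg) {
  if (length(angles_deg) < 2) {
    abort("need at least 2 angles", class = "gaitsync_empty_sample")
  }
  mr <- mean_resultant(angles_deg)
  if (is.na(mr$mean_deg)) {
    warn("mean direction undefined (R = 0); skewness/kurtosis flagged NA")
    return(list(b = NA_real_, k = NA_real_))
  }
  centred <- deg2rad(angles_deg - mr$mean_deg)
  list(b = mean(sin(2 * centred)), k = mean(cos(2 * centred)))
}

#' Standardised circular skewness and kurtosis
#'
#' The alternative, distribution-standardised moments (Pewsey/Fisher): the
#' second trigonometric moment is centred on twice the mean direction and
#' rescaled by powers of `1 - R`, so that magnitudes are comparable across
#' concentrations. Distinct from the plain second-moment `b` and `k` of
#' [circ_skew_kurt()], which [phase_summary()] reports.
#'
#' @inheritParams circ_skew_kurt
#' @return A list with `b0` (standardised skewness) and `k0` (standardised
#'   kurtosis); `NA` for degenerate samples (`R` of 0 or 1).
#' @export
circ_skew_kurt_std <- function(angles_deg) {
  if (length(angles_deg) < 2) {
    abort("need at least 2 angles", class = "gaitsync_empty_sample")
  }
  mr <- mean_resultant(angles_deg)
  if (is.na(mr$mean_deg) || mr$R > 1 - 1e-12) {
    return(list(b0 = NA_real_, k0 = NA_real_))
  }
  a <- deg2rad(angles_deg)
  mu <- deg2rad(mr$mean_deg)
  rho2 <- sqrt(mean(cos(2 * a))^2 + mean(sin(2 * a))^2)
  mu2 <- atan2(mean(sin(2 * a)), mean(cos(2 * a)))
  list(b0 = rho2 * sin(mu2 - 2 * mu) / (1 - mr$R)^(3 / 2),
       k0 = (rho2 * cos(mu2 - 2 * mu) - mr$R^4) / (1 - mr$R)^2)
}

#' 95% confidence interval for the circular mean direction
#'
#' Standard large-sample interval for the mean direction (Fisher 1993; the
#' CircStat `circ_confmean` formula), only meaningful for samples whose
#' Rayleigh test rejects uniformity. Degenerates to zero width when all
#' angles coincide.
#'
#' @param angles_deg Angles in degrees.
#' @param conf Confidence level (default 0.95).
#' @return A list with `low_deg` and `high_deg`, on the `(-180, 180]` scale.
#' @export
mean_ci95 <- function(angles_deg, conf = 0.95) {
  n <- length(angles_deg)
  mr <- mean_resultant(angles_deg)
  if (is.na(mr$mean_deg)) {
    abort("mean direction undefined (R = 0); no confidence interval",
          class = "gaitsync_domain")
  }
  r <- mr$R
  Rn <- n * r
  if (r > 1 - sqrt(.Machine$double.eps)) {
    return(list(low_deg = mr$mean_deg, high_deg = mr$mean_deg))
  }
  chi2 <- qchisq(conf, df = 1)
  t <- if (r < 0.9) {
    arg <- (2 * n * (2 * Rn^2 - n * chi2)) / (4 * n - chi2)
    if (arg < 0) {
      abort("sample too dispersed for the mean-direction interval",
            class = "gaitsync_domain")
    }
    sqrt(arg)
  } else {
    sqrt(n^2 - (n^2 - Rn^2) * exp(chi2 / n))
  }
  d <- rad2deg(acos(pmin(1, t / Rn)))
  list(low_deg = to_display(wrap_360(mr$mean_deg - d)),
       high_deg = to_display(wrap_360(mr$mean_deg + d)))
}

#' Eight-parameter circular summary of a phase sample
#'
#' One row describing a relative-phase distribution: sample size, mean angle
#' with its 95% confidence limits, mean resultant vector length `R`, circular
#' variance `V = 1 - R`, angular deviation `s = sqrt(2(1 - R))` (radians),
#' circular skewness `b` and circular kurtosis `k`.
#'
#' @param angles_deg Angles in degrees (e.g. the `phi_display` column of
#'   [phase_series()]).
#' @param ci Compute the mean-direction confidence limits (default TRUE; they
#'   are only meaningful for non-uniform samples and are set to `NA` when the
#'   interval does not exist).
#' @return A one-row tibble of class `phase_summary` with columns `n`,
#'   `mean_angle_deg`, `ci95_low_deg`, `ci95_high_deg`, `R`, `V`, `s`, `b`,
#'   `k`.
#' @examples
#' phase_summary(c(-20, 0, 20))
#' @export
phase_summary <- function(angles_deg, ci = TRUE) {
  mr <- mean_resultant(angles_deg)
  sk <- if (length(angles_deg) >= 2 && !is.na(mr$mean_deg)) {
    circ_skew_kurt(angles_deg)
  } else {
    list(b = NA_real_, k = NA_real_)
  }
  lims <- list(low_deg = NA_real_, high_deg = NA_real_)
  if (ci && !is.na(mr$mean_deg)) {
    lims <- tryCatch(mean_ci95(angles_deg),
                     gaitsync_domain = function(e) list(low_deg = NA_real_, high_deg = NA_real_))
  }
  out <- tibble::tibble(
    n = length(angles_deg),
    mean_angle_deg = mr$mean_deg,
    ci95_low_deg = lims$low_deg,
    ci95_high_deg = lims$high_deg,
    R = mr$R,
    V = circ_variance(mr$R),
    s = angular_deviation(mr$R),
    b = sk$b,
    k = sk$k
  )
  class(out) <- c("phase_summary", class(out))
  out
}

new_circ_test <- function(test_name, statistic, p_value, n, n2 = NA_integer_,
                          method = NULL) {
  structure(
    list(test_name = test_name, statistic = statistic,
         p_value = min(max(p_value, 0), 1), n = n, n2 = n2, method = method),
    class = "circ_test"
  )
}

#' @export
print.circ_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g, n = %d%s\n",
              x$test_name, x$statistic, x$p_value, x$n,
              if (!is.na(x$n2)) sprintf(" / %d", x$n2) else ""))
  invisible(x)
}

#' @method tidy circ_test
#' @export
tidy.circ_test <- function(x, ...) {
  tibble::tibble(test = x$test_name, statistic = x$statistic,
                 p.value = x$p_value, n = x$n, n2 = x$n2)
}

#' @method glance circ_test
#' @export
glance.circ_test <- function(x, ...) tidy(x)

#' Rayleigh test of circular uniformity
#'
#' Tests the null of circular uniformity against a unimodal alternative.
#' The statistic is `Z = n * R^2`; the p-value uses the standard four-term
#' series in `Z` and `n` (Zar 2010), accurate for `n >= 10` and excellent for
#' the sample sizes used here (hundreds to tens of thousands).
#'
#' @param angles_deg Angles in degrees, `n >= 3`.
#' @return An object of class `circ_test` with fields `test_name`,
#'   `statistic` (Z), `p_value`, `n`. `tidy()` gives a one-row tibble.
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 3) {
    abort("Rayleigh test needs n >= 3", class = "gaitsync_insufficient_sample")
  }
  R <- mean_resultant(angles_deg)$R
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  new_circ_test("rayleigh", Z, p, n)
}

# minimum number of points in any closed half-circle (the Hodges-Ajne
# statistic), by rotating a half-plane boundary through every data direction
hodges_ajne_m <- function(angles_deg) {
  n <- length(angles_deg)
  a <- sort(wrap_360(angles_deg))
  # counts in half-open arcs [a_i, a_i + 180): two-pointer over doubled array
  aa <- c(a, a + 360)
  counts <- integer(n)
  j <- 1
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (aa[j + 1] < a[i] + 180 && j < i + n - 1) j <- j + 1
    # j indexes the last point strictly inside [a_i, a_i + 180)
    counts[i] <- j - i + 1
  }
  # a closed half-circle maximises points on one side; m = n - max count over
  # all half-circles; scanning arcs anchored at data points suffices
  m <- n - max(counts)
  m
}

#' Hodges-Ajne (omnibus) test of circular uniformity
#'
#' Tests circular uniformity with sensitivity to multimodal alternatives
#' (which the Rayleigh test misses when modes cancel). The statistic `m` is
#' the minimum number of sample points falling in any closed half-circle.
#' For `n <= 50` the exact formula `p = (n - 2m) * choose(n, m) / 2^(n-1)`
#' is used (sharpest for `m < n/3`, the usual rejection region; near
#' `m = n/2` — very evenly spread samples — it degenerates towards 0 and
#' should not be over-read); for larger `n` the Ajne approximation
#' `p = sqrt(2*pi)/A * exp(-pi^2/(8 A^2))` with `A = pi * sqrt(n) / (2 (n - 2m))`.
#'
#' @param angles_deg Angles in degrees, `n >= 9` for the formula's validity.
#' @return A `circ_test` object with statistic `m`.
#' @export
hodges_ajne_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 9) {
    abort("Hodges-Ajne test needs n >= 9", class = "gaitsync_insufficient_sample")
  }
  m <- hodges_ajne_m(angles_deg)
  p <- if (n <= 50) {
    (n - 2 * m) * choose(n, m) / 2^(n - 1)
  } else {
    A <- pi * sqrt(n) / (2 * (n - 2 * m))
    sqrt(2 * pi) / A * exp(-pi^2 / (8 * A^2))
  }
  new_circ_test("hodges_ajne", m, p, n)
}

# Watson U2 statistic from two sorted circular samples, mid-ranks for ties
watson_u2_stat <- function(a_deg, b_deg) {
  n1 <- length(a_deg)
  n2 <- length(b_deg)
  N <- n1 + n2
  x <- wrap_360(a_deg)
  y <- wrap_360(b_deg)
  pooled <- sort(unique(c(x, y)))
  # empirical cdf steps of each sample at the pooled points
  cx <- cumsum(tabulate(match(sort(x), pooled), nbins = length(pooled))) / n1
  cy <- cumsum(tabulate(match(sort(y), pooled), nbins = length(pooled))) / n2
  d <- cx - cy
  # weights: multiplicity of each pooled point (mid-rank tie handling folds
  # into weighting each distinct point by its total multiplicity)
  wts <- (tabulate(match(sort(x), pooled), nbins = length(pooled)) +
            tabulate(match(sort(y), pooled), nbins = length(pooled)))
  dbar <- sum(d * wts) / N
  (n1 * n2 / N^2) * sum(wts * (d - dbar)^2)
}

# asymptotic null tail of Watson's U2: P(U2 > u) = 2 * sum (-1)^(k-1) exp(-2 k^2 pi^2 u).
# The alternating series needs ~1/sqrt(u) terms to converge; below u ~ 1e-4
# the tail probability is 1 to double precision.
watson_u2_pvalue <- function(u) {
  if (u < 1e-4) return(1)
  k <- seq_len(max(20L, ceiling(3 / sqrt(u))))
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u))
  min(max(p, 0), 1)
}

#' Two-sample Watson U-squared test
#'
#' Tests whether two circular samples come from the same population (or two
#' populations with the same direction), via the squared integrated
#' difference of their circular empirical distribution functions. Ties across
#' samples are handled by mid-ranks. The p-value uses the asymptotic null
#' series of the statistic, adequate for the sample sizes used here
#' (n in the tens and above).
#'
#' @param a_deg,b_deg The two angle samples, degrees, both non-empty.
#' @return A `circ_test` object with statistic `U2` and fields `n`, `n2`.
#' @export
watson_u2_two_sample <- function(a_deg, b_deg) {
  if (length(a_deg) < 1 || length(b_deg) < 1) {
    abort("both samples must be non-empty", class = "gaitsync_empty_sample")
  }
  u2 <- watson_u2_stat(a_deg, b_deg)
  new_circ_test("watson_u2", u2, watson_u2_pvalue(u2),
                length(a_deg), length(b_deg))
}

#' Fraction of participants classified as synchronised
#'
#' Runs a Rayleigh test on each participant's phase sample and reports the
#' fraction with `p < alpha`. No multiple-testing correction is applied
#' (`alpha` is configurable).
#'
#' @param per_participant_angles Either a named list of angle vectors
#'   (degrees) or a data frame with columns `participant_id` and
#'   `phi_display` (or `phi_display_deg`).
#' @param alpha Significance level (default 0.05).
#' @return A list with `fraction`, and `per_participant`: a tibble of
#'   `participant_id`, `n`, `R`, `p_value`, `synchronised`.
#' @export
participant_sync_fraction <- function(per_participant_angles, alpha = 0.05) {
  if (is.data.frame(per_participant_angles)) {
    col <- intersect(c("phi_display", "phi_display_deg"), names(per_participant_angles))[1]
    if (is.na(col)) abort("need a phi_display column", class = "gaitsync_domain")
    per_participant_angles <- split(per_participant_angles[[col]],
                                    per_participant_angles$participant_id)
  }
  if (length(per_participant_angles) < 1) {
    abort("need at least one participant", class = "gaitsync_empty_sample")
  }
  rows <- purrr::imap(per_participant_angles, function(a, id) {
    rt <- rayleigh_test(a)
    tibble::tibble(participant_id = id, n = length(a),
                   R = mean_resultant(a)$R, p_value = rt$p_value,
                   synchronised = rt$p_value < alpha)
  })
  per <- dplyr::bind_rows(rows)
  list(fraction = mean(per$synchronised), per_participant = per)
}

#' Angular histogram counts
#'
#' Bins angles over `[-180, 180)` (display convention) into bins of the given
#' width; +180 wraps onto the `[-180, ...)` edge-most bin boundary at -180.
#'
#' @param angles_deg Angles in degrees.
#' @param bin_width_deg Bin width; must divide 360.
#' @return A tibble with `bin_mid_deg`, `bin_low_deg`, `bin_high_deg`,
#'   `count`; counts sum to `length(angles_deg)`.
#' @export
angular_histogram <- function(angles_deg, bin_width_deg = 20) {
  if (360 %% bin_width_deg != 0) {
    abort("bin width must divide 360", class = "gaitsync_domain")
  }
  lo <- seq(-180, 180 - bin_width_deg, by = bin_width_deg)
  x <- wrap_360(angles_deg + 180) - 180 # onto [-180, 180)
  idx <- floor((x + 180) / bin_width_deg) + 1
  idx[idx > length(lo)] <- length(lo)
  tibble::tibble(
    bin_low_deg = lo,
    bin_high_deg = lo + bin_width_deg,
    bin_mid_deg = lo + bin_width_deg / 2,
    count = tabulate(idx, nbins = length(lo))
  )
}
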
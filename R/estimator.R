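# Cadence estimation on a footfall event stream: a rolling window of up to 5
# accepted inter-step intervals, with harmonic-mismatch rejection. A new
# interval enters the window only when it matches the current averaged
# interval or one of its harmonics (x0.5, x1, x2) within a relative margin;
# otherwise the step is flagged erroneous and the estimate is unchanged, so
# sensor glitches, stops and obstacles do not corrupt the tempo estimate.

#' Create an empty gait estimate
#'
#' @param window_steps Maximum number of accepted intervals retained
#'   (default 5).
#' @param margin Relative harmonic-match margin (default 0.2, i.e. 20%).
#' @return A list of class `gait_estimate` with fields `window` (accepted
#'   intervals, seconds, normalised to the fundamental), `spm` (steps per
#'   minute, `NA` until the first interval), `valid`, `accepted` (was the
#'   last offered interval accepted), `last_interval` (last accepted raw
#'   interval in seconds).
#' @export
new_gait_estimate <- function(window_steps = 5, margin = 0.2) {
  structure(
    list(window = numeric(0), spm = NA_real_, valid = FALSE,
         accepted = NA, last_interval = NA_real_,
         window_steps = window_steps, margin = margin),
    class = "gait_estimate"
  )
}

#' Update a gait estimate with a new step
#'
#' Offers the inter-step interval `new_step_time - prev_step_time` to the
#' rolling window. With an empty window the interval is accepted outright.
#' Otherwise it must match the window average or a harmonic (half or double)
#' of it within the relative margin; a harmonic match is stored normalised to
#' the fundamental (`interval / m`) so the average stays on the step period.
#' A mismatch leaves the window untouched and flags the step erroneous.
#'
#' @param estimate A `gait_estimate`.
#' @param new_step_time,prev_step_time Consecutive footfall times in seconds
#'   (`new_step_time > prev_step_time`).
#' @return The updated `gait_estimate`; check `$accepted` for the verdict on
#'   this step and `$spm` for the 5-step average cadence.
#' @export
update_gait_estimate <- function(estimate, new_step_time, prev_step_time) {
  if (new_step_time <= prev_step_time) {
    abort("footfall times must be strictly increasing",
          class = "gaitsync_ordering")
  }
  interval <- new_step_time - prev_step_time
  if (length(estimate$window) == 0) {
    estimate$window <- interval
    estimate$accepted <- TRUE
  } else {
    avg <- mean(estimate$window)
    matched <- NA_real_
    for (m in c(1, 0.5, 2)) {
      if (abs(interval - m * avg) <= estimate$margin * m * avg) {
        matched <- m
        break
      }
    }
    if (is.na(matched)) {
      estimate$accepted <- FALSE
      return(estimate)
    }
    estimate$window <- c(estimate$window, interval / matched)
    if (length(estimate$window) > estimate$window_steps) {
      estimate$window <- tail(estimate$window, estimate$window_steps)
    }
    estimate$accepted <- TRUE
  }
  estimate$last_interval <- interval
  estimate$spm <- 60 / mean(estimate$window)
  estimate$valid <- TRUE
  estimate
}
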
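# Shared fixtures, all built in code.

# k unit phasors at `at` plus an (n - k)-point uniform grid whose resultant
# vanishes, so the sample's mean resultant length is exactly k/n
constructed_sample <- function(k, n = 100, at = 0) {
  grid <- seq(0, 360, length.out = n - k + 1)[seq_len(n - k)]
  c(rep(at, k), at + grid)
}

# small isochronous library spanning typical walking tempi
tiny_library <- function() synthetic_library(n_songs = 7, bpm_range = c(90, 150))

# perfectly periodic footfall stream
periodic_footfalls <- function(spm = 120, duration = 60, t0 = 60 / spm) {
  times <- seq(t0, duration, by = 60 / spm)
  tibble::tibble(participant_id = "p", time_s = times, valid = TRUE)
}

# callback presenting a fixed isochronous beat schedule to a walker
fixed_beat_callback <- function(bpm = 120, first_beat = 0) {
  t_beat <- 60 / bpm
  function(t) {
    k <- floor((t - first_beat) / t_beat)
    if (t < first_beat) return(NULL)
    c(first_beat + k * t_beat, first_beat + (k + 1) * t_beat)
  }
}

# brute-force Hodges-Ajne statistic: scan all closed half-circles
brute_hodges_m <- function(a) {
  a <- a %% 360
  cand <- sort(unique(c(a, a + 1e-7)))
  min(vapply(cand, function(th) sum(((a - th) %% 360) < 180), numeric(1)))
}

# Monte-Carlo null p-value for a uniformity statistic (large values of
# `stat_fn` towards rejection must be encoded by the caller via `lower_tail`)
mc_null_p <- function(stat_fn, observed, n, B = 10000, lower_tail = FALSE) {
  null_stats <- vapply(seq_len(B), function(i) stat_fn(runif(n, 0, 360)), numeric(1))
  if (lower_tail) mean(null_stats <= observed) else mean(null_stats >= observed)
}
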
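# gaitsync

Closed-loop simulation and evaluation of gait–music phase alignment
strategies.

Adaptive music players for walkers and runners try to keep the musical beat
aligned with the footfall: the player estimates the user's cadence (steps
per minute, SPM), picks songs of matching tempo (beats per minute, BPM),
stretches the tempo within ±10%, and may start songs exactly on a predicted
footfall or nudge the tempo whenever the step drifts off the beat. Whether a
listener *entrains* — settles into a stable relative phase with the music —
depends on which of these alignment strategies the player uses. `gaitsync`
re-creates this human–machine loop entirely in software: a virtual player
(four controllers) coupled to a virtual walker, plus the circular-statistics
pipeline used to analyse the resulting phase distributions. No audio and no
sensors are involved; beats and footfalls are timestamped events.

## The model

**Relative phase.** For a footfall at `t_f` bracketed by beats at `t_b1 ≤
t_f < t_b2`, the relative phase is `φ = 360·(t_f − t_b1)/(t_b2 − t_b1)`
degrees, displayed on `(−180°, 180°]`: 0° is on the beat, ±180° exactly
between beats, negative values mean the step preceded the beat.

**Four controllers** acting once per detected step on the 5-step average
cadence:

1. *Period-adaptive, phase-random* — tempo modifier set to SPM/BPM every
   step; songs start at an uncontrolled phase.
2. *Period-fixed, phase-random* — the modifier is fixed once per song.
3. *Period-adaptive, phase-aligned start* — as 1, but new songs are queued
   and started, skipped to their first beat, at the wall time where the
   walker's predicted phase equals 0° (or 180°).
4. *Period- and phase-adaptive* — as 3, plus a ±0.03 modifier nudge whenever
   |φ| leaves the ±30° synchronisation band.

All controllers clamp the modifier to [0.9, 1.1] and change songs (nearest
BPM to the current SPM) when an out-of-range stretch persists beyond a 5 s
debounce. Inter-step intervals that fail to match the running average or its
harmonics (×½, ×1, ×2) within 20% are rejected as sensor errors.

**The walker** is a discrete coupled-oscillator phase-correction map
(HKB-style): the next inter-step interval is
`60/SPM_intrinsic + noise − (a·sin φ + b·sin 2φ)·T_beat/2π`,
giving a stable in-phase attractor, a weaker anti-phase attractor when
`2b > a`, and no response at all when `a = b = 0` (non-entrainers). A 100 Hz
sensor model rounds detected footfalls up to the next tick (≈5 ms mean,
<10 ms max error).

**Statistics.** Phase samples are summarised by the mean angle with 95%
confidence limits, mean resultant vector length `R`, circular variance
`V = 1 − R`, angular deviation `s = √(2(1−R))` (radians), circular skewness
and kurtosis (second trigonometric moments); uniformity is tested with the
Rayleigh (`Z = nR²`) and Hodges–Ajne (emptiest half-circle) tests, and
condition pairs with the two-sample Watson U² test.

## Worked example

A five-minute closed-loop trial of the phase-adaptive controller (strategy
4) against the default walker:

```r
library(gaitsync)

lib   <- synthetic_library(n_songs = 20)           # 20 songs, 80-140 BPM
cfg   <- experiment_config(strategy = 4, library = lib, duration_s = 300)
trial <- run_trial(cfg, walker_params(), seed = 42)

trial$summary
#> # A tibble: 1 x 10
#>   participant_id     n mean_angle_deg ci95_low_deg ci95_high_deg     R      V      s         b     k
#>   <chr>          <int>          <dbl>        <dbl>         <dbl> <dbl>  <dbl>  <dbl>     <dbl> <dbl>
#> 1 walker           573           10.9         9.98          11.8 0.981 0.0189  0.195 -0.000332 0.926

rayleigh_test(trial$phases$phi_display)
#> rayleigh test: statistic = 551.5, p = 2.571e-236, n = 573

mean(abs(trial$phases$phi_display) <= 30)
#> [1] 0.9668412
```

573 steps were taken; their phases concentrate near 0° (mean 10.9°, high
resultant length `R = 0.981`, so variance `V = 0.019` and dispersion
`s = 0.195` rad), the Rayleigh test overwhelmingly rejects uniformity, and
97% of steps stay inside the ±30° band — the controller, not the walker,
does the entraining. `plot_trace(trial$trace)` shows the tempo nudges and
the phase series; `plot_phase_histogram(trial$phases)` draws the angular
histogram. Cohort experiments (`run_cohort()`) pool participants per
condition and add per-participant Rayleigh classification and, for two
conditions, the Watson U² comparison; `report_files()` writes the summary
table with one column per condition.

A thin command-line front end is included:

```sh
Rscript inst/cli/gaitsync.R simulate --config exp.yaml --seed 7 --out runs/
Rscript inst/cli/gaitsync.R analyze --footfalls f.csv --beats b.csv --out report/
```

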
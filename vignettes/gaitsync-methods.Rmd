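---
title: "Models and methods behind gaitsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gaitsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsync)
```

`gaitsync` simulates the interaction between an adaptive music player and a
walking (or running) human, and analyses the resulting footfall–beat phase
distributions with circular statistics. This vignette records the models,
the conventions, and the design decisions that were genuinely open, so that
every number the package produces can be traced to an explicit choice.

## Relative phase

For a footfall at time $t_f$ bracketed by consecutive beats $t_{b,1} \le t_f
< t_{b,2}$ of the same song, the relative phase is

$$\varphi = 360^\circ \cdot \frac{t_f - t_{b,1}}{t_{b,2} - t_{b,1}},$$

reported for display on $(-180^\circ, 180^\circ]$: negative values mean the
footfall preceded the nearest beat. Two boundary conventions are ours, since
any convention must pick a side:

* a footfall exactly on a beat belongs to the interval that beat *opens*
  ($t_{b,1} \le t_f < t_{b,2}$), so $\varphi = 0$ is representable;
* the exact anti-phase midpoint maps to $+180^\circ$, making the display
  scale the half-open interval $(-180, 180]$ with a single canonical
  anti-phase value.

Left and right steps are treated identically — the phase is per step, not
per gait cycle. All times live on one simulation clock in seconds; phases
are degrees at every interface and radians only internally.

## The virtual player

A playback is a timing contract, not audio: the song's nominal beat grid is
replayed on the wall clock with every *remaining* inter-beat interval scaled
by the inverse of the tempo modifier. Three consequences follow:

* modifier changes take effect at the next unemitted beat, never
  retroactively (a real time-stretcher cannot alter the past);
* non-isochronous grids are rescaled beat by beat, not by average tempo, so
  rubato survives stretching;
* the number of beats in a song is independent of the modifier trajectory
  (only their spacing changes).

The modifier is clamped to $[0.9, 1.1]$ — a 20% total adjustment range — and
every request records whether it was in range before clamping; the
controllers use that flag for the song-change debounce. An optional
quantised mode snaps the modifier to the 1% steps $\{0.97, \dots, 1.03\}$,
emulating players that pre-render a handful of stretched versions instead of
stretching continuously; it is the same mechanism with a coarser actuator,
not a second code path.

Songs without an explicit beat grid are isochronous at $60/\text{BPM}$ with
a default duration of 120 s (two-minute excerpts are the natural unit for
this kind of experiment); the duration determines when "song ending"
triggers reselection. Song selection minimises $|\text{BPM} -
\text{SPM}|$; ties break on the lexicographically smallest song id so that
runs replay identically. Played songs are excluded from reselection (the
exclusion resets if the library is exhausted, so the player is never
stranded).

## The virtual walker

The walker is a *discrete per-step phase-correction map*, not a
continuous-time oscillator: footfalls are the only instants at which a
walker can act, and a per-step map is what the event logs can actually
constrain. The $(n{+}1)$-th inter-step interval is

$$T_{n+1} = \frac{60/\text{SPM}_0}{d} + \eta_n -
\bigl(a \sin\varphi_n + b \sin 2\varphi_n\bigr)\frac{T_{beat}}{2\pi},$$

with intrinsic cadence $\text{SPM}_0$, detuning ratio $d$, noise $\eta_n$,
and coupling gains $a, b \ge 0$ acting on the walker's current phase
relative to the heard beats. The correction term is the gradient of the
classic two-attractor coupled-oscillator potential $-a\cos\varphi -
b\cos 2\varphi$: the in-phase fixed point $\varphi = 0$ is stable whenever
$0 < a + 2b < 2$, and a *locally* stable anti-phase fixed point exists
exactly when $2b > a$, with basin boundary at $\arccos(-a/2b)$ — always
smaller than the in-phase basin when $a > 0$. This reproduces the
asymmetry between the strong 0° attractor and the weak 180° attractor that
motivates phase-aligned song starts. With $a = b = 0$ the walker ignores the
music entirely; such non-entrainers exist in every population and default to
20% of a generated cohort.

### Parameter defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `base_spm` | 115 | steps/min | typical spontaneous walking cadence |
| `noise_sd` | 0.015 | s | ≈3% step-time CV, mid-range for natural walking |
| `coupling_a` | 0.2 | – | phase correction of ~20% of the error per step, the order observed in human synchronisation tasks |
| `coupling_b` | 0.12 | – | $2b > a$: anti-phase locally stable but shallow |
| `detuning` | 1.0 | – | cohort draws vary it ±1% |

No human coupling strengths are published for this setting; these are free
parameters of the simulator, chosen once so that the walker reproduces the
qualitative phenomena the strategies are known for (an entrainer locks to a
matched fixed tempo within tens of steps; an uncoupled walker's phase
against a fixed beat is a wrapped random walk), and then frozen. Cohorts
draw uniformly from ranges centred on these defaults (`make_cohort()`), one
derived sub-seed per participant so a cohort can be extended without
perturbing earlier members.

The default noise is white. A long-memory mode (`noise_type = "pink"`)
synthesises step-interval noise with a $1/f$-like spectrum, matching the
serial structure of real gait timing more closely; the package's own
property tests do not need it, and analyses that only see phase
distributions (not their time order) are largely insensitive to it.

### What the generator does and does not emulate

It emulates stable mean cadence with step-to-step variability, attractor
entrainment with realistic asymmetry, non-entrainers, sensor quantisation,
and scripted disturbances (pauses that randomise phase, cadence jumps,
missed step detections). It does **not** emulate biomechanics, treadmill
dynamics, fatigue or tempo drift, deliberate synchronisation effort, or
motivational effects of music. Passing closed-loop tests therefore shows
that the *controllers* behave as designed against a plausible walker — not
that any particular human population would produce the same numbers.

## The sensor model

Footfall detection at 100 Hz cannot report an event before it happens, so
detected times are rounded *up* to the next 10 ms tick. For uniformly
arriving events this yields a mean error of about 5 ms and a 10 ms maximum,
and never reorders events. The controller sees quantised times; the walker
keeps true times. Audio and actuation latency are deliberately out of
scope: beats are heard the instant they are scheduled.

## Cadence estimation

The gait frequency is the 5-step average of accepted inter-step intervals.
A new interval is accepted only if it matches the current window average or
one of its harmonics (×½, ×1, ×2) within a 20% relative margin; otherwise
the step is flagged erroneous and ignored by the controllers — this is what
protects the tempo estimate from stops, obstacles and sensor glitches. One
storage choice was open: a harmonically matched interval (say, a half-step
glitch of 0.26 s against a 0.5 s window) enters the window *normalised to
the fundamental* (0.52 s). Storing the raw value would corrupt the average
that the very same rule depends on. The averaging window is 5 *steps*; a
5-*second* window is sometimes the natural description at walking cadence,
and the window length is configurable where the distinction matters.

## The four controllers

All four share one per-step loop: switch to a queued song whose scheduled
start has passed, play out beats to the current footfall, update the
estimate, then act. Open details, and how they were resolved:

* **Random-phase starts** (strategies 1–2) place the first beat uniformly
  within one beat period after the triggering step, from the trial's seeded
  generator — "random" is reproducible.
* **Aligned starts** (strategies 3–4) skip the queued song to its first
  beat and schedule it at $t_{last} + T_{step}$ (next predicted footfall)
  for a 0° start, offset back half a beat period for 180°. The prediction
  uses the *last accepted* inter-step interval rather than the 5-step
  average: the start should land on the next actual step, and the most
  recent interval is the best one-step predictor.
* **The strategy-4 nudge.** With the display convention above, the per-step
  phase velocity is $360(T_{step}/T_{beat} - 1)$ degrees: *raising* the
  tempo *raises* the phase. A step lagging the beat ($\varphi > +30^\circ$)
  therefore needs the beats delayed — modifier *minus* 0.03 — and a leading
  step the opposite. The opposite sign makes $\pm180^\circ$ a stable trap
  and 0° unstable, visibly destroying alignment in closed loop; the
  implemented sign is the one that pushes the phase back to 0°, which is
  the controller's entire purpose. The nudge is additive, applied at most
  once per detected step, re-evaluated only at the next step, and the clamp
  is applied after it.
* **Debounce.** An out-of-range (pre-clamp) tempo request must persist for
  more than 5 s before a song change; the clock resets whenever the request
  re-enters range. Strict inequalities are used at all band and clamp
  comparisons; at the measure-zero boundaries the choice is immaterial but
  has to be fixed.
* Strategy 2 touches the modifier only at song boundaries, so its traced
  tempo is piecewise constant by construction.

The per-step trace records time, cadence, base modifier, nudge, final
modifier, phase, tempo difference `delta`, song and event
(`song_change`, `queued_start`, `rejected_step`), which is sufficient to
reproduce the usual tempo-and-phase trial plots (`plot_trace()`).

### Online versus logged phase

The controller's own phase estimate uses the preceding *emitted* beat and
the succeeding *scheduled* beat — what a real-time system knows. The
analysis phase series is recomputed from the logs
(`phase_series(footfalls, beats)`), so every reported sample is exactly
re-derivable from the CSVs alone; for adaptive strategies the two can
differ by the amount a later modifier change moved the not-yet-emitted
bracketing beat. Tests assert the re-derivation identity on the logged
series.

## Circular statistics

Conventions follow the second-trigonometric-moment definitions of the
standard circular-statistics toolbox this analysis tradition uses:

* mean direction and resultant length from the average unit phasor; the
  mean is flagged undefined when $R$ is numerically 0;
* $V = 1 - R$ and $s = \sqrt{2(1-R)}$ **exactly** — they are emitted from
  the same $R$, never recomputed downstream, and $s$ is reported in
  radians;
* skewness $b = \overline{\sin 2(\theta - \bar\theta)}$ and kurtosis
  $k = \overline{\cos 2(\theta - \bar\theta)}$; the distribution-
  standardised variants are available separately as `circ_skew_kurt_std()`
  (`b0`, `k0`) and are not what the summary table reports;
* the 95% confidence interval for the mean direction uses the standard
  large-sample dispersion formula (with its high-concentration branch at
  $r \ge 0.9$), cross-checked against a bootstrap percentile interval in
  the tests rather than asserted against any unpublished formula. It is
  only meaningful for Rayleigh-significant samples and degenerates to zero
  width for identical angles;
* the Rayleigh p-value is the standard four-term series in $Z = nR^2$ and
  $n$, excellent for $n \ge 10$;
* the Hodges–Ajne statistic $m$ is the minimum count in any closed
  half-circle (computed by a rotating-boundary scan, verified against a
  brute-force oracle); $p$ uses the exact combinatorial formula for
  $n \le 50$ and the Ajne approximation above. Two honest caveats are
  documented rather than papered over: the formulas degenerate near the
  very-evenly-spread corner $m \approx n/2$, and because $m$ is
  integer-valued the test's attainable type-I error at $n = 100$ sits at
  ≈0.03 for a nominal 0.05 — the null CDF simply jumps across 0.05. The
  Rayleigh test, with its continuous statistic, calibrates to 0.05
  cleanly;
* the two-sample Watson U² uses pooled circular ranks with mid-rank tie
  handling and the asymptotic series for its null tail (the series is
  summed to convergence; below $u = 10^{-4}$ the tail is 1 to double
  precision);
* per-participant synchronisation is the fraction of participants whose
  individual Rayleigh test rejects at $\alpha$ (default 0.05, no
  multiple-testing correction — configurable, none applied by default).

Angular histograms bin the display scale $[-180, 180)$ into widths dividing
360 and conserve counts.

## Reproducibility and problem sizes

Every run is a pure function of (configuration, seed): one master seed,
sub-seeds derived per participant and condition by a fixed integer counter
scheme kept inside 32-bit range. The package's simulation tests use
10-minute trials at walking cadence (≈1100 steps), 20 seeds per condition
for orderings and condition contrasts, 10 seeds for the forced-alignment
check, and $10^4$ ($10^3$ for Watson) replicates for test-size
calibration — sizes at which the checked effects are far from their
decision boundaries while a full suite runs in about a minute.

## Known limitations

* Zero audio/actuation latency. Real systems lag by a few beats; the lag
  is the main reason real period-adaptive alignment wobbles more than the
  simulated one. The closed-loop contrasts here are therefore conservative
  for strategy 1 and optimistic for absolute $R$ values.
* The walker has no intrinsic tempo drift; detuning enters as a constant
  ratio or a scripted cadence jump.
* The Hodges–Ajne test has no power against *balanced* antipodal bimodal
  distributions (every half-circle then holds ~half the points); the
  unbalanced bimodal shapes that occur in practice are detected.
* Pooled-phase summaries treat steps as exchangeable; serial dependence
  within a trial (strong by construction) means pooled test p-values
  should be read as descriptive, which is how they are used here.
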
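---
title: "Measuring finger-tapping performance from wearable accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring finger-tapping performance from wearable accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapmetrics)
```

## The measurement problem

A finger-tapping test asks a participant to tap as fast as possible for
30 s in one of four conditions: index + middle finger of the dominant
hand tapping simultaneously (`UniSIM`) or alternating (`UniALT`), or the
two index fingers of both hands doing the same (`BimSIM`, `BimALT`). A
fingertip-mounted IMU records tri-axial acceleration per finger at
120 Hz over ±8 g. Everything downstream — fatigue, coordination,
repeatability — is derived from the *times* and *amplitudes* of the tap
impacts, so the pipeline splits into tap detection, per-finger metrics,
two-finger metrics, and cohort statistics.

## Tap detection

**Axis selection.** Tapping loads the axis perpendicular to the surface.
The pipeline selects the axis with the largest robust excursion (99th
minus 1st percentile), falling back to the full range when activity is
too sparse for the trimmed range to see it. Exact ties resolve z > y > x,
z being the expected axis for the standard mounting.

**Peak finding.** Taps are local maxima of the (optionally smoothed,
optionally sign-flipped) signal whose *topographic prominence* — height
above the higher of the two saddles separating the peak from higher
terrain — reaches `min_prominence`, thinned so that retained peaks are at
least `min_separation` apart (the more prominent peak wins; the earlier
on a tie). Defaults are `min_prominence = 0.5` g and
`min_separation = 0.08` s: conservative against sensor noise, yet below
the shortest plausible tap period at maximal speed. Both knobs, the
smoothing half-width, and the polarity (`positive`, `negative`, `auto` —
impact deceleration can register as downward spikes depending on
mounting) live in `detection_params()`.

Two numerical details matter in noise:

- With a biphasic pulse (crest then trough), baseline noise bumps sit
  between deep valleys, so their prominence is roughly their height
  *plus* the baseline excursion — small absolute thresholds misfire. For
  traces whose pulse scale is known or estimable, the packaged guidance
  (`synth_detection_params()`) is a threshold at half the pulse amplitude
  plus a 5-sample moving average.
- Smoothing flattens the crest, so after detection each peak is
  re-localised to the maximum of a minimally smoothed (3-sample) signal
  inside the smoothing window: detection robustness without blurring the
  event time. Detected times are always timestamps of actual samples.

## Single-finger metrics

**Inter-tap intervals** ΔT_i = t_{i+1} − t_i are attributed to the later
tap time, and the **fatigue slope** is the ordinary least-squares slope
of ΔT against elapsed time; positive means slowing (fatigue), negative a
training effect. Attributing the interval to its later endpoint maps a
generative drift *m* to a fitted slope of exactly m/(1+m) in the
noiseless case — a relative bias of about m (4·10⁻⁴ at m = 0.02),
negligible against the cohort spread but made explicit here and in the
recovery tests. When the intervals have zero variance the fit is
returned as slope 0 with R² = 1 and a `degenerate` flag rather than NaN,
so cohort aggregation never propagates missing values silently.

**Windowed excursion.** The amplitude swing of each tap is its crest
minus the minimum signal value within ± half the local inter-tap
interval around the peak. This definition is invariant to constant
offsets (gravity components, sensor bias), scales linearly with the
signal, and captures the crest-to-trough swing of the impact; the raw
crest value is available behind `raw_crest = TRUE`. Swings are averaged
inside consecutive non-overlapping 5 s windows; windows without taps are
reported `NA` and *omitted* from the mean/SD (zero-filling would bias
the mean downward). Percent differences between conditions use
`100 · (reference − other) / reference`, positive = amplitude loss
relative to the reference test.

## Two-finger metrics

Per paired tap event the **inter-finger delay** |t₂ − t₁| is computed;
its per-trial mean and sample SD summarise coordination. Pairing is
ambiguous when the two detections disagree in count, so two rules are
provided: `index_aligned` (default) truncates to the shorter series and
pairs i-th with i-th — the natural reading when counts match — while
`nearest` computes the order-preserving assignment minimising the total
|Δt| (exact dynamic program), which is robust to isolated missed
detections. Neither is asserted as *the* correct rule; results carry the
raw delays so users can re-derive.

Classification uses the empirical simultaneity threshold of 0.1 s — the
worst-case mean delay observed in the easiest (UniSIM) condition — with
*strict* inequality: a simultaneous trial passes iff mean delay < 0.1 s,
an alternating trial passes iff mean delay > 0.1 s (a failed alternation
is typically the participant collapsing into simultaneous tapping). The
boundary value fails both, and the raw mean is always reported so a
different threshold can be applied. An `adaptive` alternation criterion
instead requires the delay to exceed mean + SD of the same participant's
simultaneous test of the same manual condition. Cohort failure rates are
reported unrounded.

## Cohort statistics

**Placement repeatability.** CV = 100 · sd(NTap)/mean(NTap) over
repeated executions; scale-invariant, lower is better. `mean_cv()`
averages participants. Over the published ten-participant table
(`reference_placement_cvs()`) the two sensor placements give 5.57%
(intermediate phalanx) and 4.23% (distal phalanx), which is why the
protocol mounts the sensor distally.

**Sample Fatigue Percentage.** The per-participant slopes of one
test/finger cell are modelled as Gaussian with sample mean μ and sample
(n−1) SD σ; the SFP is the complementary normal CDF at zero,
P(X > 0) = 1 − Φ(−μ/σ) — the estimated fraction of the population that
fatigues in that condition. It is computed from the *fitted* density by
default (an empirical exceedance variant exists behind a flag, matching
the definition rather than replacing it). Degenerate σ = 0 returns 0 or
1 by the sign of μ and errors at μ = 0, where exceedance of a boundary
point mass is undefined. Applying the closed form to the published
per-cell (μ, σ) summaries (`reference_slope_distributions()`) reproduces
five of the eight published SFP cells at two decimals (UniALT index
0.54, UniALT middle 0.50, UniSIM middle 0.31, BimSIM right index 0.38,
BimSIM left index 0.30); the remaining three are not reproducible from
the *rounded* inputs (the closed form gives 0.27, 0.50, 0.48 against
published 0.29, 0.48, 0.47) and were evidently computed from unrounded
values, so only the five consistent cells are used as golden values.

## The synthetic generator

`synth_params()` + `generate_trial()` emulate the acquisition chain:
tap times follow
t_{i+1} = t_i + max(2·pulse_width, T0 + m·t_i + jitter), each tap is
rendered as a biphasic raised-cosine pulse (crest +A, trough −A/2 over
`pulse_width`) on the z axis plus white noise on all axes, and finger 2
is finger 1 plus a per-event offset — δ0 + jitter for simultaneous
modes, T0/2 + jitter for alternate modes. Defaults: 30 s at 120 Hz,
T0 = 0.25 s (4 taps/s, a comfortable maximal rate for a healthy adult),
A = 2 g (a typical fingertip impact), pulse_width = 0.1 s, noise 0.05 g.
One seed fans out into per-finger substreams, so every trace is
independently reproducible.

Design notes:

- The first tap is placed at t = T0, not 0: an event at the trace edge
  could neither be rendered nor detected.
- The `2·pulse_width` floor keeps intervals physical, which bounds how
  much *negative* drift a trajectory can express: at T0 = 0.25 s,
  m = −0.02 s/s hits the floor mid-trial. The drift-recovery experiments
  therefore run at T0 = 0.9 s, where the interval stays above the floor
  for the whole 30 s at every m in the ±0.02 grid.
- A simultaneous trial with zero-mean offset jitter has mean |delay|
  equal to the folded-normal mean σ·√(2/π), not 0;
  `folded_normal_mean()` provides the exact closed form the recovery
  harness asserts against.
- The generator produces clean quasi-periodic tapping. It does **not**
  model tremor, hesitations, double-contacts, baseline drift from hand
  motion, gravity reorientation, or sensor clock skew — so tests passing
  on synthetic cohorts validate the *measurement chain*, not robustness
  to every behaviour of real recordings.

## Validation problem sizes

The test suite checks detection against a brute-force prominence oracle
on random signals up to 2000 samples; perfect recall/precision and ≤ 1
sample timing error over 100 noisy trials at amplitude SNR 10; drift
recovery within ±0.002 s/s averaged over 200 seeds per grid point;
inter-finger delay recovery within ±0.005 s of the folded-normal
expectation over 200 seeds per jitter level; and SFP against a 10⁶-draw
Monte-Carlo within 0.002. These sizes give Monte-Carlo standard errors
comfortably below the asserted tolerances.

## Known limitations

- Published per-trial recordings for the original cohort are not
  available, so cohort-level figures that require raw traces (per-test
  excursion percent differences, failure rates) are validated by
  parameter recovery on synthetic cohorts rather than by reproduction.
- The CSV schema is a documented neutral dialect (`time, ax, ay, az`,
  comma-separated, with a `column_map` escape hatch and unit flags);
  vendor exports may need remapping.
- Inter-sensor synchronisation is assumed done upstream; the package
  validates only that the two traces of a trial overlap for ≥ 90% of the
  stated duration.
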
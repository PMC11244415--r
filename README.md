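# tapmetrics

Analysis pipeline for **instrumented finger-tapping tests** recorded with
wearable tri-axial accelerometers.

The tapping test is a standard probe of fine motor function: a participant
taps two fingers on a flat surface as fast as possible for 30 s, either
simultaneously or alternating, with one hand (index + middle finger) or
both hands (the two index fingers) — four conditions, called here
`UniSIM`, `UniALT`, `BimSIM`, `BimALT`. A small IMU on each fingertip
records tri-axial acceleration at 120 Hz (±8 g full scale). `tapmetrics`
turns those raw traces into interpretable motor metrics:

- **Tap detection** — the motion axis is the one with the greatest robust
  acceleration excursion; taps are local maxima with topographic
  prominence ≥ a threshold and a minimum inter-peak separation.
- **Single-finger metrics** — tap count; inter-tap intervals
  ΔT_i = t_{i+1} − t_i; the **fatigue slope**, the angular coefficient of
  the least-squares line of ΔT versus elapsed time (positive = slowing =
  fatigue, negative = training effect), with its R²; and the tap
  **amplitude excursion** averaged over 5 s windows.
- **Dual-finger metrics** — per-event absolute inter-finger tap delay
  |t₂ − t₁| (near 0 when tapping simultaneously, near half the tap period
  when alternating), its per-trial mean and SD, and pass/fail
  classification against the 0.1 s simultaneity threshold (or an adaptive
  per-participant criterion).
- **Cohort statistics** — the placement-repeatability coefficient of
  variation CV = 100·sd(NTap)/mean(NTap); Gaussian modelling of the
  per-participant fatigue slopes; and the **Sample Fatigue Percentage**

  SFP = P(X > 0) = 1 − Φ(−μ/σ),  X ~ N(μ, σ),

  the estimated fraction of participants showing fatigue in a given test
  and finger.
- **Synthetic generator** — ground-truthed quasi-periodic biphasic tap
  pulses with timing drift, jitter, inter-finger offset, amplitude decay
  and sensor noise, so the full pipeline is testable and calibratable
  without hardware.

## Worked example

```r
library(tapmetrics)

# a 30 s alternating trial with a true fatigue drift of 0.02 s/s
p <- synth_params(drift = 0.02, timing_jitter = 0.01, noise = 0.1, seed = 19)
g <- generate_trial("UniALT", p)

cfg <- session_config(detection = synth_detection_params(p))
res <- analyze_trial(g$trial, cfg)

res$single[c("finger", "n_taps", "slope", "r_squared", "excursion_mean")]
#>       finger n_taps  slope r_squared excursion_mean
#> 1  index_dom     61 0.0196     0.997           2.94
#> 2 middle_dom     61 0.0196     0.997           2.95

res$dual[c("n_pairs", "sa_mean", "sa_std", "classification")]
#>   n_pairs sa_mean  sa_std classification
#> 1      61   0.125 0.00304 alternate_pass
```

The fitted slope 0.0196 recovers the generated drift (0.02 s/s; the small
deficit is the known attribution of each interval to its later tap), R²
is near 1 because the drift dominates the jitter, and the mean
inter-finger delay of 0.125 s ≈ half the tap period classifies the trial
as a correctly executed alternation.

Cohort-level, the SFP of a published test/finger cell is one call:

```r
sample_fatigue_percentage(slope_distribution(mu = 0.006, sigma = 0.060))
#> 0.5398278   # ≈ 0.54: slightly more than half the cohort fatigues
```

A command-line wrapper for simulating and analysing trials is installed
at `inst/scripts/tapmetrics-cli.R` (subcommands `simulate` and
`analyze`).

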
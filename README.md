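# tremorlink

Linking the periodicity of fixational eye movements to the critical
flicker fusion threshold (CFFT).

The CFFT — the frequency at which a flickering light starts to look
continuous — varies between individuals and tracks fatigue, age and a
range of neurological conditions. Ocular **microtremor**, the smallest
fixational eye movement, is a low-amplitude oscillation conventionally
placed in the 70–150 Hz band, right where individual CFFTs live.
`tremorlink` implements, as a tested R package, an analysis chain that
asks whether gaze periodicity predicts a person's CFFT range:

* a **synthetic gaze generator** — alternating fixations and saccades
  between two targets 19° apart, ocular drift as a random walk,
  a circular microtremor oscillation with finite phase coherence,
  microsaccades and blinks, plus simulated flicker-identification trials
  governed by a tremor→CFFT link;
* **kinematics** — forward-difference gaze velocities `v(t) = (X(t+τ) −
  X(t))/τ` with unit and fixational variants, the inter-velocity angle
  `φ(t, t+τ) = arccos(v(t)·v(t+τ) / |v(t)||v(t+τ)|)`, and the
  direction-reversal probability `Pr_φ,k(τ) = P(φ ∈ [(1−1/k)π, π])`,
  whose peak lag estimates the tremor half-period;
* **spectra** — per-segment normalized power spectra and the cumulative
  power spectrum `C_X(f′)` on a 0.5 Hz grid up to the 500 Hz Nyquist;
* **EMD / Hilbert–Huang** — empirical mode decomposition by sifting,
  instantaneous amplitude/phase/frequency of each intrinsic mode
  function, and the cdf of instantaneous frequency per IMF;
* **psychophysics** — the 2-of-3 detection criterion (chance level
  `P(X≥2), X~Bin(3,1/3) = 7/27`), detection fractions `P>f`, and an
  exponential frequency-tolerance fit `P(f) = exp(−f/f_ℓ)`;
* **group statistics** — a Mann–Whitney U scan for the frequency `f*`
  where a feature curve best separates detecting from non-detecting
  participants;
* a **classifier** — decision trees on the four velocity-component
  spectrum features at their `f*`, with SMOTE inside training folds and
  nested stratified 5×5 cross-validation, reporting pooled confusion
  counts, accuracy, sensitivity, specificity and precision.

## A worked example

One minute of synthetic 1 kHz gaze from a participant with a 150 Hz
microtremor, then the reversal statistic on fixational velocities:

```r
library(tremorlink)

prof <- participant_profile("P1", tremor_freq = 150, cfft = 100)
rec  <- simulate_recording(prof, simulation_config(duration = 60), seed = 42)
rec
#> Gaze recording: participant P1, 60000 samples @ 1 ms (60.0 s)
#>   labels: FIX 50600 (84%), SACC 8950, BLINK 450

v     <- fixational_velocity(rec)
curve <- reversal_probability(v, k = c(2, 4, 8), tau_grid = 1:10)
reversal_peak(curve)
#>   k tau_max    pr_max
#> 1 2       3 0.8988129
#> 2 4       3 0.6218617
#> 3 8       3 0.3413211
```

For every interval-narrowness parameter `k` the probability of a gaze
direction reversal peaks at a lag of 3 ms: the gaze inverts direction
every ~3 ms, i.e. a full oscillation period of 5–7 ms,

```r
period_to_frequency(c(5, 7))
#> [1] 142.8571 200.0000
```

an oscillation in the 143–200 Hz range — the upper microtremor band the
recording was generated to contain. The same machinery scales to cohorts:
`run_pipeline(run_config(...), out_dir)` simulates a cohort, extracts the
16 feature families, produces the `f*` separation table and the
classifier report, and writes a manifest that makes the run byte-for-byte
reproducible.

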
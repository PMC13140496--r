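# respmech

Neuromuscular and neuromechanical analysis of respiratory EMG and
inspiratory pressure recordings.

`respmech` is for physiologists who record respiratory muscle
electromyograms (diaphragm, external intercostal, parasternal) together
with oesophageal pressure in small rodents — typically anaesthetised
mice studied across behavioural states (baseline, post-vagotomy,
chemostimulation with hypercapnic hypoxia, and a sustained tracheal
occlusion driven to task failure) — and need the standard quantitative
indices of respiratory neuromuscular performance computed reproducibly
from raw delimited text exports.

## What it computes

Per breath and per behavioural state, from filtered EMG and pressure:

- **Neural respiratory drive**, the tidal EMG as a fraction of maximal
  activation:
  `NRD = EMG / EMG_max × 100 (%)`,
  where `EMG_max` is the mean peak envelope over the best five
  consecutive peak efforts of the sustained tracheal occlusion.
- **Neuromechanical efficiency**, pressure generated per unit of
  integrated EMG:
  `NME = P / ∫|EMG| dt (cmH2O / µV·s)`.
- **Tension–time index**, the fatigue-risk product of relative pressure
  and duty cycle:
  `TTI = (P / MIP) × (Ti / Ttot)`,
  with `MIP` the largest inspiratory deflection during occlusion.
- **Inspiratory drive rate** and **EMG rise slope**: onset-to-peak
  slopes of the pressure deflection (cmH2O/s) and of the integrated EMG
  envelope (µV/s).
- **Welch spectrum parameters** of the filtered EMG (Hamming windows of
  2048 samples, 50% overlap): mean, median and maximum frequency with
  their powers, and total band power over 30–1000 Hz (the 30 Hz floor
  excludes ECG contamination).
- **Entropy** of the filtered EMG: Shannon entropy of the 3-decimal
  amplitude distribution (bits), and approximate and sample entropy
  (`m = 2`, `r = 0.25 × SD`, Chebyshev distance;
  `SampEn = −ln(A/B)` with self-matches excluded).
- **Occlusion pressure–time analysis**: one (time, peak pressure) point
  per effort, task failure as the first sustained decline below 90% of
  the peak nadir, and the trapezoidal AUC of the effort envelope to
  failure.

Preprocessing follows standard practice for rodent respiratory EMG: a
50 Hz notch (Q = 35) plus a fourth-order Butterworth bandpass
(30–1000 Hz), both applied with zero phase; filter stability is
verified automatically and unstable transfer-function designs fall back
to an analytically derived second-order-section cascade.

A seeded synthetic-recording generator (`generate_recording()`)
emulates the whole protocol with exact ground truth for every stage,
which is how the package tests itself end to end.

## Worked example

```r
library(respmech)

gen <- generate_recording(generator_config(seed = 42))
gen$recording
#> <recording> subject sim1 (wt, 8 months)
#>   dia         520000 samples @  20000 Hz [uV]
#>   eic         520000 samples @  20000 Hz [uV]
#>   ps          520000 samples @  20000 Hz [uV]
#>   pressure     26000 samples @   1000 Hz [cmH2O]
#>   states: baseline [0.50, 4.70], post_vagotomy [5.70, 11.90],
#>           hchx [12.90, 16.30], occlusion [17.30, 25.50]

an <- analyze_recording(gen$recording)
an
#> <resp_analysis> subject sim1: 46 breaths, 12 muscle-state spectra
#>   MIP 22.96 cmH2O; occlusion failure at effort 12, AUC 85.5 cmH2O.s

an$indices[an$indices$muscle == "dia",
           c("state", "nrd", "nme", "tti", "ti", "ttot", "duty_cycle")]
#>           state  nrd  nme   tti    ti  ttot duty_cycle
#> 1      baseline 36.4 2.57 0.132 0.156 0.399      0.391
#> 2          hchx 57.2 2.69 0.212 0.128 0.320      0.401
#> 3     occlusion 70.3 2.50 0.205 0.157 0.500      0.314
#> 4 post_vagotomy 47.4 2.57 0.115 0.157 0.600      0.262
```

Reading the numbers: neural drive rises from 36% of maximum at baseline
through vagotomy (47%) and chemostimulation (57%), the expected
progressive recruitment; the median NME of 2.57 cmH2O/µV·s recovers the
generator's configured coupling gain of 2.5 within 3%; the baseline TTI
of 0.13 is the product of relative pressure (~0.34 of MIP) and the 0.39
duty cycle; and task failure is detected at effort 12 of 16, exactly
where the generator placed the onset of decline.

Directory-level batch processing mirrors the same analysis over many
recordings and writes five tidy CSV tables plus a run manifest:

```r
write_recording(gen$recording, "data/in")
run_batch("data/in", "data/out")
```

A thin command-line wrapper with `generate` and `analyze` verbs lives
in `inst/cli/respmech.R`.

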
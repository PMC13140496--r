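---
title: "Methods: respiratory neuromuscular indices from EMG and pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiratory neuromuscular indices from EMG and pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameters and numerical decisions
behind `respmech`, in the order the pipeline applies them. Everything
here describes what the code does and why; no empirical claim is made
beyond what the package's tests and `scripts/acceptance.R` themselves
compute.

## Recordings and assumptions

A recording is a set of uniformly sampled channels — respiratory muscle
EMG in µV (typically 20 kHz) and oesophageal pressure in cmH2O
(typically 1 kHz) — sharing one time origin, plus labelled
behavioural-state intervals (baseline, post-vagotomy, hypercapnic
hypoxia, sustained tracheal occlusion). The package assumes a common
clock across channels; if an acquisition system timestamps channels
independently, alignment must happen upstream. Sampling must be
regular: the reader infers each channel's rate from the median
inter-sample interval and rejects files whose intervals deviate from it
by more than 1%. Non-finite samples are kept and flagged at read time —
artifact handling is an explicit later step, never a silent one.

## Filtering

EMG is conditioned by a 50 Hz notch (quality factor 35; an RBJ biquad)
followed by a fourth-order Butterworth bandpass at 30–1000 Hz, the
physiologically relevant myoelectric band; the 30 Hz floor also rejects
most ECG contamination, which is why no template subtraction is
attempted. Both filters are applied forward–backward (zero phase).
Phase handling matters here: the onset-to-peak slope measures
(inspiratory drive rate, EMG rise slope) depend on burst onset and peak
*timing*, which zero-phase filtering preserves. The cost is that
effective attenuation in dB doubles, which the tests account for.

Stability is checked by the pole-magnitude test (all poles strictly
inside the unit circle, tolerance `1 − 1e−9`). The transfer-function
Butterworth design is numerically fine at order 4, but higher orders or
narrow bands relative to the sampling rate destabilise the rooted
polynomial form. In that case the filter is rebuilt as second-order
sections directly from the analytic Butterworth prototype poles
(lowpass→bandpass transform and bilinear transform applied pole by
pole, with corner prewarping), so the ill-conditioned high-order
polynomial is never formed; each conjugate pole pair becomes a biquad
with zeros at z = ±1. The result is flagged (`bandpass_form = "sos"`).

## Envelope and per-breath EMG integral

The "integrated EMG" trace is full-wave rectification followed by a
centred moving average. The window default is 50 ms: long enough to
smooth individual motor-unit spikes, short relative to mouse
inspiratory bursts (~100–300 ms). A leaky integrator would be an
alternative definition; the moving average was fixed because it has
zero lag (centred) and an exact closed form under test signals, and the
window is exposed as configuration.

The NME denominator is *not* the envelope but the trapezoidal time
integral of the rectified filtered EMG over the breath (µV·s), matching
the index's stated units. Breath windows are inclusive of both
endpoints so that a constant of 2 µV over 0.1 s integrates to exactly
0.2 µV·s.

## Breath segmentation

Breaths are detected from the pressure channel by default — it is
present and phasic in every state, including occlusion, where airflow
(and in severe disease, EMG in a given muscle) may not be informative.
An EMG-envelope driver is available by configuration. Inspiratory
pressure swings are sub-atmospheric, so pressure is analysed as the
magnitude of deviation below the zero-flow baseline.

The baseline and its variability are estimated from the quietest decile
of 200 ms windows. Quietness is scored by mean deviation from the
global median (level), not by within-window SD: a smoothed envelope's
quiet windows have tiny internal SD, which would underestimate the
baseline variability and admit spurious bursts. Onsets are upward
crossings of `median + 3 × SD`; offsets the subsequent downward
crossing of half that threshold (hysteresis); bursts closer than 50 ms
are merged, then bursts shorter than 30 ms discarded — in that order,
deterministically. Because the threshold is data-adaptive, the detected
breath count is invariant to uniform amplitude scaling, the property
that makes normalised indices comparable across preparations.

Timing definitions: `Ti` is onset to offset; `Ttot` is onset to next
onset (standard respirometry — the last breath of a segment has no
defined `Ttot` and is excluded from duty-cycle statistics); the peak is
the argmax of the deflection within the burst, earliest sample on ties.
Slopes are two-point endpoint slopes from onset to peak; a least-squares
fit over the rising limb would be an alternative, but "onset to peak"
reads as an endpoint definition and the two-point form is what the
half-sine ground truth validates.

## Reference maxima and the indices

`EMG_max` is the mean peak envelope over the window of five consecutive
occlusion efforts with the largest mean (earliest window on ties; with
fewer than five efforts the mean of all efforts is used and flagged).
`MIP` is deliberately different: the single largest per-effort
inspiratory deflection, because maximal inspiratory pressure is
conventionally a single best effort. From these:

- `NRD = 100 × peak envelope / EMG_max` (%). Since numerator and
  reference derive from the same channel, uniform gain changes cancel —
  NRD is comparable across electrodes and animals even when raw µV are
  not.
- `NME = pressure amplitude / EMG integral` (cmH2O/µV·s).
- `TTI = (P / MIP) × (Ti / Ttot)`, per breath, using that breath's
  deflection magnitude as `P`.

Within-state aggregation is the median — robust to an occasional
mis-segmented breath — and per-breath rows are always emitted so any
other aggregate can be recomputed downstream. Note one near-tautology:
occlusion-state NRD is computed against a reference drawn from the same
occlusion, so it sits near (but below) 100% by construction; it is
reported for completeness, not inference.

## Spectral parameters

Welch's method with Hamming windows of 2048 samples and 50% overlap
(signals shorter than one window fall back to a single full-length
segment), mean removal per segment, no padding, density scaling — so
the PSD integrates to the signal's mean square, which the tests verify
to 5% on stationary noise. Spectra are computed per muscle per
*state* interval, not per breath: one spectrum per muscle per condition
is the granularity at which spectral summaries are reported. EMG is
converted from µV to mV first, so powers are in mV².

Over the 30–1000 Hz band: mean frequency is the power-weighted average;
median frequency is the first bin where cumulative trapezoidal power
reaches half the band total (bin-resolution, no interpolation); maximum
frequency is the earliest argmax bin; total power is the trapezoidal
band integral. An all-zero band yields `NaN` frequencies, zero power
and an invalid flag rather than an error.

## Entropy

All three measures operate on the filtered EMG of a state interval —
the amplitude-distribution complexity of the myoelectric signal itself,
not its envelope.

- **Shannon**: amplitudes rounded to 3 decimals; `H = −Σ p log2 p`
  (bits); at least 50 finite samples, else flagged invalid. The
  discretisation is absolute, so Shannon entropy is deliberately *not*
  scale-invariant.
- **ApEn** (m = 2, r = 0.25 × SD): `Φm − Φm+1`, Chebyshev distance,
  self-matches included, counts normalised per template.
- **SampEn**: `−ln(A/B)` over ordered pairs of distinct templates, both
  template indices restricted so every B-pair has an (m+1)-extension;
  `A ≤ B` by construction, hence `SampEn ≥ 0`. `A = 0` yields an
  invalid flag, never an infinity.

SD is the sample standard deviation (n − 1) of the cleaned signal;
cleaning removes non-finite values and subtracts the least-squares
linear trend (the package's concrete reading of "preprocessing for
stationarity"; it is the minimal detrending with an exact closed form).
A constant signal has r = 0 and is returned as 0 with a degenerate
flag, so batch tables stay rectangular. Template matching runs in
compiled code; the test suite pins it to independent pure-R
double-loop implementations within 1e−9, and to the affine-invariance
property (a·x + b leaves ApEn/SampEn unchanged because r scales
with SD).

At 20 kHz, minutes of EMG make the O(N²) template search expensive and
oversampled: after the 1000 Hz bandpass there is no content above
2 kHz Nyquist, so signals are decimated to 2 kHz (simple subsampling,
alias-safe post-filter) before ApEn/SampEn. This is configuration
(`decimate_to_hz`, default 2000; `NULL` disables) and it changes the
measures' absolute values — entropies are rate-dependent statistics —
so comparisons must hold the rate fixed, which the pipeline does.

## Occlusion pressure–time analysis

Each occlusion effort becomes one (time, peak deflection) point. The
"sustained peak nadir" is the maximum deflection magnitude (the most
negative pressure), earliest effort on ties. Task failure is the first
effort after the nadir at which two consecutive efforts fall below 90%
of the nadir — the decline fraction and run length are declared
conventions, exposed as configuration, since "decline" is not otherwise
quantified. If no sustained decline occurs the last effort is used and
flagged. The AUC is the trapezoid of the effort points (the envelope of
discrete maximal efforts, not the continuous trace) from the first
effort through failure.

## The synthetic generator

`generate_recording()` exists so that every stage can be tested against
exact ground truth. It emulates: phasic inspiratory bursts (half-sine
envelopes of duration Ti, period Ttot) modulating brick-wall
band-limited Gaussian noise (30–1000 Hz); a broadband EMG noise floor;
50 Hz line interference; a biphasic 4 ms ECG-like pulse train at 10 Hz;
a coupled pressure channel; and the four-state protocol, with
post-vagotomy breathing slower and deeper (×1.5 Ttot, ×1.3 amplitude),
chemostimulation faster and stronger (×0.8 Ttot, ×1.6 amplitude), and
an occlusion of escalating maximal efforts (×3 tidal amplitude at peak)
declining multiplicatively (×0.85 per effort) from a configured failure
onset.

Default conditions, chosen once as realistic for a urethane-
anaesthetised adult mouse: EMG at 20 kHz, pressure at 1 kHz, Ti 0.16 s,
Ttot 0.40 s (150 breaths/min, duty cycle 0.4), burst amplitudes
dia/eic/ps = 40/25/20 µV over a 2 µV floor, 5 µV line noise, 20 µV ECG
spikes, pressure coupling gain 2.5 cmH2O/µV·s (≈8 cmH2O tidal swings,
≈23 cmH2O peak efforts), cardiac pressure artifact 0.15 cmH2O at
10 Hz plus 0.05 cmH2O white sensor noise, 16 occlusion efforts with
failure onset at effort 12.

Two coupling decisions make the ground truth exact rather than
approximate. First, pressure couples to the *expected* rectified burst
(amplitude × √(2/π) for the Gaussian carrier), not to the noisy EMG
realisation, so the configured NME gain is a true parameter. Second,
that expectation includes the rms fraction of the carrier retained by
the default zero-phase bandpass (≈0.93, computed analytically from the
filter response): the Butterworth corners sit exactly at the carrier
band edges, so a few percent of carrier power lies beyond the −3 dB
points, and the pipeline — which integrates *filtered* EMG — would
otherwise see a systematically biased gain.

What the generator does **not** emulate: motor-unit structure and its
spectral signature (the carrier is flat in band, so spectral-parameter
recovery tests calibration, not myopathic spectral shifts);
cardiorespiratory coupling (ECG is independent of breath phase);
gas-exchange dynamics (chemostimulation is a pure amplitude/timing
change); airflow (out of scope); and electrode artifacts such as
movement transients. Passing the recovery tests therefore demonstrates
that the pipeline measures what it claims under the stated signal
model — not that the model captures every property of real recordings.

## Problem sizes and determinism

The test suite exercises the full default conditions (20 kHz, ~26 s,
three muscles) in its end-to-end blocks and a lighter 4 kHz, six-breath
configuration in unit tests; entropy oracles are pinned at n = 300–1000
where the O(N²) reference is cheap. All generator randomness flows from
one integer seed; a fixed seed yields bit-identical recordings, and
batch analysis of identical inputs yields byte-identical tables (rows
deterministically ordered, doubles written with `%.17g` so text
round-trips are exact). The generator saves and restores the caller's
RNG state.

## Known limitations

- Segmentation quality degrades on heavily smoothed envelopes whose
  noise correlation time approaches `min_ti`; the adaptive threshold is
  a convention, not a detector with guarantees, and pathological noise
  can still produce spurious bursts (the count-invariance property
  holds regardless).
- Median frequency is reported at bin resolution (no interpolation);
  with the default settings the bin is ~9.8 Hz at 20 kHz.
- ApEn/SampEn values depend on the (decimated) sampling rate and on
  segment length; they are comparable only at fixed settings.
- Group-level statistics (ANOVA and post hoc tests) are deliberately
  out of scope: the pipeline ends at tidy per-breath and per-state
  tables that any statistics package can consume.
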
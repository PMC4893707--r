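---
title: "Time-frequency mapping and random-field inference for spike-wave discharges"
author: "swdmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency mapping and random-field inference for spike-wave discharges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdmap)
```

## The problem

Rats of the GAERS strain (Genetic Absence Epilepsy Rat from Strasbourg)
produce frequent spontaneous spike-wave discharges (SWDs): stereotyped,
harmonic-rich oscillations around 7 Hz, highly synchronized across the
cortex. A focal cortical intervention — here, thin radiosurgical
transections made by interlaced synchrotron microbeams in one hemisphere —
is expected to change two things about these seizures on the treated side:
their 6–8 Hz power and the coherence between nearby electrodes, while
leaving the contralateral side and the interictal (between-seizure)
background untouched.

`swdmap` implements the complete quantification pipeline for that question:

1. a calibrated synthetic session generator standing in for raw recordings,
2. SWD spike/event detection with the first-spike/last-spike rule,
3. sliding-window Welch power and magnitude-squared coherence on a fixed
   4–20 Hz grid,
4. per-frequency baseline z-normalization and linear rescaling of seizure
   time to a common axis,
5. Gaussian smoothing and pixel-level inference on pooled time-frequency
   maps with random-field-theory (RFT) control of the family-wise error,
6. 6–8 Hz band summaries with repeated-measures ANOVA and post-hoc tests,
   and interictal FFT band statistics,
7. the interlaced-microbeam transection geometry itself.

## The synthetic generator

No public recordings exist for this design, so the generator *is* the data
source, and its defaults define the study conditions:

| parameter | default | meaning |
|---|---|---|
| `fs` | 5000 Hz | sampling rate of the emulated acquisition |
| `swd_rate` | 62.2 / h | baseline Poisson event rate |
| `swd_duration_mean`, `swd_duration_sd` | 24.8 s, 2.7 s | event durations, normal truncated to [5, 60] s |
| `f0` | 7 Hz | SWD fundamental |
| `harmonic_amps` | `0.58^(k-1)`, 8 harmonics | phase-aligned harmonic series |
| `snr_amplitude` | 10 | ictal/interictal 6–8 Hz *amplitude* ratio |
| `coupling` | 0.4 | background inter-channel coherence |
| `swd_coupling` | 0.95 | ictal inter-channel coherence (hypersynchrony) |
| `background_exponent` | 1 | 1/f^β background slope |

Electrode coordinates are not printed in the source material; the layout
places two rows of five electrodes at AP {+3, +1, −1, −3, −5} mm, ML
±4.5 mm, so the four transection planes (+2, 0, −2, −4 mm) fall midway
between adjacent electrodes.

The SWD waveform is a *stochastic narrowband process*: phase-aligned
harmonics of `f0` (their sum is a periodized pulse — one sharp spike riding
on a slow wave per cycle) modulated by a slow lognormal amplitude envelope
and slow random phase jitter. The jitter is essential, not cosmetic: two
deterministic periodic signals always have magnitude-squared coherence 1,
so a purely deterministic waveform could not express a coherence drop
between channels. The phase process is smoothed (a twice-filtered
Ornstein–Uhlenbeck path) because raw OU phase noise has Lorentzian spectral
wings that leak harmonic power across the whole analysis band. Both jitters
use correlation times of a few hundred milliseconds.

Amplitude calibration is numeric: reference realizations of the waveform
and of the 1/f background are generated from a private, fixed RNG stream,
and the SWD amplitude is scaled so the 6–8 Hz amplitude ratio equals
`snr_amplitude`. The private stream matters: a per-session random
calibration scale would shift every seizure of a session together, which
violates the independence that fixed-effects pooling assumes and inflates
the false-positive rate of the map inference. The amplitude ratio (rather
than a power ratio) of 10 reflects how completely SWDs dominate the GAERS
trace in-band; it also makes the background contribution to in-band ictal
power about 1%, so an injected power scaling is recovered almost exactly
by a periodogram ratio.

A "treatment" is an `effect_spec()`: on target channels (default: the left
hemisphere) the harmonic components falling inside the effect band are
scaled by `sqrt(power_scale)` (so in-band *power* scales by `power_scale`),
and a fraction `coherence_drop` of the shared SWD component is replaced by
independent waveform copies.

What the generator does *not* emulate: biophysical thalamocortical
dynamics, movement and electrode artifacts, distance-dependent coherence
(a single shared-component model is used), non-stationary background, and
circadian rate fluctuations. Passing tests therefore demonstrate the
correctness and calibration of the *analysis machinery* under controlled
conditions, not performance on real recordings.

## Events and windows

Events are defined by their first and last spikes. The detector proposes
candidate regions with a hysteresis gate on sliding 6–8 Hz band power
(enter at 8x, exit at 3x the session median), then finds spikes as local
maxima of the rectified trace above 4 robust SDs. The robust SD is the
median absolute deviation (x 1.4826) of the *whole* session, because the
MAD of an ictal excerpt is inflated by the seizure itself. Spikes closer
than 40 ms are merged (largest wins); spike runs with gaps at most 1 s
spanning at least 2 s become events.

Each event's analysis window runs from 10% of the event duration before
onset to 10% after offset. Events whose window (plus the spectral margin)
leaves the recording are excluded, never clipped.

## Spectral estimation

Power and coherence are estimated on a fixed grid: 4–20 Hz in 0.1 Hz steps
(161 bins), one 4 s window every 100 ms. Within each window, Welch's
method averages seven Hann-tapered, constant-detrended 1 s sub-segments
with 50% overlap. Seven averages are the minimum for a usable coherence
estimate; the sub-segment count K is recorded in map metadata, and the
expected coherence bias for independent signals is 1/K. The 0.1 Hz grid is
finer than the 1 Hz native resolution of a 1 s sub-segment; the DFT is
evaluated directly at the grid frequencies (algebraically identical to
zero-padding to `fs`/0.1 samples) — spectral interpolation, not added
resolution.

## Normalization, rescaling, smoothing

Maps are z-scored per frequency against the pre-onset baseline (sample
SD), then each frequency row is linearly interpolated onto a common
seizure axis of 121 points spanning [−0.1, 1.1] (onset = 0, offset = 1),
so that seizures of different durations align. 121 bins keep at least the
native 0.1 s resolution for the shortest admitted (5 s) seizures.

One estimation choice deserves emphasis. The nominal baseline is the 10%
pre-onset margin, but a 4 s window *centred* inside that margin overlaps
the seizure itself; the contamination makes the baseline SD proportional
to ictal power and cancels the very power differences under test (in
simulation, a 40% injected reduction became statistically invisible).
The pipeline therefore computes baseline statistics only from bins whose
full window lies before onset, and extends the map grid three window
lengths to the left of the nominal window start so that the baseline SD
has enough effective degrees of freedom despite the heavy window overlap.
Sessions destined for map analysis must provide a clean pre-onset epoch
(about 12 s) for each event; `session_event_maps()` skips events whose
baseline epoch overlaps a neighbouring event.

Smoothing is a separable Gaussian with FWHM 5% of seizure duration in time
and 5 Hz in frequency, truncated at 4 SD, with edge handling by kernel
renormalization (mass-preserving truncation) rather than padding, so map
borders are not contaminated by implicit zeros.

## Inference

A fixed-effects analysis pools animals and seizures per condition. The
pixel-wise statistic is a pooled-variance two-sample t (df = n1 + n2 − 2),
one-sided (pre > post) by default; the "paired" reading of the original
description is contradictory for unpaired sets of different sizes, so the
two-sample form is the default and `paired = TRUE` is available when
counts match.

The corrected threshold solves E[EC](u) = alpha, where E[EC] is the
expected Euler characteristic of a smooth t-field:
rho0 is the t upper-tail probability and rho1, rho2 the standard 1D/2D
t-field EC densities; resel counts come from the applied kernel
(smoothness is known by construction, not estimated from residuals):
R1 = (T−1)/f_t + (F−1)/f_f, R2 = (T−1)(F−1)/(f_t f_f). The root is found
by bisection to 1e-8 in a bracket starting at the pointwise t quantile;
at low df the polynomial tails of the EC densities can keep E[EC] above
alpha at the nominal upper bracket, so the bracket extends geometrically
until it straddles the root. On 500 simulated null experiments at the
pipeline's grid and smoothness (121 x 161, FWHM 5 and 50 bins, 20 + 20
observations) the empirical family-wise error is about 0.04 — controlled
and slightly conservative, as lattice RFT should be.

## Band statistics

Band summaries average the z-maps over 6–8 Hz, the ictal bins, and the
three central electrodes of each hemisphere (adjacent pairs for
coherence), and are expressed as percent of each animal/side's baseline.
The repeated-measures two-way ANOVA is fitted with `stats::aov` as
`value ~ timepoint * side + Error(animal/side)`; with the same animals at
every timepoint the time effect is tested in the within-animal stratum
(the original description of time as a "between" factor with repeated
measures on the same animals is internally inconsistent; this is the
standard resolution). Post-hoc comparisons are paired t-tests of each
post-baseline timepoint against baseline, per side, Bonferroni-corrected
over the post-baseline timepoints (Sidak available, matching the two
corrections named in the source material; Bonferroni is the default).
All-equal inputs (zero sums of squares) are reported as F = 0, p = 1
rather than NaN.

Interictal band edges are conventional rodent-LFP definitions — delta
1–4, theta 4–8, alpha 8–12, beta 12–30, low gamma 30–55, high gamma
65–120, epsilon 120–600 Hz, with the 55–65 Hz notch region skipped — and
are configurable. Interictal epochs are 2–10 s segments taken before SWD
onsets.

## Beam geometry

One transection is delivered as a single 50 um-thick, 2 mm-wide microbeam
through four ports 45 degrees apart, the animal shifted 50 um along the
stacking axis between ports. Thickness along that axis is
`width + (n_ports − 1) x step` = 200 um. In the transection plane the four
2 mm strips intersect in a regular octagon; its width across flats
(rotating-calipers minimum) equals the strip width, 2 mm, and the
across-vertices diameter is 2/cos(22.5 deg) ≈ 2.165 mm. "Diameter" is
geometrically ambiguous for an octagon, so both are reported; the
across-flats reading matches the printed value exactly. Dose values are
carried as metadata only — no radiation transport is computed.

## Problem sizes and numerical choices

Simulation-based tests run at reduced sampling rates (50–200 Hz; the
analysis band ends at 20 Hz, and event statistics do not depend on `fs`)
and with sessions sized to the seizure counts they need; rate, durations,
`f0`, grid, smoothing and effect sizes always stay at the study values.
The effect-recovery check uses 4 animals x 5 seizures per condition
(20 per condition) with a 40% left-hemisphere power reduction; the RFT
calibration uses 500 null replicates; the post-hoc specificity check uses
120 replicate null experiments.

Other numerical choices: durations are drawn by rejection from the
truncated normal; event placement redraws collisions and falls back to
sequential placement with exponentially distributed slack when rejection
cannot fit a dense session (an error is raised only when the events
genuinely cannot fit); Gaussian kernels use SD = FWHM / (2 sqrt(2 ln 2));
the baseline SD is the sample (n − 1) SD; coherence values are clamped to
[0, 1] against floating-point overshoot; EDF output quantizes to 16 bits
of the per-channel amplitude range.

## Known limitations

* The generator's single shared-component coupling has no inter-electrode
  distance dependence.
* RFT thresholds assume the lattice is dense relative to the smoothness;
  with time FWHM of 5 bins this holds, but much coarser grids would make
  the threshold conservative.
* Percent-of-baseline is unstable when the baseline-condition band mean is
  near zero (it can be for coherence z-maps when ictal and background
  coherence coincide); the generator's hypersynchronous `swd_coupling`
  default keeps the baseline well away from zero.
* The EDF writer/reader covers plain EDF with equal sampling rates across
  signals — sufficient for this pipeline's round-trips, not a general
  EDF+ implementation.
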
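---
title: "Work-of-breathing indices from respiratory inductance plethysmography: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Work-of-breathing indices from RIP: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripwob)
```

## The measurement problem

Respiratory inductance plethysmography (RIP) records breathing noninvasively
with two elastic transducer bands, one around the rib cage (RC) and one
around the abdomen (AB). Under the classical Konno–Mead two-compartment view
of chest-wall motion, the two band signals approximate the compartmental
volume excursions, and their relative amplitude and timing carry clinically
useful information: how much of each breath the rib cage contributes, and
how synchronously the two compartments move. Asynchrony raises the work of
breathing; rib cage and abdomen moving in opposition ("paradoxical
breathing") is a hallmark of obstruction or respiratory muscle dysfunction.

`ripwob` computes the standard work-of-breathing (WOB) index set from an
uncalibrated two-band recording:

* **Phase angle (Φ)** — unsigned synchrony measure in degrees, 0° for
  perfect synchrony, 180° for paradox.
* **Labored breathing index (LBI)** — ratio of the maximal (in-unison)
  compartmental amplitude to the tidal-volume proxy actually recorded;
  1 at synchrony, growing with asynchrony.
* **Percent rib cage (RC%)** — the rib cage's share of the combined
  compartment excursion.
* **Breaths per minute (BPM)** — the dominant spectral frequency of the two
  channels, times 60.

All four are ratios or angles, so no volume calibration is needed; band
units are arbitrary throughout. The reference conditions the package's
synthetic generator emulates are a small anaesthetised rodent: breathing
near 0.943 Hz (≈ 57 breaths/min), RC% slightly above 50, and tight normal
ranges (Φ below 30°, LBI below 1.05) for synchronous breathing.

## Per-window index definitions

Indices are computed on a sliding analysis window of `window_n` samples
(default 20). At the default 10 Hz sampling rate a window spans 2 s — about
two rat breaths — and with stride 1 the pipeline emits 10 index samples per
second. One consistent window feeds all three windowed indices, so each
emitted sample describes one stretch of signal.

**Phase angle.** Both window channels are normalised by mean subtraction,
then

$$\Phi \;=\; \arccos
  \frac{\sum_n x(n)\,y(n)}
       {\sqrt{\sum_n x(n)^2 \sum_n y(n)^2}},$$

the angle whose cosine is the cosine similarity of the zero-mean windows.
Mean subtraction is essential: the bands carry large, tension-dependent DC
offsets that would otherwise dominate the inner product. The arccos argument
is clamped to [−1, 1] to absorb rounding. Two consequences of this estimator
are worth keeping in mind:

* It is symmetric and scale-invariant, but **unsigned** — it cannot say
  whether the rib cage leads or lags the abdomen.
* Near the folds of its range (0° and 180°) it has a **noise floor**: with
  channel noise at 5% of the signal amplitude and 20-sample windows, a true
  0° lag reads as ≈ 5°, and a true lag θ is pulled toward
  $\sqrt{\theta^2 + \text{floor}^2}$. The floor shrinks with the
  noise-to-signal ratio; it is a property of any bounded-range angle
  estimate, not a bug, and the test suite checks the floor model
  quantitatively.

**Excursion estimator.** RC%, LBI and the tidal proxy all need a compartment
amplitude per window. The package uses the peak-to-peak range after removing
the straight line through the window's first and last samples (endpoint or
"bridge" detrending). This choice is deliberate:

* it is *exactly* invariant under linear baseline drift added to both
  channels (band tension creep, thermal drift);
* it is linear in the window, which guarantees LBI ≥ 1 (the range of a sum
  never exceeds the sum of ranges);
* on windows covering whole breath cycles the endpoints coincide, the
  estimated slope is zero, and the peak-to-peak is unbiased at any breath
  phase.

A least-squares trend line — the other obvious candidate — was evaluated and
rejected: on windows only one or two breaths long its slope correlates with
the breathing waveform itself (the fitted slope of a pure sinusoid over
whole periods is proportional to cos φ/ωT, not zero), inflating excursions
by an amount that depends on where in the breath the window falls. In
practice that bias moved equal-amplitude RC% estimates several points off 50
and distorted dense-window LBI by up to 8%.

**LBI.** With $A_{RC}$, $A_{AB}$ the channel excursions and $A_{RC+AB}$ the
excursion of the sample-wise sum (the uncalibrated tidal-volume proxy),

$$\mathrm{LBI} = \frac{A_{RC} + A_{AB}}{A_{RC+AB}} \;\ge\; 1 .$$

The numerator is the amplitude the two compartments would produce moving in
unison; the denominator is what they actually produce. For equal-amplitude
sinusoids at lag θ the continuous-limit value is $1/\cos(\theta/2)$, which
the windowed pipeline reproduces within 0.5% across the lag grid. One
ambiguity in the source definitions — instantaneous sample magnitudes versus
window amplitudes — is resolved here in favour of window amplitudes: the
instantaneous reading makes the denominator vanish twice per breath, whereas
the window reading yields the observed behaviour (LBI = 1 at synchrony,
smoothly increasing with lag).

**Degenerate windows.** A flat window (excursions below 10⁻⁹ of the signal
scale), a zero-variance channel, or a vanishing summed-signal excursion
(near-total paradox with equal amplitudes, where LBI is unbounded) produces
a `valid = FALSE` sample with `NA` indices rather than an error, so one
artefact cannot abort a long recording. The standalone index functions, by
contrast, raise classed errors for these cases, since a caller passing a
single window should hear about it. Invalid samples are excluded from
summaries and histograms but counted, and the valid fraction is reported.

**Synchrony classification** is a pure threshold rule: synchronous iff
Φ < 30° *and* LBI < 1.05 (the conventional normal range), paradoxical iff
Φ ≥ 150°, asynchronous otherwise. The paradox cutoff extends the 180°
definition to a band because exact 180° is never observed under noise; both
thresholds are configurable via `wob_thresholds()`.

## Respiratory rate

The rate estimator transforms both mean-removed channels with an FFT
(rectangular window, zero-padded to the next power of two), averages the two
magnitude spectra per bin, and restricts the result to a physiological band,
0.3–3.0 Hz (18–180 breaths/min) by default, DC excluded. Within the band it
selects the maximum magnitude and every bin within 20% of it, and reports 60
times the amplitude-weighted mean frequency of the selected bins. For a
single clean line this reduces to the peak frequency; for a peak split
across bins it interpolates. The weighting interpretation ("weighted average
using indices") is resolved as amplitudes-as-weights over bin frequencies —
the only reading that collapses to the peak for a single line.

Two guards keep the estimate honest. The record must be at least 2 s long,
and if the maximum in-band magnitude is under 3× the in-band median the
result is flagged invalid rather than reporting a noise peak (the
channel-averaged max/median ratio of pure white noise sits near 2.4).

Bin width (fs/nfft; 0.0024 Hz ≈ 0.15 BPM for a 210 s record at 10 Hz) is
reported with every estimate so tolerances are explicit. Sub-bin agreement
with a generator frequency is only meaningful for rate-stable breathing:
5% breath-period jitter broadens the line over ~20 bins, shifting the
weighted mean by a few tenths of a BPM. The whole record is analysed at
once; breath-by-breath rate tracking is out of scope.

## The synthetic generator

Real band recordings for the target preparation are not distributable, so
verification rests on a generator whose ground truth is known by
construction. The waveform model is one sinusoidal cycle per breath:
per-breath periods are drawn with a stated coefficient of variation around
1/f, per-breath amplitude scales (common to both compartments) likewise, the
RC channel is phase-shifted against AB by a fixed lag, and common linear
drift plus independent white Gaussian noise are added. Defaults are the
study conditions: 0.943 Hz breathing, amplitudes 1.13 : 1.0 (RC% ≈ 53),
5% rate and amplitude jitter, noise at 5% of the AB amplitude, 210 s at
10 Hz.

The model is deliberately minimal. The index formulas are waveform-agnostic,
typical band traces are near-sinusoidal, and a sinusoid-per-breath makes
closed-form truth available: phase lag θ, LBI $1/\cos(\theta/2)$, RC%
$100\,a_{RC}/(a_{RC}+a_{AB})$, rate f. What it does **not** emulate: band
slippage and motion artefacts, nonlinear band response, inspiration/
expiration asymmetry, time-varying asynchrony, or characterised sensor noise
spectra. Passing the recovery tests therefore demonstrates correctness of
the estimators under the stated signal model, not robustness to every
artefact of real hardware.

Presets cover the phenotypes of interest: `healthy_synchronous` (lag 10°),
`mild_async` (45°), `paradoxical` (175°), and `anesthesia_deep` — shallow
irregular breathing under deep anaesthesia, modelled as amplitudes × 0.3,
rate-jitter CV 0.25, noise 0.15.

Cohorts derive one child seed per subject from the cohort seed, so subject
*i* is bit-reproducible independently of cohort size. Between-subject
variation (lag uniform on 5–15°, rate normal around 0.943 Hz with SD
0.08 Hz, RC amplitude normal around 1.13 with SD 0.06) is mild, matching a
healthy homogeneous group; per-subject physiologic metadata (weight, heart
rate, SpO₂, end-tidal CO₂) are drawn as Gaussians around the reference
cohort means with SD = √5 × SEM, and exist purely to exercise the metadata
pass-through — they are never claimed as physiological simulation.

## Cohort summaries and histograms

Summary tables compute per-subject means first (over valid windows), then
the cohort mean and SEM across subjects, with n = number of subjects. This
keeps a long recording from dominating a short one and matches how small
cohort tables are conventionally built; SEM for a single subject is reported
as `NA`. Histograms pool valid samples across subjects with fixed-width
bins anchored at the variable's floor (so LBI bins start exactly at 1.0);
bins and percent-in-range counts are left-closed, right-open. Default bin
widths are 2° for phase, 0.01 for LBI, 2 points for RC%. Windows are
right-aligned (causal), as a real-time instrument that only has past samples
would produce.

## Numerical choices and problem sizes

* arccos argument clamped to [−1, 1]; flat-window tolerance 10⁻⁹ of the
  window's signal scale; LBI denominator guard at 10⁻⁶ of the numerator.
* Analysis is vectorised across window positions (window matrices, row-wise
  range), and cross-checked in the test suite against naive per-window
  loops at 10⁻⁹.
* The test suite and acceptance script use 210 s recordings at 10 Hz
  (2100 samples, 2081 windows) for pipeline-scale checks, 30 s recordings
  for structural checks, and dense closed windows (2 periods at 400
  samples/period) for closed-form amplitude checks; a BPM recovery sweep
  runs ~100 seeded 210 s generations. Everything completes in well under a
  minute on one core.

## Known limitations

* Phase angles are unsigned; lead/lag direction is not recoverable from the
  cosine-similarity formula.
* Small true lags are inflated by the estimator noise floor (≈ 5° at 5%
  channel noise); comparisons between conditions should use matched noise
  levels.
* LBI explodes as lag approaches 180° with matched amplitudes (the tidal
  proxy vanishes); such windows are flagged invalid rather than reported.
* The rate estimator reports one whole-record value; rapidly varying rates
  are summarised, not tracked.
* Uncalibrated RIP: all quantities are ratios; absolute tidal volume is out
  of scope.
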
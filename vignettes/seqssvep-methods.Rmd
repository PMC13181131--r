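---
title: "Methods: quantifying high-frequency entrainment by sequential visual flicker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying high-frequency entrainment by sequential visual flicker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqssvep)
```

## The problem

Full-field visual flicker entrains cortex at the flicker frequency, but the
visual system behaves as a low-pass filter: entrainment weakens rapidly above
a few tens of Hz. Spatially organized *sequential* flicker sidesteps full-field
stimulation by splitting the screen into N sections (6, 7 or 14) and exposing
exactly one checkerboard section per screen refresh cycle. Each retinotopic
location then sees its own section re-exposed at the **repeat frequency**
`refresh_hz / N`, while neighboring locations are driven with a phase shift of
one frame period (`1000 / refresh_hz` ms; 6.94 ms at 144 Hz). The scientific
question this package's analysis chain addresses is whether such stimulation
enhances local field potential (LFP) power in a high-frequency (HF) band,
100–190 Hz, over a spatially defined span of recording channels — and how
strongly single units phase-lock to the repeat frequency.

The package provides four analysis stages behind one reproducible workflow:

1. **stimulus schedules** (`stimulus_spec()`, `build_sequential_schedule()`,
   `enumerate_stimulus_set()`) — frame-accurate timelines and their derived
   timing quantities;
2. **synthetic recordings** (`synthetic_config()`, `generate_lfp()`,
   `generate_spikes()`, …) — Neuropixels-like ground-truth data;
3. **LFP spectral chain** (`preprocess_lfp()`, `epoch_and_average()`,
   `stockwell_transform()`, `zscore_spectrum()`, `hf_amplitude()`,
   `hf_size()`);
4. **unit analysis and statistics** (`spike_phases()`, `ppc()`,
   `sta_receptive_field()`, `paired_wilcoxon()`, `rm_anova_two_way()`).

## Stimulus schedules and timing arithmetic

A sequential stimulus with N sections at refresh rate R shows section
`i mod N` on frame `i`; a 2 s trial at 144 Hz therefore holds
`floor(2 * 144) = 288` frames, and a full cycle of 14 sections lasts
`14 * (1000/144) = 97.2 ms`, i.e. a repeat frequency of `144/14 ≈ 10.29 Hz`.
Reported frequencies are rounded to one decimal with ties away from zero
(`round_half_up()`), giving the familiar 10.3/12.9/17.1 (14 sections),
20.6/25.7/34.3 (7) and 24/30/40 Hz (6) at 144/180/240 Hz. Across the
4 kinds × 3 refresh rates there are 12 sequential stimuli but only 9 distinct
repeat frequencies, because the two wedge kinds share N = 6.

Three choices here were genuinely open and are resolved as follows:

* A 2 s trial need not contain an integer number of section cycles (288
  frames / 14 sections leaves a partial cycle). Every trial restarts at
  section 0, so trials are identical — the natural choice when the analysis
  averages across trials.
* Checkerboard polarity alternates across sections starting black-leading;
  only the alternation itself matters downstream, so this is metadata.
* Whether the 7-section stimulus is "horizontal" or "vertical" bars is
  cosmetic; section orientation never enters the analysis and is kept only
  as the `kind` label.

Schedules are abstract (section index per frame), not rendered images; screen
gamma and warping are out of scope.

```{r timing}
sp <- stimulus_spec("vertical_bars", n_sections = 14, refresh_hz = 144)
c(repeat_hz = round_half_up(repeat_frequency(sp), 1),
  phase_shift_ms = round_half_up(section_phase_shift(sp), 2))
```

## The synthetic recording generator

No public recordings accompany the study design this package targets, so all
quantitative guarantees are established on synthetic data with known ground
truth. The generator emulates a Neuropixels-style probe: 384 LFP channels by
default at 2,500 Hz with 10 µm between sorted channels, and a trial structure
of 2 s stimulus alternating with 2 s gray, 50 trials per condition.

* **Background**: Gaussian noise synthesized in the frequency domain with
  power ∝ 1/f^α (α = 1 by default), random phases, deterministic per-bin
  magnitudes. This mimics the low-pass 1/f character of neural tissue; the
  deterministic magnitudes make band powers analytically known, which is what
  lets the injected HF gain be exact in expectation. Background RMS defaults
  to 30 µV.
* **SSVEP**: a harmonic series at the repeat frequency (fundamental 20 µV,
  amplitudes falling as 1/h, 3 harmonics by default), identical across trials
  and phase-shifted linearly across channels to mimic retinotopic
  progression. A parametric harmonic series is used because the evoked
  waveform's exact shape is immaterial to the HF question; harmonics stay
  below 100 Hz for every repeat frequency in the set with the default count.
* **HF injection**: on a contiguous channel span, during stimulus windows
  only, band-limited (100–190 Hz) Gaussian noise scaled so the band power is
  `hf_gain` times the background's band power. The background and injection
  use independent RNG streams, so changing the gain leaves the background
  realization untouched — the property behind the monotonicity tests. The
  generator injects the phenomenon; it does not arbitrate between candidate
  mechanisms for it.
* **Spikes**: inhomogeneous Poisson processes whose rate during stimulation
  follows a von Mises profile of the instantaneous phase at the repeat
  frequency, `rate(t) = r·[(1−m) + m·exp(κ cos 2π(φ−µ))/I₀(κ)]`. Phases are
  then von Mises(µ, κ) distributed, so the population pairwise phase
  consistency has the closed form `(I₁(κ)/I₀(κ))²` — the analytic anchor for
  the recovery tests. κ = 0 is homogeneous Poisson; κ = ∞ places one spike
  per cycle exactly at the preferred phase.
* **Waveforms**: biphasic templates with trough-to-peak durations drawn from
  0.20–0.41 ms (narrow) and 0.45–0.80 ms (broad), snapped to the 30 kHz
  sample grid — disjoint ranges clear of the 0.43 ms class boundary by
  ≥ 0.02 ms.
* **Receptive fields**: sparse-noise responses with Gaussian spatial tuning
  (σ = 12° by default) around known centers on the 36 × 22 grid of 15°
  squares, two targets per 100 ms frame.

What the generator does **not** emulate: traveling-wave dynamics, biophysical
membrane or synaptic mechanisms, spike-sorting artifacts (drift, collisions),
behavioral state, and any coupling between the spiking and LFP compartments.
Passing tests therefore demonstrate that the analysis chain measures what it
claims on data with known structure — not that real cortex behaves this way.

## The LFP spectral chain

The chain mirrors standard SSVEP practice. The raw 2.5 kHz LFP is band-passed
0.1–400 Hz (Butterworth order 3) and downsampled to 1,250 Hz by averaging
neighboring sample pairs. Filtering is zero-phase (forward–backward) so that
evoked latencies are unbiased; only the filter family and order are
prescribed, and forward–backward application is this package's choice. Trials
are epoched −500 ms…+2000 ms around onset and averaged; the Welch PSD of the
evoked average confirms the repeat-frequency peak.

Time-frequency analysis uses the **Stockwell (S-) transform**,

$$S_x(t, f) = \int_{-\infty}^{+\infty} x(\tau)\,|f|\,
e^{-\pi (t-\tau)^2 f^2} e^{-j 2\pi f \tau}\, d\tau,$$

a phase-corrected wavelet transform with a frequency-scaled Gaussian window:
absolutely referenced phase like the short-time Fourier transform, with
resolution that tightens in time as frequency grows. The implementation works
in the frequency domain (FFT of the signal, spectrum shift by each voice
frequency, multiplication by the sampled Gaussian `exp(−2π²m²/k²)`, inverse
FFT per voice); the f = 0 voice is defined as the signal mean, the standard
convention where the |f|-scaled Gaussian degenerates. The test suite holds
this implementation to ≤ 1e−8 relative error against a brute-force direct-sum
evaluation of the discrete definition.

The transform is applied to the **trial-averaged evoked LFP**, one transform
per channel. Averaging attenuates trial-incoherent power in the stimulus and
baseline windows equally, so the contrast below is preserved for induced
(non-phase-locked) HF power as well; for magnitude spectra an injected power
gain g appears as a contrast of `(√g − 1)/(√g + 1)`.

The **evoked-contrast spectrum** normalizes each (frequency, channel) pair:

$$z(f, ch) = \frac{A - B}{A + B}, \qquad
A = \overline{|S|}_{t \in [0, 2000]\,\mathrm{ms}}, \quad
B = \overline{|S|}_{t \in [-500, -5]\,\mathrm{ms}},$$

bounded in (−1, 1), zero when stimulus and baseline power match. The stimulus
term is time-averaged exactly like the baseline term, yielding one z per
(frequency, channel) — the 2-D form the downstream metrics consume. Bins with
zero total power get z = 0 and are counted.

Two cumulative metrics quantify HF enhancement on a fixed 1 Hz frequency grid
(fixed so the 15 a.u. threshold means the same thing in every run):

* **amplitude** `hf_amplitude()`: trapezoidal area under
  `|Σ_ch z(f, ch)|` over the band, channels taken from the configured
  visually driven range (never hard-coded; for synthetic data the known
  driven span);
* **size** `hf_size()`: the number of channels with
  `|Σ_f z(f, ch)| > 15 a.u.`, converted to µm via the 10 µm channel pitch,
  flagged as spatially large above 500 µm.

The band defaults to 100–190 Hz and is fully configurable (the size metric is
sometimes quoted over 90–180 Hz; both conventions are reachable through the
`band` argument, and every run's band is logged in the report). Whether the
amplitude's area is taken over the HF band only or the full axis was open;
band-limited is the default, and the full axis is available by passing a
wider `band`.

## Unit analysis

* **MUA**: common-median reference across channels, 0.3–3 kHz Butterworth
  order 2, threshold at 4 SD per channel, 1 ms dead time. On pure Gaussian
  noise the detection rate agrees with the Rice level-crossing rate computed
  from the designed filter response (a factor-2 property test).
* **Waveform classes**: trough-to-peak duration split at 0.43 ms, the
  boundary itself assigned to broad (the cut value alone is prescribed;
  non-strict on the broad side is this package's convention).
* **Quality**: inter-spike-interval violation fraction below 0.05% passes;
  isolation distance is sorter-feature-dependent and deliberately out of
  scope.
* **Responsiveness**: peak PSTH rate in 500–2000 ms must reach the baseline
  mean + 7.5 × baseline SD (−500…−5 ms). The "7.5 × SNR" rule does not define
  its SNR estimator; mean + 7.5 SD over baseline bins is the reading adopted
  here, with a zero-variance baseline degenerating to "exceeds the baseline
  mean".
* **Receptive fields**: spike-triggered average over the sparse-noise grid,
  upsampled by separable natural cubic splines (the 2-D cubic interpolation
  step), center at the interpolated peak, size as width at half peak, SNR as
  peak deviation over the SD of the outermost one-square ring (the gate is
  15 a.u.; the periphery-ring estimator is this package's choice).
  Retinotopic coverage is the maximal pairwise Euclidean distance between
  gated centers.
* **Phase locking**: per-spike phases are cycle fractions of a fixed
  sinusoid at the repeat frequency anchored at each trial onset, restricted
  to stimulus windows (the inter-trial interval carries no stimulus phase).
  Pairwise phase consistency is the mean over spike pairs of the cosine of
  their phase difference,
  $$\mathrm{PPC} = \frac{2}{N(N-1)} \sum_{j<k}
  \cos\theta_j \cos\theta_k + \sin\theta_j \sin\theta_k
  = \frac{|\sum_j e^{i\theta_j}|^2 - N}{N(N-1)},$$
  computed through the resultant-length identity (the O(N²) double loop is
  the test oracle). Phases are stored in cycles but converted to radians
  before the trigonometry — omitting that conversion silently corrupts the
  estimator. N is the spike count within one unit; units are averaged within
  recording, then recordings within mouse, so mice are the unit of
  inference. PPC is undefined below 2 spikes.

```{r ppc-demo}
sch <- build_sequential_schedule(
  stimulus_spec("wedge_top", 6, 144, n_trials = 20))
cfg <- synthetic_config(n_units = 1, baseline_rate_hz = 60,
                        locking_kappa = 1, rng_seed = 7)
spk <- generate_spikes(cfg, sch)
ph <- spike_phases(spk$spikes[[1]], repeat_frequency(sch$spec),
                   sch$events$onset_s, 2)
c(estimated = ppc(ph)$ppc,
  analytic = (besselI(1, 1) / besselI(1, 0))^2)
```

## Statistics

Per-mouse paired comparisons use the **exact Wilcoxon signed-rank test**:
zero differences are dropped (Wilcoxon's prescription), absolute differences
are midranked, and the exact two-sided p comes from the sign-flip null
distribution computed by convolution over the (doubled) ranks — which stays
exact under ties, where the usual exact algorithms fall back to a normal
approximation. With six same-direction pairs the minimal attainable p is
2/2⁶ = 0.03125. For n > 25 the normal approximation takes over.

The **two-way repeated-measures ANOVA** (e.g. waveform class × repeat
frequency) uses the classical within-subject error decomposition with one
aggregate value per mouse per cell, followed by pairwise paired t-tests per
factor with Bonferroni correction (raw p × number of comparisons, capped at
1). Sphericity corrections are intentionally omitted.

## Numerical choices and degenerate inputs

* Reported frequencies: one decimal, ties away from zero; raw rational
  values are kept internally and used in all computation.
* S-transform voices are the DFT frequency rows of the epoch; metrics
  interpolate z linearly onto the 1 Hz grid.
* `z` with zero denominator → 0, counted and warned.
* Degenerate spike sets: PPC absent below 2 spikes; ISI fraction 0 (flagged)
  below 2 spikes; coverage undefined below 2 gated fields.
* All generators draw from private, seed-derived RNG streams and restore the
  caller's RNG state; a fixed seed reproduces recordings bit-identically.

## Problem sizes

The validation suite establishes every guarantee at desk scale, chosen once:
S-transform oracle equality on 100 signals of length ≤ 128; PPC recovery
with 20 replicates of ~10,000 spikes at κ ∈ {0, 0.5, 1, 2} (24 Hz stimulus,
whose 2 s trials hold an integer cycle count, making the phase exposure
exactly uniform); end-to-end HF detection at 80 channels, 50 trials, a
50-channel injected span and gains {1, 2, 4, 8}, where detection must
overlap truth with Jaccard ≥ 0.8 at gain 4 and amplitude must be
non-decreasing in gain; STA recovery within one 15° grid square on 400 s of
sparse noise. The default workflow demo runs all 12 sequential conditions at
16 channels × 6 trials.

## Known limitations

* The evoked S-transform route quantifies induced HF power through the
  trial average; per-trial transforms would estimate it with lower variance
  at proportionally higher cost, and are not implemented.
* The generator's LFP and spike compartments are independent; tests cannot
  detect analysis errors that would only manifest under genuine spike-field
  coupling.
* The ANOVA assumes a balanced design and will refuse missing cells rather
  than impute them.
* Amplitude and size metrics inherit the (−1, 1) saturation of the
  evoked-contrast normalization: very strong enhancements compress toward
  the bound, so neither metric is linear in underlying power.
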
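---
title: "Methods: ERSP biomarkers of swallowing EEG and their synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERSP biomarkers of swallowing EEG and their synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

During a cued swallow, sensorimotor cortex desynchronizes: alpha (7–13 Hz)
and beta (13–30 Hz) band power over C3, Cz and C4 drops below its pre-cue
level for several seconds. The depth of that event-related
desynchronization (ERD), and its left–right balance, behave as biomarkers:
post-stroke patients show weakened beta ERD, dysphagic patients additionally
show weakened alpha/beta ERD at the left and midline electrodes and an
abnormally lateralized response. `swersp` turns multichannel EEG with swallow
cues into exactly those quantities and their group statistics.

Because clinical swallowing-EEG recordings are not publicly available, the
package treats a synthetic cohort generator as a first-class module: every
downstream stage is validated against signals whose ground truth is known
analytically.

## Signal model of the generator

Each trial of each channel is

x(t) = σ_bg·b(t) + a_α·(1 − d_α·w(t))·n_α(t) + a_β·(1 − d_β·w(t))·n_β(t)

* `b(t)`: 1/f ("pink") background, synthesized in the frequency domain —
  independent complex-normal coefficients on the FFT bins between 1 Hz and
  100 Hz with amplitude ∝ f^(−1/2) — and scaled to an exact unit variance.
  Default RMS σ_bg = 10 µV.
* `n_α, n_β`: narrowband Gaussian oscillators (band-limited white noise over
  6–14 Hz and 13–30 Hz, centers ≈ 10 and ≈ 21 Hz). Amplitude-modulated noise
  rather than sinusoids keeps realistic spectral width, so time–frequency
  estimates are not trivially sharp. The alpha-range oscillator deliberately
  overfills the 7–13 Hz *analysis* band: Morlet bandwidths at 3–8 cycles are
  1.5–2.5 Hz, so the analysis bins at the band edges would otherwise see
  mostly out-of-band, unsuppressed background, biasing the band-averaged
  suppression toward zero by ~0.6 dB. Default RMS 5 µV each.
* `w(t)`: raised-cosine suppression window — 0 outside
  [onset, offset] (defaults 250–4000 ms, matching ERD that outlasts the
  overt swallow), 1 on the plateau, cosine ramps of 400 ms. Its timing is
  jittered per trial (uniform ±100 ms, shared across channels, emulating
  swallow-timing variability).
* `d`: fractional amplitude suppression in [0, 1) per channel and band —
  the generative ERD depth.

Because amplitude scales by (1 − d·w), band *power* on the plateau relative
to baseline is analytically

ratio = (P_bg + (1 − d)²·P_osc) / (P_bg + P_osc),

with `P_osc` and `P_bg` the oscillator and background shares falling inside
the analysis band (for the f^(−1) power spectrum,
`P_bg = σ_bg²·ln(f2/f1)/ln(100)`; the flat-spectrum oscillator contributes
the band-overlap fraction of its total power).
`expected_plateau_db()` exposes `10·log10(ratio)`; the test suite checks
that a 200-trial, band-limited ensemble recovers it within 0.5 dB through
the full wavelet chain, and within 3 standard errors with an independent
Hilbert-envelope oracle.

### Group presets and their calibration

The printed group medians of the motivating clinical dataset cannot be
reproduced without its recordings, so preset depths were calibrated once —
against the package's own pipeline, then frozen — to reproduce the
*qualitative* findings and the approximate dB scale:

| preset      | alpha depth (C3/Cz/C4) | beta depth (C3/Cz/C4) |
|-------------|------------------------|-----------------------|
| healthy     | .30 / .30 / .30        | .42 / .42 / .42       |
| control     | .18 / .18 / .18        | .22 / .22 / .22       |
| dysphagic   | .06 / .05 / .18        | .06 / .05 / .18       |

Design reasoning:

* **Ordering.** Median ERI must order healthy < control < dysphagic (more
  negative = stronger ERD) in both bands at C3. This forces the control
  alpha depth strictly between the others; "alpha largely preserved after
  stroke" is expressed as a modest (0.30 → 0.18) reduction rather than
  equality, because exactly equal presets would make the ordering a coin
  flip at finite cohort sizes.
* **Alpha vs beta separability.** The healthy-vs-control contrast must
  separate in beta but not in alpha. This is achieved through between-subject
  variability, not through the means: the subject-level depth SD is 0.30 in
  alpha (inter-individual alpha power is famously variable) against 0.07 in
  beta. At n = 21 vs 32 the alpha contrast then stays non-significant under
  the Mann–Whitney test while the beta contrast rejects decisively.
* **Lateralization.** The dysphagic preset suppresses C3 (left) much less
  than C4, producing |LI| medians near 0.45 against ≈ 0.1 in the symmetric
  groups. The subject-level depth factor is shared across channels within a
  band (a band-reactivity trait), with only a small independent per-channel
  jitter (SD 0.02) — otherwise channel-independent variability would inflate
  |LI| in the symmetric groups too.
* **Stratified heterogeneity.** Subject depth factors sit on permuted normal
  quantiles (`qnorm((i−0.5)/n)`) rather than independent draws, so a finite
  cohort represents its target distribution without Monte-Carlo drift and
  the ordering properties above are properties of the presets, not of a
  lucky seed. The cost is that adding a subject re-grids the group's
  subject effects; per-subject *signal* streams remain independently seeded
  by a counter, so they are unaffected.

One known non-reproduction: with alpha variability large enough to keep
healthy-vs-control non-significant, the dysphagic-vs-control alpha contrast
(a location shift of similar size) generally does not reach significance
either, although the clinical data reports it as significant. Location-shift
Gaussian presets cannot satisfy both; the package prioritizes the contrasts
checked by the test suite and records the limitation here.

## Preprocessing

1. **Resampling** to 512 Hz by the Fourier method (spectral truncation,
   inherently anti-aliasing). The polyphase resampler available in the R
   ecosystem introduced a fractional-sample delay and percent-level
   amplitude error, so the FFT method is implemented in the package and
   tested against analytically sampled sines (≤ 1% amplitude error away
   from edges).
2. **Band-limiting 7–35 Hz.** 4th-order Butterworth high- and low-pass,
   applied zero-phase: the squared magnitude response
   `1/(1+(hp/f)^8) · 1/(1+(f/lp)^8)` multiplies the FFT of each channel.
   This is the forward–backward ("filtfilt") response applied exactly, with
   zero group delay — ERD latencies are not shifted — and it batches all
   channels of a trial in one transform. Measured attenuation: ≈ 0.0002 at
   1 Hz, ≈ 0.989 at 20 Hz, ≈ 0.055 at 50 Hz (mains); these measured values
   are frozen into the tests. The 7 Hz high-pass does bite into the lower
   alpha band, but baseline corrections are per-frequency ratios, so any
   linear time-invariant filtering cancels exactly in the ERSP.
3. **Artifact stage.** A channel whose MAD-based robust amplitude exceeds
   `reject_sd` (default 10) times the median across channels is rejected and
   rebuilt by inverse-distance-weighted interpolation of its 4 nearest
   neighbours on a 2-D projected 10–20 layout. This is a deliberate,
   documented simplification standing where subspace reconstruction and
   ICA-based classification would sit in a clinical pipeline; it is
   interface-compatible with such replacements. More than 25% rejected
   channels marks the recording unusable.
4. **Epoching** −1000…5000 ms around the cue, half-open at the right edge so
   every trial has an identical sample count; events whose span crosses a
   recording edge are dropped with a warning.
5. **Common average reference**, applied after epoching; idempotent, channel
   means are zero at every sample thereafter.
6. **Inclusion**: subjects with fewer than 20 valid trials are excluded, and
   every exclusion, rejection and LI degeneracy is written to the run log —
   cohort attrition stays auditable.

## Time–frequency decomposition

Complex Morlet wavelets on a 7–30 Hz grid (default 0.5 Hz spacing, 47 bins),
with cycle count rising linearly from 3 at 7 Hz to 20 at 30 Hz:
`cycles(f) = 3 + 17·(f − 7)/23`. Wavelets are unit-energy, truncated at ±4
temporal SDs; convolution runs via FFT and is verified against direct
time-domain convolution at rtol 1e−6. Cells whose wavelet support crosses
the epoch boundary are **masked**, not zero-filled, and all band/window
integrals skip masked cells — this keeps the −1000…0 ms baseline free of
edge bias. The output time grid is decimated to 32 Hz (187 points per epoch
at 512 Hz), which contains 0, 500 and 2000 ms exactly.

Baseline correction is two-stage, both stages as divisions per frequency:

1. each trial's power map is divided by its own full-epoch mean (damps
   outlier trials before averaging);
2. the trial average is divided by its pre-stimulus (−1000…0 ms) mean and
   transformed by `10·log10`.

The dB convention is a *power* ratio (10·log10). Because both corrections
are ratios, the ERSP is exactly invariant to per-trial amplitude scaling;
the tests assert invariance at 1e−9.

## Biomarkers

ERO, ERI and LI are discrete trapezoidal averages on the native grid, with
a fine-grid Riemann oracle guarding the integration. Conventions worth
stating:

* the printed integral limits of the ERI definition appear in descending
  order in the source material; they are read as ordinary ascending-limit
  integration, since a doubly reversed sign would contradict the stated
  "negative = desynchronization" convention;
* the 13 Hz grid bin belongs to both bands, as the band edges are printed;
* LI is undefined when |ERI_C3 + ERI_C4| < ε (default 1e−3 dB); such
  subjects are flagged, reported, and excluded from LI statistics rather
  than producing unbounded values;
* time-averaging the ERO trace over the window equals the double integral
  by construction (Fubini on the grid), asserted at 1e−9.

## Statistics

The battery mirrors standard nonparametric practice for non-normal,
heteroscedastic biomarkers: Lilliefors and Levene screens (classic
mean-centered Levene by default, Brown–Forsythe optional), Kruskal–Wallis
omnibus per channel × band, pairwise Mann–Whitney with Cliff's δ, paired
C3-vs-C4 Wilcoxon signed-rank with rank-biserial r, chi-square without
continuity correction for demographic tables. All tests are two-sided at
α = 0.05; no multiplicity correction is applied by default (the exploratory
convention of the motivating study), with Holm and Benjamini–Hochberg behind
a flag. Rank tests use average ranks with tie-corrected variances; zero
paired differences are dropped (Wilcoxon's original treatment). δ is
oriented so that a positive value means the first sample is stochastically
larger; every report row carries its group labels so orientation is never
ambiguous. Exact small-sample p-values are validated against exhaustive
enumeration (all rank assignments / sign patterns) for n ≤ 8 at 1e−12.

Cliff's δ and rank-biserial r are computed from their definitions
(`(#{x>y} − #{x<y})/(n_x n_y)` and `(W⁺ − W⁻)/(W⁺ + W⁻)`); the underlying
p-values come from R's `wilcox.test`, `kruskal.test` and `chisq.test`, plus
`nortest::lillie.test` and `car::leveneTest` for the screens. The Lilliefors
implementation requires n ≥ 5, so the normality screen is skipped (not
failed) for smaller groups.

## Problem sizes used by the test suite

Chosen as the package's own validation design:

* parameter recovery: 200 trials, one channel, 512 Hz;
* full cohort reproduction: 21/32/50 subjects, 30 trials each (inside the
  20–40 range of the protocol, near the reported mean swallow counts),
  32 channels at 512 Hz, fixed seed — about 3 minutes;
* null calibration: 200 replicates of two cohorts drawn from the *same*
  preset (6 subjects × 6 trials each, 256 Hz, 2 Hz frequency grid), beta
  ERI at the three mutually independent sensorimotor channels, 600
  Mann–Whitney tests in total; the rejection rate must sit inside the
  binomial 99% interval around the nominal 0.05.

Generating directly at 512 Hz (rather than 2 kHz followed by downsampling)
is a validation-design choice; the resampler is tested separately and the
2 kHz path is exercised by the EDF round-trip tests.

## What passing tests do and do not show

The generator emulates stationary 1/f background, band-limited oscillators,
amplitude suppression with realistic timing jitter, subject heterogeneity
and hemispheric asymmetry. It does **not** emulate ocular/muscular artifact
topographies, volume-conducted channel correlations, non-stationary
background, or any relation between ERD and clinical covariates. Passing
tests therefore demonstrate that the pipeline measures what it claims to
measure on signals with known ground truth — not that the clinical effect
sizes themselves are reproduced. EDF files written by the package quantize
to 16 bits over a per-channel range; round-trip error is bounded by
range/2^16 per sample and tested.

## Known limitations

* The artifact stage is a stand-in; real muscle/ocular artifacts need the
  subspace or ICA methods it replaces.
* Only EDF is supported for interchange; events travel in a CSV sidecar.
* The EDF writer requires whole-second recordings (1 s data records).
* No per-trial ERI variants, no inter-trial coherence, no significance
  masking of the ERSP maps themselves.
* FFT-based filtering and resampling assume approximate periodicity; edge
  neighbourhoods of continuous recordings differ slightly from per-epoch
  processing (tested to agree within 10% RMS away from boundaries).
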
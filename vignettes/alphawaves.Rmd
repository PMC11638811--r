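---
title: "Quantifying directional alpha traveling waves: model, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying directional alpha traveling waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(alphawaves)
```

## The measurement model

A cortical traveling wave, at the sensor level, is an oscillation whose
phase advances monotonically along a line of electrodes. `alphawaves`
measures it as follows.

**Axes and interpolation.** Three posterior-to-anterior electrode axes
(midline, left, right) are defined per montage; see
`axis_set()` and `inst/extdata/axes.yaml`. Each axis is linearly
interpolated to seven virtual channels so every axis has the same spatial
sampling. The interpolation abscissa is channel *rank* along the axis
(equally spaced ranks rescaled to [0, 1]), not 3-D scalp distance. Rank
spacing is the reproducible choice when only the channel sequence is
specified; it makes the map exact on rank-affine profiles and the identity
on seven-channel axes, at the cost of ignoring true inter-electrode
distances — a deliberate simplification shared with the measurement
tradition this package follows. One montage's printed midline listing
contains a repeated label; the shipped default uses the corrected reading
(`POz, Pz, Cz, Fz`) and the literal listing remains available as the
`midline_literal` variant for transparency, without asserting which was
intended.

**Windowing.** A 500 ms window slides in 100 ms steps (`window_spec()`),
starting at the epoch start; only fully contained windows are used, each
labelled by its center. With 500 ms windows the temporal resolution of the
spectrum is 2 Hz. Window length and step must be whole numbers of samples
at the recording's sampling rate.

**Directional decomposition.** Each 7 × *n* segment is Fourier-transformed
in 2-D (implemented as the temporal DFT of each channel followed by a
7-point spatial DFT of each temporal column — algebraically identical to
the 2-D FFT and faster at the few bins needed). In the zero-centered power
spectrum the horizontal midline (zero spatial frequency) carries
standing-wave power and is excluded; temporal DC is excluded too. For a
temporal bin *f*, forward power is the maximum over the three negative
spatial-frequency bins of the column at +*f*, backward power the maximum
over the three positive bins. Conjugate symmetry makes the opposite
quadrant pair redundant. The sign convention is pinned operationally by a
permanent test: a generated posterior-leading wave must measure as
forward. No detrending, tapering or zero-padding is applied by default; a
Hann taper is available as `compute_wave_power(taper = TRUE)` (applied
identically to numerator and denominator) and off by default.

**Normalization.** Raw directional power is divided by `FFT_f`, the 1-D
temporal power at the same bin averaged over the segment's seven channels,
and expressed in dB:

\[ \mathrm{FW_{dB}} = 10\log_{10}\!\frac{\mathrm{FW}_{f,\max}}{\mathrm{FFT}_f},
\qquad
\mathrm{BW_{dB}} = 10\log_{10}\!\frac{\mathrm{BW}_{f,\max}}{\mathrm{FFT}_f}. \]

Both numerator and denominator use the same unnormalized-DFT power
convention and the same transform length, so the 0 dB baseline ("as much
directional power as average temporal power") is meaningful, and the
measure is exactly invariant to amplitude rescaling of the segment. Two
consequences worth remembering: the denominator is shared by the two
directions, so injecting power in one direction *lowers* the other
direction's dB value; and under pure spatially incoherent noise both
directions sit well above 0 dB (a maximum over three independent bins
exceeds their mean) — the meaningful quantities are always contrasts:
forward vs backward, contra vs ipsi, between conditions.

**Aggregation.** Per-bin dB values are averaged over closed frequency
bands on bin centers (alpha 8–12 Hz → bins {8, 10, 12}; theta 4–7 → {4, 6};
beta 13–30 → {14 … 30}), then over sliding windows whose *centers* fall in
the closed retention interval (0.2–1.2 s for the `ds1` template, 0.25–1.55 s
for `ds2`), then over trials by mean (default) or median
(`aggregate_trials()`, the robustness variant). Closed intervals on bin
and window centers are used everywhere because they are the least
ambiguous anchors; degenerate bins with exactly zero temporal power (only
possible in noiseless synthetic input) propagate `NaN` rather than an
arbitrary value, and `normalize_db()` refuses an all-zero segment.

**Lateralization.** `assign_roles()` relabels the hemispheric axes
contralateral/ipsilateral to the items of interest; items presented in the
left hemifield make the right axis contralateral. In designs where either
targets or distractors are the lateral cluster, requesting roles relative
to the other item type flips the mapping, because those items occupy the
opposite hemifield.

## The synthetic-data generator

`simulate_dataset()` emulates the two study layouts the analysis is built
for: `ds1` (1000 Hz, epochs −800…1600 ms, distractor load 2/4/6 ×
lateralized targets/distractors) and `ds2` (250 Hz, epochs −1400…1548 ms,
set size 1/3/6, lateralized targets). Channels are generated *directly on
the analysis axes* — no volume-conduction forward model — because the
measure operates on axis stacks and the artifact-vs-veridical debate about
sensor-level waves is outside this package's scope. Each trial is 1/f^β
background noise (β = 1 by default, per-channel SD 1, independent across
channels) plus the plane-wave components of the design's *effect map*:
amplitude, direction, temporal frequency (10 Hz default), spatial phase
gradient, time interval and target axis, optionally conditional on load,
set size or side, with `contra`/`ipsi` resolved per trial. Initial phase
is drawn uniformly per trial (the measure is phase-gradient based, and
random phase avoids spurious across-trial coherence). A log-normal
per-participant factor (`participant_sd`) scales all injected amplitudes
to create between-participant heterogeneity.

Two conventions matter when interpreting recovery results. First,
effect-map phase steps are specified per *interpolated* channel step, so a
given gradient is comparable across axes with different electrode counts.
Second, a gradient of 2π/7 (one spatial cycle across the array) lands
exactly on a spatial bin and measures almost noiselessly, while π/7 (half
a cycle) sits between bins and leaks into both quadrants — forward still
dominates clearly (raw ratio ≈ 7.9), but with a compressed dynamic range.
Validation simulations therefore use π/7 where the point is direction
recovery under leakage, and 2π/7 where the point is a graded,
condition-dependent effect.

The generator does **not** emulate volume conduction and reference
effects, eye/muscle artifacts, non-sinusoidal or burst-like alpha,
inter-channel noise correlations, or behaviour beyond the hit/false-alarm
rates needed for Cowan's K. Passing recovery tests on these simulations
shows the measurement and inference chain is correct and calibrated under
its own assumptions; it does not by itself certify conclusions on real
recordings.

## The inference layer

All tests are Bayesian, mirroring the reporting conventions of the studies
this pipeline serves.

* `jzs_ttest_bf()` — JZS t test: Cauchy(0, r = √2/2) prior on the
  standardized effect, marginal likelihood integrated by deterministic
  quadrature over the inverse-gamma mixing parameter. Validated against an
  independent noncentral-t/Cauchy quadrature to 0.5% (in practice ~1e−12).
* `rm_anova_bf()` — repeated-measures ANOVA inclusion BFs. The model space
  contains every subset of main effects and interactions respecting
  marginality, each with a participant intercept; equal prior mass over
  models; matched-models inclusion BFs (models containing the effect but
  none of its higher-order interactions, versus the same models without
  it). Three per-model marginal-likelihood methods: `"bic"` (Schwarz
  approximation on the participant-projected residual dimension; fast
  default), `"quadrature"` (deterministic integration of the Zellner–Siow
  g prior, r = 0.5), and `"mc"` (Monte Carlo over the same prior, with a
  reported relative error and seed). The BIC approximation corresponds to
  a unit-information prior and is systematically conservative relative to
  the JZS convention; the package's reported validation analyses use
  `"quadrature"`, which matches the scale of conventional default-prior
  ANOVA BFs while remaining fully deterministic. Since the original
  analyses' prior settings are not reproducible, agreement is expected at
  the level of qualitative evidence categories, not exact BF magnitudes.
* `posthoc_pairwise_bf()` — uncorrected paired JZS comparisons between two
  factor levels, flagged as post hoc. The degenerate case where every
  participant shows exactly zero difference is scored at t = 0 (evidence
  for the null) rather than rejected.
* `bf_linear_regression()` — single-predictor JZS regression
  (Zellner–Siow prior, r = √2/4) for the capacity analysis, with
  `fit_slopes()` extracting per-participant wave-power-vs-load slopes; a
  numerically perfect fit returns `Inf`.
* `timecourse_bf()` — the paired contra-vs-ipsi JZS test at every window
  center, annotated at the conventional BF10 > 3 threshold. No
  multiple-comparison correction is applied, matching field practice; the
  threshold is descriptive, not a gate. Participant-level values entering
  the per-timepoint tests are trial means per participant per window.

## Validation design and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`) and
`scripts/acceptance.R` run the full chain at these scales, chosen to be
informative while keeping a laptop-scale runtime:

* **Direction recovery** — 200 trials, 10 Hz plane wave (π/7 gradient,
  amplitude 1) in 1/f noise (SD 1, a moderate ~0 dB broadband SNR);
  forward-minus-backward alpha dB must exceed 1 dB (measured ≈ 2.7 dB),
  mirrored for backward waves.
* **Exactness** — channel-flip antisymmetry on 100 random segments
  (machine precision) and equality with a brute-force double-loop DFT on
  50 random 7 × 32 segments (relative error < 1e−10).
* **Null calibration** — 1000 spatially incoherent white-noise segments:
  |mean FW_dB − mean BW_dB| < 0.1 dB across all temporal bins.
* **Load-effect recovery** — 30 participants × loads {2, 4, 6} × 3
  trials/condition on the midline axis; forward amplitudes 0.1/0.2/0.3
  with the 2π/7 gradient and `participant_sd = 0.1`, calibrated from the
  measured amplitude-response curve to a participant-level effect of
  d ≈ 0.8–1 per load step. The load inclusion BF (quadrature method) must
  exceed 10 in ≥ 90% of 100 seeded replicates; under a null effect map the
  median BF_incl must fall below 1.
* **Timecourse localization** — 12 participants, a contralateral forward
  wave (amplitude 0.35) confined to 0.6–1.2 s: windows with BF10 > 3 must
  concentrate in windows overlapping that interval; null simulations (at
  the participant-level analysis unit, plus full synthetic-EEG nulls) must
  keep the per-window BF10 > 3 rate at or below 0.10 (measured ≈ 0.015).
* **Determinism** — the bundled demo configuration run twice writes
  byte-identical result tables; simulated datasets are bit-reproducible
  from their seed.

## Known limitations

The measure is sensor-level by construction and cannot distinguish true
cortical propagation from superpositions that mimic it; that debate is out
of scope here. Rank-based interpolation ignores real electrode geometry.
The 2 Hz bin grid makes the alpha band a three-bin average; narrow-band
effects between bins dilute. The maximum-over-three-spatial-bins statistic
is biased upward under noise (hence the contrast-based interpretation).
BIC-based inclusion BFs understate evidence relative to g-prior methods;
choose the method deliberately and report it. Reading epoched data is
currently limited to the package's own plain-text container
(`write_epochs()`/`read_epochs()`), which round-trips bit-exactly and is
easy to produce from any other toolchain.
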
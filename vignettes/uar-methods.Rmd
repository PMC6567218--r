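---
title: "Unsupervised EEG artefact removal: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised EEG artefact removal: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Scalp EEG mixes cortical activity with much larger signals of non-neural
origin: eye blinks and eye movements (slow, frontal, hundreds of
microvolts), muscle bursts (broadband 20–60 Hz), and equipment
interference. Most ICA-based cleaning pipelines decompose the *whole*
recording, ask a human or a trained classifier to label bad components,
and reconstruct without them — which requires supervision and alters the
entire signal. `uareeg` implements an alternative that is unsupervised end
to end and touches only the neighbourhood of each artefact:

1. **Detect** candidate artefact portions from cheap sliding-window
   features.
2. **Decompose** a local window around each detected portion with FastICA.
3. **Subtract** component projections, per electrode, in order of artefact
   influence, until a statistical test says the portion looks like clean
   background again.

Everything outside the filtered portions is preserved bit-exactly.

## Detection: AR(2) features and centroid distances

The recording (channels × samples, microvolts) is segmented into sliding
windows of `Lw` samples advanced by `d` samples. Each window is summarised
by the two coefficients of a second-order autoregression per channel,
concatenated across channels into one feature vector per interval. AR
coefficients are scale- and location-invariant, so these features transfer
across subjects, amplifier gains and reference choices; windows with
artefacts sit far from the bulk in feature space.

Detection scores each interval by the Euclidean distance of its feature
vector to the centroid (arithmetic mean) of all interval vectors. The bulk
of clean intervals forms a compact mass whose histogram is well described
by a Generalized Extreme Value distribution; artefact intervals populate
the extreme right tail. Two thresholds describe that tail:

* `T1` — the onset of the extreme tail. The default is the fixed value
  `T1 = 1.33`, which is an empirically portable operating point for
  64-channel montages (the distance scale is set by AR estimator
  variability, not by signal amplitude). A `gev_quantile` mode estimates
  the tail onset from a fitted GEV instead; since "onset of the tail" has
  no canonical definition, the quantile probability (default 0.90) is an
  explicit, documented choice and the mode is opt-in.
* `T2` — the balance point of the tail: the median of all distances at or
  above `T1`, so that as many intervals lie beyond `T2` as inside
  `[T1, T2)`. `T2` is computed for reporting; detection always runs at
  `T = T1`, deliberately over-inclusive. Portions between `T1` and `T2`
  often carry no artefact — the downstream stopping test is what decides
  whether anything is actually removed, so false positives cost processing
  time but not signal fidelity.

Runs of consecutive intervals with distance `≥ T` become detections; a run
maps to the union of its member windows (not their centres), biasing
toward wider spans. With many channels the Euclidean distance dilutes
focal artefacts; `detect_grouped()` runs detection on small channel groups
and fuses the per-group spans by plain union.

**Distances are computed on raw AR coefficients**, not standardised ones:
the two AR(2) coefficients share a natural scale, and standardising by
per-column spread would let a single noisy channel reweight the geometry.

## Geometry around a detection

Each detected span `AT` is widened by margins `AT1` (1 s) before and `AT2`
(1 s) after into `ART = AT1 + AT + AT2`, the portion actually filtered —
the margins absorb late/early detection of weak artefact onsets. If the
next detection starts inside the current `AT2`, the current `ART` is cut
at that start and the next portion's `AT1` begins there (possibly with
zero length), so portions never overlap. `ICA_P` is the trailing window of
`icap_seconds` (default 26 s) ending where `ART` ends, clipped at the
recording start and always containing `ART`; no data is fabricated for
early artefacts — simulated recordings carry a 30 s clean prefix for the
same reason. The reference `REF` has the same length as `ART` and
immediately precedes it whenever that history is clean. The exact
placement of `REF` relative to `ICA_P` is underdetermined in the source
material; "the most recent fully clean span ending at or before `ART`" is
the reading implemented, and when no full-length clean span exists the
longest clean run ending at `ART` (at least `Lw` samples) is used and
flagged short. A portion with no usable history at all is skipped with a
warning rather than filtered against an arbitrary baseline.

## Decomposition and ordering

FastICA on the `ICA_P` window estimates the model `M = A × S`: as many
independent components as channels, sources scaled to unit variance, the
mixing matrix carrying the amplitudes. Implementation choices: whitening
by PCA retaining all dimensions, symmetric (parallel) fixed-point
iteration with the cube nonlinearity, tolerance `1e-4`, at most 500
iterations, and up to 5 seeded restarts on non-convergence keeping the
best attempt. Channel means over `ICA_P` are stored separately and never
subtracted from the recording; projections `A[e, c] · S[c, ·]` are
zero-mean, so removing them cannot shift the local baseline. The
reconstruction identity `means + A S = window` is enforced to near machine
precision on every decomposition.

Components are ranked by how strongly they express in the artefact
portion: for each component, the electrode projection with the largest
peak absolute value over `ART` (default, `max_abs`) or the largest
variance (`max_var`). `max_abs` is the default because a single number —
the peak — is what distinguishes transient artefacts best; ties break by
component index so the ordering is a deterministic permutation.

## The stopping rule and per-electrode filtering

The baseline question "does this portion still contain artefact?" is
answered by a two-sample F-test of equal variances between the electrode's
`REF` samples and the current residual of its `ART` samples:
`F = var(REF)/var(N_ART)`, two-sided p-value `2·min(P(F' ≤ F), P(F' ≥ F))`
with `(n_REF − 1, n_ART − 1)` degrees of freedom, rejection (`R1`) at
`alpha = 0.01`. Both tails are computed directly from the F distribution
function — the textbook `1 − CDF` form loses all precision for the
p-values around `1e-12` that strong artefacts produce. A zero-variance
residual is treated as a degenerate rejection (`F = ∞`).

Per electrode, the loop subtracts the ordered projections one at a time.
After each subtraction it stops when **both** the reference variance
exceeds the residual variance **and** the test rejects — i.e. the residual
is now significantly *quieter* than clean background, meaning the last
subtractions removed genuine signal. On stopping, if the immediately
preceding iterations formed a consecutive run of non-rejections (`R0`),
the residual rolls back to the state saved at the first `R0` of that run:
that state already matched the reference variance, and everything after it
was overshoot. Without such a plateau the final residual stands. If all
components are exhausted without a stop, the most recent plateau state is
returned when one exists; otherwise the portion is returned unchanged —
the typical outcome for false-positive detections, which is precisely what
makes the over-inclusive `T = T1` detection safe. The simultaneous case
(stop condition and `R0` bookkeeping in the same iteration) cannot arise,
since stopping requires a rejection; the loop nevertheless follows the
written iteration order exactly, and the test suite checks it against a
literal step-through of that pseudocode.

Portions are processed in detection order on the progressively filtered
signal: each `ICA_P` is decomposed on the *current* data, and filtered
spans immediately count as clean history for later reference selection,
which is what supports closely spaced artefacts. Per-electrode filtering
depends only on that electrode's samples and the shared decomposition.

## Synthetic contaminated EEG

The generator exists so every stage is testable without clinical data. It
emulates, not replicates, the reference conditions: 64 channels, 256 Hz,
60 s of contaminated signal behind a 30 s clean prefix, six events.

* **Background**: a few shared 1/f-weighted latent sources mixed smoothly
  across channels, per-channel 1/f noise, a broadband white floor at 35%
  of channel RMS, and a shared 10 Hz alpha rhythm; channel RMS drawn from
  12–25 µV. The white floor matters: real EEG spectra flatten into a
  sensor/muscle-tone noise floor at high frequencies, and without it pure
  1/f noise has so high a lag-1 autocorrelation that smooth ocular
  transients barely move the AR(2) coefficients.
* **Templates**: blinks are raised-cosine pulses (0.35–0.4 s, 120–140 µV
  peak); eye movements are smoothed rectangular deflections (1–1.2 s,
  90–100 µV); EMG bursts are 20–60 Hz band-passed white noise (2–2.5 s,
  45–50 µV RMS), edge-tapered. Real ocular artefact shapes from clinical
  recordings are not available; these are synthetic stand-ins with the
  right time scales and amplitudes (peak ≥ 3× background RMS).
* **Topographies**: exponential decay with channel-index distance from a
  focus channel (decay 0.015/channel for ocular events — broad, as volume
  conduction spreads ocular potentials widely — and 0.03 for EMG, more
  focal). Channel index stands in for scalp geometry; a user-supplied
  weight matrix can replace it.

Additivity is exact (`contaminated = clean + injected artefacts`), events
never overlap, and everything is deterministic given the scenario seed.
What passing tests on this generator do **not** show: performance on real
EEG with non-stationary background, overlapping artefact mixtures,
electrode pops, or genuine cortical sources in the components.

## Numerical and policy choices

* Coordinates are 0-based half-open sample spans; seconds convert by
  `floor(t·fs)`.
* AR(2) estimation uses Burg's method on mean-centred windows (stable on
  155-sample windows, never produces explosive models); Yule–Walker from
  sample autocovariances serves as the independent oracle in tests. No
  detrending beyond mean removal is applied — the windows are short enough
  that a linear trend reads as genuine low-frequency content.
* Zero-variance windows map to AR coefficients `(0, 0)` so flat channels
  do not abort detection; duplicated (rank-deficient) channels abort the
  ICA with a clear error instead.
* GEV fitting is maximum likelihood via Nelder–Mead on
  (location, log scale, shape), moment-based Gumbel starting values.
* `min_run = 1`: a single above-threshold interval is a valid detection.
* Detection defaults (`Lw = 155`, `d = 32`, `T = 1.33`) target 64-channel,
  256 Hz montages. The distance threshold scales with the number of
  channels (the bulk distance grows like the square root of the feature
  dimension), so for much smaller montages either rescale `T` or use the
  GEV quantile mode; the test suite's small fixtures rely on the strongest
  (EMG) events precisely because they clear the 64-channel threshold even
  at 16 channels.

## Problem sizes used by the test suite

Deterministic fixtures keep the suite fast: the per-electrode loop is
verified on hand-built 3-component decompositions; preservation runs on
ten 16-channel, 45 s simulated recordings; end-to-end recovery runs the
full 64-channel, 90 s reference scenario across 5 seeds; the ICA-window
study compares 12 s against 26 s windows on a 64-channel, 70 s scenario
across 3 seeds, asserting that the longer window achieves at most the
whole-channel MSE of the shorter one. These sizes are the package's
chosen desk-scale study conditions, not tuning knobs.

## Known limitations

* The fixed `T1` is montage-dependent; no automatic rescaling with channel
  count is attempted.
* FastICA assumes at most as many active sources as channels and
  non-Gaussian sources; a purely Gaussian stationary artefact would not
  separate (EMG bursts separate because they are nonstationary within the
  ICA window).
* The F-test assumes roughly normal, independent samples; EEG samples are
  autocorrelated, so the effective significance level on real data departs
  from the nominal 1% (the calibration target holds for white Gaussian
  inputs).
* Offline processing only: the chunk geometry mirrors what an online
  implementation would need, but no streaming scheduler is provided.
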
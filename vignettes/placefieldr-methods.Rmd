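---
title: "Methods: models, parameters and design choices in placefieldr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in placefieldr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
analysis chain from raw two-photon fluorescence to place-field statistics on
circular virtual-reality (VR) tracks, the assumptions each stage makes, the
parameters that matter, what the synthetic-session generator does and does
not emulate, and the choices we made where the analysis design was genuinely
open.

## The pipeline and its assumptions

The unit of analysis is a *session*: a head-fixed mouse runs laps on a
circular track (one lap = one traversal, boundaries at the tunnel-cue
center), is teleported at a lap boundary into a second, visually distinct
environment, and keeps running. Synchronized streams are per-frame time,
position, speed, licks and reward deliveries, plus per-cell somatic
fluorescence, neuropil fluorescence and deconvolved calcium events (DCEs:
frame + amplitude). Deconvolution itself is out of scope — event trains are
inputs.

**Preprocessing.** Somatic traces are neuropil-corrected
(`F = F_soma − 0.7 F_neuropil`) and converted to ΔF/F against a running
baseline: the minimum, over a trailing 60 s window, of the 5 s trailing
running average. Both windows are truncated to the available history at the
trace start (no padding), so the first frames use shorter windows rather
than fabricated samples. Whether the running average should be trailing or
centered is not determined by the procedure's description; we implement
trailing (causal) windows throughout, which also keeps the baseline
deployable online. ΔF/F is undefined where the baseline is ≤ 0; such frames
are flagged and carry `NA`.

For field size/COM estimation the 50% lowest-amplitude DCEs are removed
per cell; ties at the median are *retained* (deterministic: a train of equal
amplitudes passes unchanged). Spatial information and decoding use all
amplitudes.

**Binning.** Signals are averaged into a laps × 100 matrix of
occupancy-normalized rates: frames slower than 1 cm/s are excluded
(stops/backing up), the per-(lap, bin) signal sum is divided by the seconds
spent there, and zero-occupancy entries are `NA`. Bin 1 and bin 100 are
spatially adjacent; every smoothing, boundary scan, distance and COM
computation in the package respects that circular topology. Bins are
indexed 1-based (R convention); all physical quantities are in cm and
seconds, so the indexing convention never leaks into results.

**Smoothing.** All map smoothing uses a raised-cosine (Hanning-family)
kernel of the stated length with *nonzero endpoints*, renormalized to unit
sum — for a 2-bin window this degenerates to `c(0.5, 0.5)`; textbook Hann
endpoints are zero and would waste taps. Convolution is circular. `NA` bins
are imputed by circular linear interpolation before smoothing and come back
as values, so one empty bin does not poison a map.

## Place-field detection

The three-step criterion on a cell's lap × bin ΔF/F matrix:

1. Smooth the lap average (5-bin window); local strict maxima above
   3.5 × the trace's 50th percentile are candidates (plateaus contribute
   their leftmost bin). Scanning outward from a peak, the boundary is the
   *nearer* of (a) the first bin below the 50th percentile and (b) the
   first local trough beyond which the trace reaches below 70% of the peak.
   The detected field is the span *strictly inside* the two stopping bins:
   those bins are by definition already below threshold (or past the
   trough), and counting them would inflate every extent by two bins.
   Candidates whose boundary spans overlap by ≥ 1 bin are merged, keeping
   the higher peak.
2. The per-lap in-boundary peak must exceed 3.5 × baseline — baseline being
   the 50th minus the 5th percentile of all bins and laps — on at least
   max(⌈laps/3⌉, 5) laps. The first such lap is the field's *onset lap*.
3. Fields narrower than 20 cm or wider than 150 cm are discarded. The
   per-cell counts entering and removed by this filter are recorded so the
   filter's bite can be audited.

The criterion uses only percentiles and ratios, so it is invariant to
global rescaling of activity. It presumes ΔF/F fluctuates around zero
outside transients (it does, after running-minimum baselining); feeding it
maps with a large constant offset would make step 2 vacuous.

Detection quality has an intrinsic asymmetry worth knowing: the calcium
kernel (≈1.5 s decay) smears ΔF/F *forward* along the track by roughly
(decay time) × (running speed) — 2–4 bins at typical speeds — so ΔF/F peak
positions sit slightly ahead of the underlying event-rate peak, and ΔF/F
extents run wider than the event-rate field. Ground-truth recovery tests of
the detector therefore use event-amplitude maps (smear-free); the ΔF/F
route is validated against distributional properties instead.

## Per-lap field dynamics

For each detected field, laps from the onset lap onward with ≥ 2 in-boundary
(thresholded) DCEs contribute: a COM (amplitude-weighted mean of bin
offsets from the peak — offsets, so wrapped fields average correctly), a
size (distance from first to last event-containing bin), and, on the ΔF/F
side, a width at half of the lap's in-boundary peak plus a ΔF/F-weighted
COM (laps with in-boundary peak ≤ 3.5 × baseline excluded: fields are only
analyzed after formation). COMs are reported as deviations from the
field's across-lap mean; negative deviations point opposite to travel
(backward).

**Shift classification.** A field is backward/forward-shifting when the COM
of its first 3 included laps differs from all later included laps by a
directional two-sample t-test at α = 0.025 per direction. Two choices here
were open:

* *Which t-test?* We use the pooled-variance (Student) test. With only 3
  early laps, the Welch approximation is measurably anti-conservative
  (simulated per-direction false-positive rate ≈ 3.5% at α = 0.025),
  whereas the pooled test is exact under the null; the calibration test in
  the suite verifies 2.5% ± 1% per direction on 10,000 white-noise fields.
* *Sidedness.* "p < 0.025" with a direction read off the sign is
  implemented as directional p (two-sided/2) < α in each direction, i.e.
  2.5% per direction under the null.

## Spatial information and its null

`SI = Σᵢ pᵢ (fᵢ/f̄) log₂(fᵢ/f̄)` (bits per event), computed on the
lap-averaged, 2-bin-smoothed DCE amplitude map with occupancy
probabilities `pᵢ`; zero-activity bins contribute zero, and an all-zero
cell is an error, not a 0. The null rotates every lap's bin vector by an
independent uniform offset (which preserves each lap's total activity and
the occupancy map) and recomputes SI; 100 shuffles by default.

## Population analyses and decoding

PV correlation matrices correlate, bin against bin, the vectors of
per-cell mean activity over two lap intervals (3-lap intervals by
default); the diagonal mean summarizes same-place similarity. Zero-variance
population vectors yield `NA` entries, which are counted and excluded from
the diagonal mean.

The Bayesian decoder is the standard memoryless-Poisson construction:
prior = relative occupancy over training laps; per-cell rate maps =
occupancy-normalized mean DCE amplitude per bin over training laps,
circularly smoothed (9 bins) and floored at 1e−6 events/s (no log(0));
observed activity = summed population amplitude in a *trailing* 2 s window
at each frame (causal; centering was unspecified, and a trailing window
never uses future data); posterior ∝ prior × ∏ cells Poisson. Decoded bin =
posterior argmax with ties to the lowest bin index. Frames with zero window
activity fall back to the prior and are flagged. Cross-validation is
leave-one-lap-out; frames below 1 cm/s are not decoded, matching the
binning policy.

*Error metric.* The track is circular — bins 1 and 100 adjacent — so the
primary decoder error is the circular distance between decoded and true
bin centers, in cm (chance level: track length / 4). The plain absolute
difference is also reported for comparability with linear-track analyses.

Session-level errors subsample 146 neurons 100 times by default (the
cross-dataset protocol) and average per-lap mean errors across repeats.
Sessions with familiar-environment error above 30 cm are flagged for
exclusion, alongside the ≥ 10 laps and ≥ 50 cells gates applied by
`run_pipeline()`.

## Behavior

Licks within 4 s after any reward delivery are consumption and removed
(per reward event, possibly across a lap boundary); remaining licks are
binarized per (lap, bin) so bursts weigh no more than single exploratory
licks. The anticipatory zone is the 10 bins immediately *preceding* each
reward bin — half-open, excluding the delivery bin — matching the
description of correct bins as those just prior to reward. Precision =
anticipatory licked bins / licked bins remaining after exclusion; a lap
with no remaining licks scores 0 (so lap-wise scores can fall below the
0.2 chance level). Session-level precision pools bins across laps rather
than averaging lap scores; both are reported because both views are used.

Cell categories (familiar-only / novel-only / both / neither, from field
detection per environment) get per-lap mean activity z-scored against the
mean and SD of the lap-averaged activity of *all* cells and laps in the
session — removing between-animal fluorescence scale while preserving
between-cell differences. Multi-session summaries average cells → sessions
→ animals, in that order.

## Lap trends

`linear_trend()` is OLS with the usual two-sided slope test.
`exp_decay_fit()` fits `Y = (A − C)e^(−kX) + C` by Levenberg–Marquardt
(`minpack.lm`), initialized at A = first y, C = last y, k from a log-linear
fit of y − C, with k bounded in [0, 10]; a fit that cannot beat the best
constant collapses to it and is flagged `converged = FALSE` (k is
unidentifiable when A ≈ C). The extra-sum-of-squares F statistic compares
the 2-parameter line with the 3-parameter exponential on the same data.
`compare_slopes()` is the ANCOVA-style common-slope test (interaction term
F-test), followed by a common-intercept test when slopes are compatible.
Mixed-effects and repeated-measures machinery is deliberately not
re-implemented: the package emits tidy per-lap tables ready for `lme4` or
similar.

## The synthetic-session generator

`generate_session()` emulates the experimental design so every stage has
ground truth:

* **Geometry/behavior**: circular track (default 400 cm / 100 bins = 4 cm
  bins, within the 3–5 cm range of real 314–502 cm tracks), ~7 Hz frames,
  20 familiar + 15 novel laps, teleport exactly at a lap boundary. Mean
  running speed defaults to 12 cm/s — real sessions cover at least 10 laps
  in roughly ten minutes, i.e. 30–50 s per lap — with per-lap speed jitter
  and occasional sub-1 cm/s pauses so the speed exclusion is exercised.
* **Tuning**: tuned cells fire Poisson DCEs along a wrapped-Gaussian tuning
  curve (σ = width/4); the minimal single-peaked shape, since the analysis
  never assumes more. Field widths are log-normal (median 50 cm,
  sdlog 0.25 → 5–95% range ≈ 33–75 cm). Peak in-field rate 2 events/s over
  a 0.1 events/s background. Fields are expressed per lap with probability
  `reliability` (default 0.8) and can drift a configured number of cm per
  lap (backward drift = negative). Event amplitudes are log-normal.
* **Fluorescence**: events convolved with a single-exponential kernel
  (1.5 s decay, GCaMP6s-scale; only relative dynamics matter downstream),
  transient gain 0.3 ΔF/F per unit amplitude, additive Gaussian ΔF/F noise
  (default SD 0.1/frame), plus a shared low-pass contaminant injected into
  both the soma (×0.7) and neuropil channels so neuropil correction has
  something to remove.
* **Remapping**: cells are allocated to familiar-only/novel-only/both/
  untuned by stratified exact-count (largest-remainder) assignment, so the
  realized tuned fraction and both-environment overlap match their targets
  up to integer rounding. The default overlap is the chance level
  `frac_tuned²` — global remapping with independent field locations.
* **Licking**: Bernoulli per (lap, bin), with the anticipatory-bin rate set
  so the expected precision equals `lick_precision_target`; rewards are
  delivered at the first frame entering each reward bin.

Reliability and amplitude are not quantities the experimental design
reports; the defaults above are this package's choices of plausible values,
documented here, and are *not* estimates of any study's parameters.

What the generator does **not** emulate: imaging artifacts (motion,
bleaching, segmentation cross-talk), non-Gaussian or multi-peaked tuning,
direction- or speed-modulated rates, theta-timescale structure, reward- or
cue-locked non-spatial responses, pupil/arousal dynamics, and
between-environment differences in track length. Passing tests on
synthetic sessions therefore validate the *estimators and their
bookkeeping* (binning, boundaries, exclusion rules, cross-validation,
nulls), not robustness to every pathology of real recordings.

## Numerical choices and degenerate inputs

* Oracle equivalences (ΔF/F baseline, SI closed forms, OLS) are tested to
  1e−9; posterior rows normalize to 1 within 1e−9.
* Argmax ties: lowest bin index. Median ties in event thresholding: retain.
  Plateau peaks: leftmost bin.
* Rate floor 1e−6 events/s in decoding; prior floored at 1e−12 before logs.
* All-NA map rows, all-zero activity, zero session SD, zero x-variance, and
  fields with no qualifying laps raise errors or return flagged `NA`s
  rather than silent numbers.
* Every randomized step (generation, shuffles, subsampling, sort-half
  draws) takes an explicit seed; identical seeds reproduce results
  bit-exactly, and the session container records the seed in its manifest.

Problem sizes in the shipped tests are desk-scale choices: sessions of
40–200 cells and 10–35 laps, 5-session cohorts for filter audits, 10,000
simulated fields for the shift-test calibration, and single-repeat decoder
runs in the pipeline smoke test (the 146 × 100 subsampling protocol remains
the default for real use).

## Container format

One directory per session: `manifest.json` (geometry, configuration echo,
seed, per-table MD5 checksums), `frames.csv`, per-cell trace and event
CSVs, and an optional `ground_truth.json` sidecar for synthetic sessions.
A plain-text container keeps sessions diff-able and dependency-free;
reading validates checksums and frame-clock consistency across all streams
before constructing a session. A hierarchical binary store would be the
natural choice for very large cohorts and could back the same read/write
interface.

## Known limitations

* ΔF/F-based size/COM estimates inherit the forward calcium smear; the
  DCE-based estimators are the ones to trust for shift analyses (the two
  can disagree on real data for exactly this reason).
* Detected boundaries are static per field; for strongly drifting fields
  the early/late laps can be clipped at the boundary edges, attenuating
  apparent drift measured through detected (rather than ground-truth)
  boundaries.
* The decoder's trailing 2 s window introduces a backward lag of roughly
  half a window of travel at constant speed; this is shared by any causal
  window and is part of the measured error.
* `compare_slopes()` treats laps as independent observations (as do the
  per-lap regressions); hierarchical dependence across sessions/animals is
  left to downstream mixed-effects modelling.
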
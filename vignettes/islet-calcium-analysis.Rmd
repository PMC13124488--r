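---
title: "Methods: islet calcium dynamics and functional beta-cell subpopulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: islet calcium dynamics and functional beta-cell subpopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletca)
```

## The measurement and the model

Pancreatic islets expressing a genetically encoded Ca²⁺ indicator (GCaMP6f in
beta-cells) are imaged on a confocal microscope during a glucose ramp: 3 mM
baseline, a submaximal step to 11 mM, a maximal step to 25 mM, and a terminal
KCl depolarization that forces Ca²⁺ influx in every viable cell. The response
is biphasic: a large *first-phase* Ca²⁺ peak starting 3–10 minutes after the
11 mM step, followed by *second-phase* steady-state Ca²⁺ waves. `isletca`
takes the per-ROI fluorescence table that ImageJ "Multi Measure" exports
(plus ROI centroids and the stimulus timeline) and computes the islet-level
dynamics and three functional beta-cell subpopulations:

* **first-responders** — the 10% of cells with the fastest first-phase
  activation time (T₂₀, a 20% rise of the normalized trace);
* **highly connected "hub" cells** — from a binarized coactivity network
  (either ≥80% of significant connections with coactivity ≥0.8, or the top
  10% best-connected);
* **leaders** — cells whose mean per-wave activation latency is at or below
  the 10th percentile during the second phase.

The package works on a single canonical frame axis (1-based; stimulus frame
*k* means frames 1..*k* are pre-stimulus), with seconds derived as
frame × `frame_interval_s`. Analysis windows are: 3 mM baseline `[1, g11]`,
first phase `(g11, first_phase_end]`, second phase `(g25, kcl]`, and the KCl
window `(kcl, n]`.

## Signal conditioning

**Smoothing.** A centered moving average (default 15 frames = 7.5 s at
2 frames/s, configurable 3–15) with shrinking windows at the edges. It
suppresses shot noise and small focus wobbles; over-smoothing can hide short
waves, which is why the window is capped.

**General fold change.** `(F − F_min)/F_min` with `F_min` the minimum over
the 3 mM baseline. Used for the first-phase metrics, the AUCs and the KCl
filter. It is invariant to per-cell gain, so sum vs. mean of ROIs and
detector settings drop out.

**Adaptive baseline.** After the first phase the Ca²⁺ baseline often fails
to return to its 3 mM level, and it can drift within a section. Each
analysis section (by default the 25 mM period) is first expressed as a
*section fold change* over its own minimum; local extrema are detected;
valleys are filtered into baseline anchors; and the anchors are connected by
straight lines (flat beyond the terminal anchors) to form the adaptive
baseline. The section is then re-expressed relative to that baseline. Since
a section fold change (and its baseline) can be ~0, both are shifted by +1
into ratio space: `SF = (1 + F)/(1 + BL) − 1`, which is exactly
`(F_raw − BL_raw)/BL_raw` when applied to raw intensities.

Two rules select the anchors:

1. *Proximity*: peaks closer than 12.5 s (25 frames at 2 frames/s) to a
   valley are discarded from the pairing — a genuine wave needs about that
   long to deactivate, so a nearer valley marks a noise peak. The rule is
   specified in seconds and converted with the frame interval, so recordings
   at other frame rates keep the same physical meaning.
2. *Drop fraction*: a valley is kept only if it sits at least 30% below the
   immediately preceding surviving peak, `(Peak − Valley)/Peak ≥ 0.30`.
   Valleys with no surviving peak before them are retained.

**Prominence pruning (a numerical choice).** Strict local extrema on any
real (even smoothed) trace occur every few frames, and with a literal
reading of rule 1 every genuine wave peak would have a noise valley within
25 frames and be discarded, leaving valleys on top of waves as anchors. We
therefore prune extrema by prominence before filtering: alternating
peak/valley pairs whose amplitude difference is below half the activation
threshold (default 0.1 in fold-change units) are merged away — the same role
as a minimum-prominence argument of the usual peak finders. The default ties
the pruning scale to the activity threshold: an excursion that could never
count as activity can never place an anchor either. With pruning, retaining
orphaned valleys (rule 1 can discard *every* peak when waves are closer than
25 frames to their flanking valleys) is safe, because surviving valleys are
genuine inter-wave minima.

## Global metrics

**Wave detection** imposes a double threshold on the detrended trace: an
event opens at the first frame strictly above 0.2 (20% over the local
baseline — for GCaMP6-family sensors this sits at the elbow of the
connectivity-vs-threshold curve; other sensors may need another value) and
closes at the first frame strictly below it; values exactly at the threshold
do not toggle. Events shorter than 2 s are discarded; an event still open at
the end of the trace is kept but flagged truncated. Width is the number of
active frames × the frame interval.

**AUC.** Both estimators are computed per phase against the 3 mM baseline:
the *apparent AUC* (plain sum of fold-change values over the window) and the
trapezoid-rule AUC `Σ (F_i + F_{i+1})/2 · Δt`.

**First phase**: amplitude = max fold change in the first-phase window;
FP-T₂₀ = time from the 11 mM addition to the first frame strictly above 0.2;
width = time from activation until the trace first falls back below 0.2.
The "first-phase end" of the width is our operationalization of a
qualitative notion (the transition into oscillations); the below-threshold
definition is deterministic and is what the tests pin down.

**Second phase**: frequency = detected waves ÷ window minutes (15 waves in a
1,200 s window = 0.75 waves/min); amplitude and width are per-event means.

## Subpopulations

**KCl filter.** Cells whose general fold change never exceeds 0.2 in the KCl
window are excluded from all subpopulation calls.

**First-responders.** Per-cell traces are min-max normalized with `F_min`
from the 3 mM window and `F_max` up to the first-phase end; FR-T₂₀ is the
first frame at or above 0.2 (inclusive, unlike wave detection, per the T₂₀
convention). The `ceiling(0.10 · n_included)` fastest cells are labeled;
ties resolve by earlier crossing then cell order; never-crossing cells are
never labeled.

**Hubs.** Per-cell traces over the section are detrended with the same
adaptive-baseline procedure as the islet (each cell gets its own anchors),
binarized at 0.2 (strict), and the pairwise coactivity
`C_ij = T_ij / √(T_i·T_j)` is computed (T = active time). This normalization
satisfies the stated semantics — 1 for perfect coordination, 0.5 for
half-time coordination of equally active cells, 0 for none; the literal
product form `T_ij/(T_i·T_j)` is kept behind `norm = "printed"` for
comparison with legacy scripts but cannot reach 1. Chance coordination is
controlled by a circular-rotation shuffle null: each surrogate independently
rotates both activity vectors by uniform offsets (preserving burst structure
and total activity, destroying alignment), and a pair is significantly
linked iff the observed coactivity exceeds the surrogate mean by more than
2 SD. The implementation samples a single uniform lag per surrogate and
reads the co-active count off the circular cross-correlation (FFT) —
statistically identical to materializing rotations (the difference of two
independent uniform offsets is itself uniform) and fast enough that the
default 10,000 shuffles on 100+ cells complete in seconds rather than hours.
Both hub rules are computed: the criterion rule (≥80% of *significant*
partners with C ≥ 0.8; cells with no significant partner are never hubs) and
the top-10% rule (rank by significant-connection count, ties by mean
coactivity then cell order; zero-degree cells are never flagged). Whether
non-significant pairs should enter the criterion denominator is unspecified
in the source protocol; we count significant partners only, which is the
choice the tests freeze. The islet connectivity `c_islet` is the mean
off-diagonal coactivity over all pairs (a significant-only variant is a
config option), classified low ≤ 0.5 < medium ≤ 0.75 < high (continuous
bins; the printed bins leave gaps at 0.50–0.51 and 0.75–0.76, which we
assign upward).

**Leaders.** Each islet wave gets a window from the last valley anchor at or
before its activation to the first anchor at or after its deactivation
(clipped to the section; if two waves share flanking anchors the boundary is
the midpoint between them — windows never overlap). Within each window every
cell's detrended trace is min-max rescaled and its SCSP-T₂₀ measured from
the window start. A cell participates in a wave only if its *un-rescaled*
fold change exceeds the activity threshold there — otherwise forced
rescaling of a noise-only segment would fabricate early latencies — and
cells active in fewer than half the waves are not leader-eligible (a mean
over one or two waves is too unstable to rank; the source protocol is silent
here). Cells at or below the 10th percentile (inclusive, linear
interpolation) of eligible means are leaders. Latency is referenced to the
window start rather than the islet activation; only latency *differences*
between cells matter for the percentile rule, and the window start is
well-defined even for cells that lead the islet.

## The synthetic generator

`simulate_islet()` produces recordings with planted ground truth:
`f0·(1 + drift + signal) + noise`, where the per-cell signal is a smoothed
first-phase step (onset normal across cells, mean 4 min after the 11 mM
step), a second-phase square-wave train in which participating cells
activate at the wave time plus a per-cell lag, and a KCl plateau; dead cells
are flat everywhere. This is deliberately a *statistical* model, not an
electrophysiological one: the pipeline consumes fluorescence statistics, and
an additive closed-form signal gives every stage an exact oracle (wave
counts, onsets, lags, memberships are all known).

Preset choices, made once from the phenomenology the protocol describes:

* `"clean"` (50 cells, noise 2% of baseline, no drift) plants 5
  first-responders with a 90 s onset lead over a 20 s onset SD (a ~4.5 SD
  gap: recovery failures measure pipeline faults, not overlap), 5 leaders
  with a 1.5 s wave lead (3 frames at 2 frames/s — resolvable but tight),
  and 5 hub-like cells that join every wave while ordinary cells join 75%
  of them. With the √-normalized coactivity, ordinary–ordinary pairs then
  sit near C ≈ 0.75 (below the 0.8 strong-connection bar) and
  ordinary–full pairs near √0.75 ≈ 0.87 (above it), so the fully
  participating cells are exactly the criterion hubs. Waves run at a 24 s
  period and 12 s width — short steady-state oscillations — giving ~53
  waves per section so per-wave latency means are stable.
* `"drifting"` (30 exchangeable cells, 80 s period / 20 s width waves) adds
  a linear drift of 7.5% of baseline per minute. Over the 22-minute 25 mM
  section the section fold change then ramps by ~0.6–0.7, so
  fixed-baseline detection loses the threshold crossing about a third of
  the way in and merges the remaining waves into one event, while the
  adaptive baseline tracks the ramp and recovers the full train. This is
  the preset's defining property and is asserted per-seed in the tests.
* `"noisy"` raises the noise to 8%, and `"no_heterogeneity"` removes all
  planted sets for label-bias tests.

What the generator does **not** emulate: indicator photophysics (Hill
kinetics, the ~63-fold dynamic range), bleaching, spatially structured wave
propagation (ground-truth "hubs" are defined through participation, not
geometry), irregular wave periods, or movement artifacts. Passing the
recovery suites therefore shows the pipeline correctly measures what the
model plants — latency order, wave counts, participation structure — not
that it is robust to every artifact of real microscopy.

## Numerical and reproducibility notes

* Problem sizes in the test suite: recovery suites run the full pipeline on
  50-cell, 5,040-frame recordings over 20 seeds with 300 shuffles per pair;
  the calibration suite uses 500 independent pairs × 1,000 shuffles. The
  shuffle count is configurable down from the 10,000 default precisely so
  that repeated seeded runs stay cheap; the FFT-backed null makes the
  default feasible on full islets as well.
* All randomness flows through explicit seeds (`rng_seed` in
  `simulation_params()` and `run_config()`); reruns are byte-identical,
  including the written result files (shortest round-trip number
  formatting).
* Degenerate inputs: constant traces are unanalyzable for normalization and
  are flagged rather than dropped silently; empty KCl windows include all
  cells with a warning; zero valley anchors fall back to a constant
  baseline at the window minimum; truncated waves are flagged; a
  non-positive adaptive baseline is an error naming the frame.
* Ties: plateau extrema take their first frame; the valley drop rule is
  inclusive (≥ 0.30); T₂₀ crossings are inclusive (≥) while wave
  activation/deactivation are strict (>/<), matching the respective printed
  conventions; ranking ties resolve by cell order so runs are stable.

## Known limitations

Registration, ROI segmentation and image I/O are out of scope — the package
starts at the exported trace table. The first-phase width and the per-wave
window construction operationalize qualitative descriptions; both are
documented above and frozen by tests, but other operationalizations are
defensible. The binarization threshold default (0.2) encodes the GCaMP6
elbow analysis; it is a config value, not something the package re-derives
per dataset.
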
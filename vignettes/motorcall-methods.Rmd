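---
title: "Methods: classifying larval-zebrafish motor behavior from keypoint tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying larval-zebrafish motor behavior from keypoint tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Larval zebrafish (5–7 dpf) express a small repertoire of stereotyped
motor maneuvers: they sit still, scoot forward, reorient with routine
turns, and produce fast startle maneuvers — the C-start (short-latency,
typical of acoustic startle) and the O-bend (longer-latency, typical of
dark-flash visual startle). High-throughput rigs record dozens of larvae
in parallel in 24- or 96-well plates at 160 fps and reduce each animal to
8 midline key points per frame. `motorcall` takes those keypoint tracks
and produces classified motor calls, smoothed ethograms, bout
segmentations, kinematic summaries and stimulus-response rates.

## Representation

**Windows.** Tracks are cut into overlapping 40-frame windows (250 ms at
160 fps), stride 1. A track of N frames yields `N − 40` windows, so a
standard 1,600-frame acquisition yields 1,560 — the window whose final
frame would fall past the end of the track is dropped. 250 ms is long
enough to contain any single maneuver (all bout classes average
\> 150 ms) and short enough to keep windows mostly single-behavior.

**Egocentric alignment.** For each window one rigid transform is
computed from its first frame — a rotation about the body center
(key point 3) that points the center→snout vector "up" (negative y,
image convention), followed by a translation of that center to the
origin — and applied identically to all 40 frames. Alignment is exactly
rigid (pairwise within-frame distances preserved to 1e−9) and
equivariant: pre-composing the raw window with any global rotation +
translation leaves the aligned output unchanged. The classifier
therefore sees only motion relative to the initial pose, never the
fish's absolute position or heading.

**Normalization and flattening.** Aligned coordinates are divided by the
dataset-wide maximum absolute coordinate, then the dataset mean of the
scaled values is subtracted (in that order; the constants are fitted on
the training corpus of a plate format and stored in the model bundle,
never refitted at inference). "Maximum value" is taken as max |·|, which
keeps the scale positive for either sign convention. Windows flatten
frame-major — frame 1's eight `(y, x)` pairs, then frame 2's, … — to
length-640 vectors; the order is fixed and serialized with the model.

## The classifier

Per plate format: PCA with exact SVD, centering, no whitening, retaining
the leading components holding ≥ 95 % of training variance (the recorded
random state 2023 is provenance only — exact SVD has no stochastic
step), then a 100-tree random forest (seed 2023) on the scores. Because
the class counts of the corpus are deliberately unequal (startle classes
are rare), each tree draws a class-balanced bootstrap (stratified,
`sampsize` = smallest class count); without balancing, ambiguous startle
windows default to the majority startle class. The 24-well class set is
{stationary, scoot, turn, AsLB, VsLB}; the 96-well optics cannot
reliably resolve short scoots from reorienting turns, so those merge
into a single movement class.

Clips split 90/10 into train/test, stratified by class so every class
appears in both subsets. Evaluation reports a row-normalized confusion
matrix and per-class precision/recall/F1 plus micro-, macro- and
support-weighted overall F1 (which average differently under class
imbalance; all three are reported since "overall F1" is ambiguous).

**KMeans mining.** Before any labels exist, flattened windows are
clustered with k-means (k = 9, seed 2023). Clusters whose members' mean
within-window center path length falls below 0.5 mm per window are
flagged stationary; the flags guide which windows are exported (as
coordinate CSV clips) for manual review, and are never used as final
labels.

## From window calls to ethograms

A raw per-window call series is noisy in time: a behavior can occur
anywhere inside a 250 ms window, and single-window flicker produces
biologically impossible alternations. Majority voting fixes both: frame
t receives the most frequent call among all stride-1 windows overlapping
t. Ties break by a fixed class priority (VsLB \> AsLB \> turn \> scoot \>
movement \> stationary): deterministic, and biased toward not missing
rare startle events. Under the `N − 40` convention the final frame has
no covering window and is absent from the voted series. Voting provably
never increases the number of label transitions relative to naively
assigning window calls to start frames (verified empirically on random
series), and residual timing error is below one window length (250 ms).

**Bouts.** Call bouts are maximal same-label runs strictly longer than
5 frames ("exceeding" 5 read as \> 5; configurable). The independent
speed-bout detector uses the complementary inclusive rule — speed
\> 2 mm/s sustained for at least 5 frames (31 ms) — matching the
distinct wording of the two definitions; the 2 mm/s threshold is the
default with the alternative 5 mm/s exposed as a config override. Each
bout is annotated with duration and per-bout maxima of speed and
|Δheading| from the kinematics module.

**Kinematics.** Heading is the bearing of the center→snout vector
(key points 3 → 1); frame-to-frame heading change is wrapped into
[0, 180]°; speed is the center key point's displacement × pixel pitch ×
fps (the center is the point least perturbed by tail beats); the tail
angle is the signed deviation of the center→tip vector from the body
axis (0 = straight). Frames where center and snout coincide get NaN
heading, propagated rather than interpolated.

**Response rates.** A trial is responsive when ≥ 1 frame inside the
response window carries the elicited call — AsLB within 250 ms after a
tap, VsLB within 1.0 s after a dark flash (both windows exceed the
established latency of the respective behavior). A fish is responsive
when any of its (typically 6) replicate trials is. Fish-level and
trial-level rates are reported separately; neither bounds the other in
general.

## The simulator

The synthetic module emulates what the acquisition stack would hand this
package: 10 s (or 60 s) acquisitions at 160 fps, 8 midline key points in
pixels, per-format keypoint noise, and the kinematic signatures of the
five classes. A body model places key points along the midline by arc
fraction (default {0, .12, .30, .45, .60, .75, .88, 1}; center = key
point 3, ≈ 30 % of the body at the swim-bladder region; length 3.56 mm
in 24-well optics, 3.85 mm in 96-well). Poses are built as a chain of 7
segments extending backward from the snout, bent by a per-joint signed
angle profile; trajectories integrate per-frame speed and heading
increments and reflect specularly at the well wall.

Class templates (defaults; per-bout parameters are drawn from the
stated ranges):

| class | peak speed (mm/s) | total Δheading (deg) | latency | duration |
|---|---|---|---|---|
| stationary | 0.1 (drift) | 0 | — | — |
| scoot | 5–9 | net \< 20 (drawn ±12) | 0 | 0.30 s |
| R-turn | 2–3 | 35–85 | 0 | 0.15 s |
| AsLB | 45–65 | 100–130 | 4–12 ms | 0.20 s |
| VsLB | 20–30 | 140–170 | 160–450 ms | 0.25 s |

These respect the qualitative orderings real assays show — startle
classes far exceed scoots/turns in peak speed and heading change (AsLB
≥ 5× a scoot on both), turns are the shortest bouts, VsLB has the
largest reorientation and the long latency of an O-bend — but the exact
magnitudes are simulator parameters, not claims about real fish. The
AsLB and VsLB heading ranges are disjoint by construction: the classes
are *defined* by their kinematic signatures, and at 96-well noise a
heavily overlapping pair would be unlearnable from 250 ms of 8-point
pose alone.

**Noise.** The per-format noise targets are the measured keypoint
placement errors of the two optical configurations: 70 µm RMS radial
deviation for 24-well, 133 µm for 96-well (per-axis sd = σ/√2).
Critically, the noise is AR(1)-correlated in time (lag-1 ρ = 0.995 per
coordinate, stationary marginal sd preserved): pose-estimation error is
dominated by slowly varying, pose-dependent bias, not white jitter.
White noise of this magnitude would alone read as ≈ 15 mm/s of
frame-to-frame center speed at 160 fps — incompatible with the usable
2 mm/s bout threshold — so the correlated model is the only one
consistent with both the printed placement errors and the printed speed
threshold. With ρ = 0.995 residual speed noise is ≈ 1 mm/s RMS.

**Training corpora.** Default sizes mirror the reference corpora:
66/102/75/60/137 clips (stationary/scoot/turn/AsLB/VsLB) for 24-well and
432/486/170/309 (stationary/movement/AsLB/VsLB) for 96-well. Clip
windows are sampled at varying phase of the bout, as manually reviewed
clips would be: sustained-movement clips start anywhere from 16 frames
before bout onset to 20 frames before offset (the classifier must
recognize early, mid and late phases, or voted bouts shift and
fragment); startle clips draw their start from a Gaussian-weighted
offset around the bend onset (range −16..+4 frames, sd 6 — stimulus-
locked mining concentrates clips at the burst, and a C-bend preceded by
a long stationary lead-in is genuinely confusable with the delayed-onset
signature that defines an O-bend, while the distribution's tails keep
enough phase variety for frame-level voting).

**What the simulator does not model** — and hence what passing tests do
not show about real recordings: swim-bladder-led posture dynamics and
hydrodynamics; thigmotaxis and wall-following (walls only reflect);
behavior sequencing beyond a Poisson-like bout process; the ~200-odd
rarer maneuvers (struggles, seizure-like bursts, prey capture) outside
the five classes; occlusion and identity-swap artifacts of real
tracking. High synthetic F1 demonstrates the pipeline machinery recovers
classes whose kinematic separation resembles the templates; it does not
certify performance on any particular real dataset, for which the
reference corpora would be re-labeled and the model retrained.

## Numerical choices and degenerate inputs

* Coordinates are `(y, x)`, y down; "up" = −y; headings are compass
  bearings of the center→snout vector in (−180, 180].
* Frames and key point indices are 1-based throughout the R API and CSV
  formats.
* Windows whose first-frame center and snout coincide have no defined
  heading: they are flagged degenerate and excluded from featurization
  rather than silently transformed.
* Missing-coordinate runs ≤ `max_gap` (default 5) frames are linearly
  interpolated per key point and axis; longer gaps reject the track with
  a reason. Validation is idempotent.
* Vote ties break by the fixed priority above; run-length boundaries use
  half-open `[start, end)` intervals everywhere.
* Normalization constants, PCA basis and forest are serialized so that a
  reloaded bundle reproduces predictions bitwise; exact numeric state is
  stored in R's native serialization because decimal text caps at ~15
  significant digits.
* All stochastic stages (simulation, k-means, split, forest, UMAP) take
  explicit seeds; PCA is exact SVD and needs none.

## Problem sizes used in tests and the acceptance script

Test fixtures train both plate-format models once on the default-size
corpora (440 and 1,397 clips) and reuse them; oracle-equivalence suites
run 1,000 random series per operation; the response-recovery experiment
uses 24 fish × 6 tap trials (144 ten-second acquisitions) at a scripted
75 % responder fraction; spontaneous ethograms use six 60 s tracks.
These sizes keep the full suite under a minute on one CPU while leaving
every statistical check comfortably powered.

## Known limitations

* The 96-well model's AsLB recall is the weakest link (macro F1 ≈
  0.95–0.99 across seeds): at 133 µm noise, a delayed-anchor C-start and
  an O-bend overlap in feature space. The same ambiguity is why real
  96-well assays merge scoot/turn and why startle classes are "-like".
* Majority voting bounds timing error by one window (250 ms) but cannot
  resolve two distinct behaviors closer than ~¼ s.
* The NetCDF schema is a documented stand-in; the vendor's proprietary
  layout would need a thin adapter.
* The UMAP embedding is visualization only; no quantitative claims
  attach to it.
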
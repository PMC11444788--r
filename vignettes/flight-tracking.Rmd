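---
title: "Tracking insect flight: models, parameters and validation"
author: "mostrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking insect flight: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mostrack)
```

## The problem

Laboratory studies of mosquito fitness and behaviour need continuous,
per-individual flight trajectories from video: which insect was where, in
every frame, through crossings and brief detection failures. The footage
this package targets is grayscale, roughly 1040 x 1024 pixels at 60
frames/s, showing up to five small dark bodies (about 12 px long) against
a light background. Three things make this harder than generic object
tracking: the targets are tiny and visually identical, they maneuver
quickly relative to their size, and they occasionally overlap (occlude)
so the detector sees one blob where there are two insects.

`mostrack` implements the full chain: per-frame detection, identity
tracking, removal of spurious short-lived identities, interpolation of
missing frames, and quantitative evaluation against ground truth,
together with a synthetic video generator so the whole chain can be
validated without any recorded footage.

## Detection

The built-in detector binarizes each frame at a fixed intensity threshold
(dark-on-light), labels connected components, keeps components inside an
area window, and reports tight boxes with a contrast-based confidence in
(0, 1]. It is deliberately simple: the tracker is detector-agnostic, and
detections produced by any external detector (for instance a trained CNN)
can be supplied as a `frame,x,y,w,h,conf` text file via
`read_detections()`.

Two detection-stage parameters mirror common detector conventions:

* **Confidence** (default 0.05): detections scoring *below* the threshold
  are removed; equality is kept. The default is deliberately low because
  small targets yield weak scores.
* **NMS IoU** (default 0.05): greedy non-maximum suppression drops a box
  whose overlap with a better-scoring box strictly exceeds the threshold.
  The lenient default suits small, well-separated targets; it also means
  two insects are merged into one detection slightly *before* their boxes
  would visually fuse, which the tracker's occlusion handling absorbs.
* **Image size** (default 1040): detector backbones need dimensions that
  are multiples of their maximum stride (32), so a requested size is
  rounded *up* to the next multiple — 1040 becomes 1056. Rounding up
  rather than to-nearest is intentional: downscaling small targets costs
  recall, and the canonical behaviour for the default request is 1056.

## The motion model and association

Each identity carries a constant-velocity Kalman filter on
`(cx, cy, a, h)` — box center, aspect ratio, height — plus their
per-frame velocities (8 state dimensions). Noise follows the common
height-scaled convention (position std `h/20`, velocity std `h/160` per
frame) **with absolute floors** (1 px position, 0.4 px/frame velocity):
the convention was designed for targets ~100 px tall, and for a 10 px
insect it would imply sub-pixel noise, which is far below both the
detector's quantization jitter and the accelerations of real flight. The
aspect-ratio and height dimensions get their own, much larger noise
(process 0.25 and 2 px, measurement 0.8 and 2.5 px): the box of a
rotating elongated body legitimately swings between `w/l` and `l/w`
within a few frames, and treating that swing as improbable would poison
the gate. These floors were set from the innovation statistics of
single-agent synthetic runs (so that the motion gate accepts essentially
every true continuation), not from any evaluation score.

Association per frame is a Hungarian assignment over a cost matrix
combining appearance and motion:

* **appearance**: the smallest cosine distance between the detection's
  L2-normalized intensity histogram and the track's gallery of recent
  descriptors (up to 50);
* **motion**: the squared Mahalanobis distance of the detection from the
  track's predicted measurement distribution, normalized by the gate;
* pairs whose Mahalanobis distance exceeds the chi-square 0.95 quantile
  with 4 degrees of freedom (9.4877) are forbidden outright.

The default cost weight is 0.95 appearance / 0.05 motion. A pure
appearance cost (with motion only as a gate) is the classic
deep-association design, but it presumes a discriminative embedding;
intensity histograms of two identical insects differ only by noise, so a
small motion term is what resolves those near-ties deterministically in
favour of the kinematically consistent pairing. Two structural details
matter as much as the weights:

* **Matching cascade.** Tracks associate in groups of increasing
  time-since-update. A track that has coasted for many frames has a huge
  predicted uncertainty — normalized distances become artificially small
  — and without the cascade such a track can steal detections from a
  track that is following its target frame by frame.
* **Recovery stage.** After the gated assignment, still-unmatched tracks
  may claim still-unmatched detections by plain predicted-position
  distance within twice their predicted box height (at least 16 px). This
  exists so that a single spurious gate violation (a sharp turn) does not
  fragment an established track into two identities.

The lifecycle is governed by two parameters: a new identity is
*tentative* until it is matched on `n_init = 3` consecutive frames (a
tentative track dies on its first miss, which suppresses one-frame
clutter), and a confirmed track is deleted once it goes unmatched for
more than **Max Age** (default 30 frames = 0.5 s at 60 frames/s). Ids
are never reused.

## Filtration and interpolation

Raw tracks pass two post-processing steps, in this order:

* **Filtration** (default 5%): any identity observed in strictly fewer
  than 5% of the video's frames is removed. This targets short-lived
  spurious identities — typically specular reflections on the enclosure —
  before they can be interpolated into plausible-looking trajectories.
  Only *observed* frames count toward presence.
* **Cubic-spline interpolation**: every missing frame strictly between a
  trajectory's first and last observed frames is filled by interpolating
  x and y independently against frame number. The spline passes through
  all observed points (they are never altered) and nothing is
  extrapolated beyond the observed range; with three (two) observations
  the interpolant is a quadratic (straight line). A configurable
  `max_gap` can exclude very long gaps; by default there is no cap. The
  boundary condition is the Forsythe–Malcolm–Moler end condition
  (`stats::splinefun(method = "fmm")`, R's default): it fits an exact
  cubic through the four points at each end, which makes the interpolant
  reproduce cubic-polynomial motion exactly — the property the validation
  suite pins down — and is, like any interpolating cubic spline,
  C2-continuous at the knots. A natural spline was rejected because its
  zero-second-derivative end condition fails that reproduction property.

Reported percentages (interpolated fraction, accuracy) are rounded to
two decimals, half away from zero.

## Evaluation statistics

Against a ground-truth trajectory sharing the same frames:

* **MAE** `= (1/n) * sum_f |x_f - xhat_f| + |y_f - yhat_f|` (pixels);
* **accuracy**: the percentage of frames with `|dx| < tol` **and**
  `|dy| < tol`, strict on both axes, with `tol = 6` px by default;
* the tolerance recipe `derive_tolerance()` halves the mean measured body
  length (12 px insects give the 6 px default); sampling which frames to
  measure is the caller's, seed-controlled, responsibility;
* **occlusion events**: for each pair of identities, maximal runs of
  consecutive frames whose boxes overlap with IoU strictly above 0.25.
  An event is *correctly resolved* when both identities map to the same
  nearest-centroid ground-truth agent immediately before and after the
  event; events touching the video boundary are undetermined and
  excluded. Ties in nearest-centroid go to the lower agent id.

With several estimated identities and agents, trajectories are first
matched one-to-one by minimal mean centroid distance over shared frames
(Hungarian assignment), and evaluation is restricted to the frames each
matched pair shares.

## The synthetic generator

`synth_config()` defaults encode the target recording regime: 1040 x 1024
px, 60 frames/s, five agents, 12 x 5 px elliptical bodies (intensity 60)
on a light background (220) with Gaussian pixel noise (std 2). Agent
kinematics are a mean-reverting (Ornstein–Uhlenbeck-style) velocity
process — random acceleration std 0.8 px/frame², damping 0.08, speed cap
8 px/frame — tethered weakly to per-agent anchors spread on a circle, with
a soft pairwise repulsion below 40 px. These constants were chosen once
to produce smooth, bounded paths with speeds of a few px/frame, the
visual character of leisurely laboratory flight; they are not fitted to
any data.

Forced **crossings** emulate the identity-switch hazard: one agent of a
pair flies a straight transit segment through the other's position
(smooth 20-frame blend out of its wandering path, 40-frame straight
approach, 20-frame straight exit, 40-frame blend back), while the partner
is straightened along its own heading around the crossing instant.
Crossing flights are fast, near-ballistic segments, which is also the
geometry described by "two agents crossing with disjoint entry and exit
paths"; a generator whose agents swerve *during* the occlusion would test
a different (and kinematically unidentifiable) scenario, since no
constant-velocity observer — human or filter — can attribute identities
when both targets turn unobserved mid-occlusion. The generator verifies
that the realized number of sub-body-length approach events equals the
request and raises an error for infeasible requests.

Per-agent-per-frame **dropouts** (an agent simply not rendered) exercise
interpolation; short-lived static **reflection blobs** exercise
filtration. All randomness derives from one seed through five named
sub-streams (motion, crossing geometry, pixel noise, dropout,
reflections), so each component is independently reproducible.

What the generator does *not* emulate: wing-beat or posture variation,
photometric flicker, motion blur at high speed, out-of-plane (3-D)
motion, and detector failure modes of a real CNN (confusions with
non-target objects). Passing the synthetic suite therefore demonstrates
the correctness of the tracking, interpolation and evaluation machinery
under the stated kinematics — not the performance of any particular
detector on real footage.

## Validation scale and numerical choices

The test suite validates end to end at sizes chosen to keep a full run
comfortable on one CPU: one clean five-agent video at the native
1040 x 1024 / 60 frames/s regime (3 s), a 10 s dropout video at 512², and
fifty crossing events as twenty-five 5 s two-agent videos at 320² — small
arenas do not change the per-interaction geometry, only the number of
pixels rendered. Degenerate inputs are defined rather than rejected
wherever a convention is defensible: IoU of two zero-area boxes is 0, an
all-zero histogram maps to the uniform descriptor, an empty frame yields
an empty detection table, and assignment with all pairs forbidden leaves
everything unmatched. Assignment ties are broken by row order (track
creation order); NMS confidence ties by smaller `x_min`, then `y_min`.

## Limitations

* The appearance descriptor cannot re-identify individuals after long
  absences; identity continuity rests on motion. This mirrors the
  underlying difficulty — the targets are visually identical — and is why
  `max_age` matters more here than in pedestrian tracking.
* Occlusions longer than a few tenths of a second, or in which either
  insect turns sharply while hidden, will produce identity errors; the
  achievable rate is bounded by geometry, not implementation.
* Frame input is PNG/TIFF image sequences; video containers should be
  exported to frames first.
* The evaluation assumes ground truth in the same pixel coordinates as
  the footage; no camera model or undistortion is applied.
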
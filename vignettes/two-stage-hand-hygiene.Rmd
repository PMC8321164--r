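---
title: "A two-stage multi-view system for hand-hygiene action recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage multi-view system for hand-hygiene action recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hygiene2stage)
```

## The problem

Effective hand washing is one of the strongest controls against foodborne
illness, and verifying it from video is a natural monitoring task: did the
person rub their hands long enough, apply soap, dry their hands, close the
faucet with the elbow, and avoid re-touching the faucet? `hygiene2stage`
implements a complete system for this *standard-level* task on untrimmed
paired video from a static third-person ("wall") camera and a chest-worn
egocentric camera. Seven actions are distinguished:

```{r}
standard7
```

The system's temporal atom is the **unit**: 30 consecutive frames, one
second at 30 FPS. Every decision — labels, durations, evaluation — is made
at unit granularity. Frames inside a unit are classified individually and
their softmax confidences averaged; the unit label is the argmax of the
average. Ties (e.g. a unit whose frames split 15/15 across a boundary)
break deterministically to the action listed earlier in the canonical
order above; that order is part of the package contract.

## The two-stage architecture

Densely applying a high-capacity classifier to every frame of a long
untrimmed video wastes most of its work on non-hygiene time. The system
therefore splits the work:

**Stage 1 (coarse, cheap).** A low-complexity CNN with 32 x 32 inputs
labels every wall-view unit with one of three classes: `faucet_elbow`,
`hand_hygiene` (any of the four sink-front hand actions), or
`non_hygiene` (which absorbs `dry_hands`, a post-hygiene action the wall
camera sees poorly). Units labelled `hand_hygiene` are *seeds*; everything
before the first seed is pre-hygiene, everything after the last is
post-hygiene; maximal runs of `faucet_elbow` units, padded by one unit on
each side, become faucet-elbow candidate regions. A second tiny CNN with a
single sigmoid output scans the chest view of the post-hygiene region for
drying (a unit counts as drying evidence when its mean frame score
strictly exceeds 0.5).

**Stage 2 (refinement, targeted).** A seven-class refinement classifier on
the chest view relabels the hygiene region, growing it by *iterative
expansion*: starting from each contiguous seed run it processes the next
unit to the left (then right), stopping in a direction when the refined
label is `non_hygiene` or `faucet_elbow`, the video ends, or the unit was
already processed. This repairs seeds that stage 1 missed inside the
hygiene period while touching as few units as possible. A wall-view
refinement classifier re-examines only the faucet-elbow candidates and can
veto them. The final report carries existence flags (faucet elbow/hand,
soap, dry hands), rubbing durations in seconds (unit counts), a flag for
the 20-second combined-rubbing requirement, the final unit label track,
and a frames-processed account.

The **baseline** comparator applies both refinement classifiers densely to
every unit (the wall one solely for faucet-elbow detection), so its
refinement fraction is 1 by construction; the two-stage system's fraction
is the refinement-processed share of all whole-unit frames in both views.
Trailing frames that do not fill a unit are discarded by every path and
excluded from the denominator.

One deliberate asymmetry in the final track assembly: a post-hygiene unit
whose dry-hands score is exactly 0.5 (half its frames drying) is labelled
`dry_hands`, consistent with the canonical tie-break used everywhere else,
while the existence flag keeps the strict `> 0.5` detector rule.

## The motion history image

The coarse wall classifier's selected configuration fuses RGB with a
motion history image (MHI), a per-pixel decaying memory of detected
motion:

$$H_t(x, y) = \begin{cases} \tau & |L_t - L_{t-1}|(x,y) > \xi \\
\max(0,\; H_{t-1}(x,y) - \delta) & \text{otherwise} \end{cases}$$

with BT.601 luminance $L$, history duration $\tau = 5$ frames, decay
$\delta = 1$ and difference threshold $\xi = 20$ on the 0–255 scale
(strict inequality; $H_0 = 0$). The MHI is computed at the 224 x 224
source resolution and area-averaged down to 32 x 32 for the network's
second stream. Because the recurrence floors at zero, anything older than
$\lceil \tau/\delta \rceil$ frames is forgotten, so the MHI at a sampled
training frame can be computed exactly from a short window rather than
from the clip start; the package exploits this identity throughout.

## The classifiers

All networks are VGG-style: 3 x 3 convolutions, batch normalisation before
every ReLU, 2 x 2 stride-2 max pooling.

* `conv5_fc1` — five conv groups (default widths 32, 64, 128, 256, 512;
  spatial trace 32-16-8-4-2-1) and one fully connected head. This is the
  selected coarse architecture.
* `conv4_fc2` — four conv groups, then a 512-output fully connected layer
  in place of the fifth group, then the head.
* `dwconv4_fc2` — as above with the fourth group depthwise separable
  (strictly fewer parameters).
* Dual stream — identical towers for RGB (3 channels) and MHI (1 channel);
  the final conv feature maps are concatenated (default 512 + 512 = 1024)
  before the head.
* Dry hands — `conv5_fc1` with a single sigmoid output and binary
  cross-entropy.
* Refinement — pluggable backbone: `vgg11_style` (the VGG11 convolutional
  configuration with a global-average-pooled head — the classical
  4096-wide fully connected stack alone would exceed one gigabyte of
  double-precision weights, far out of proportion for this task),
  `small_backbone` (area-downsample to 32 x 32 plus the five-group coarse
  stack with reduced widths; the desk-scale default), or `external` (any
  user-supplied scoring function, e.g. an adapter around pre-trained
  weights).

Training follows one recipe: SGD, cross-entropy (binary cross-entropy for
the dry-hands net), learning rate 0.001 decayed by a factor of 10 at
epochs 100 and 200, 250 epochs, batch 128 for coarse/dry-hands and 25 for
refinement, each batch element a randomly selected frame from a trimmed
training clip. These presets are the package defaults
(`train_config("coarse")` etc.). The reduced `desk` preset — 30 epochs,
milestones 12/24, batch 128, learning rate 0.01 — is the package's own
setting for the small synthetic problems in the test suite, where the
higher rate compensates for the short schedule. For efficiency each clip
contributes a small seeded pool of sampled frames (with their MHIs) and
batches resample from that pool rather than re-rendering a fresh frame per
draw; with tens of sessions the pool is comfortably larger than what a
short schedule can memorise. Input normalisation uses channel-wise
statistics of the training pool, stored with the model. Weight
initialisation draws from the session RNG, so a reproducible experiment
seeds both construction and training (`set.seed()` plus the config seed).

The CNN machinery itself is implemented inside the package: convolutions
are expressed as precomputed index gathers (compiled via Rcpp) feeding
BLAS matrix products, with batch norm, pooling and the SGD schedule in
vectorised R. The backward pass uses the flipped-kernel convolution
identity rather than scatter-adds. Gradient correctness is pinned by
finite-difference tests.

## The synthetic session generator

Every training and evaluation path in the package runs on data from a
fully seeded synthetic generator, so no recordings of real washing
sessions are needed to train, test or benchmark the system. A session follows the natural timeline — walk in
(non-hygiene), wet hands under the faucet, rub with water, soap, rub
without water, rinse, close the faucet with the elbow, walk to the towel,
dry hands, walk off. Segment durations are truncated-normal with a 1 s
floor; the two rubbing actions are calibrated to duration statistics
measured on real washing sessions (16.40 ± 11.83 s without water,
13.72 ± 7.93 s with water;
their standard deviations exceed half the means, hence the truncation),
and the remaining actions use shorter defaults typical of a washing
session (faucet touches 3 ± 1 s, soap 4 ± 1.5 s, drying 8 ± 2.5 s,
non-hygiene blocks 8 ± 3 s). Sessions render at 224 x 224 and 30 FPS;
frames are produced lazily by deterministic motion programs, so identical
scripts and seeds give bit-identical videos and hour-scale sessions never
materialise in memory.

Each action is a distinct motion program with per-view geometry: the wall
view shows torso-scale silhouette motion near a sink (walking translation
for non-hygiene, an arm sweep for the elbow, hand oscillation at the
basin), the chest view shows close-up hand-region motion with
action-specific props (water band, soap blob, towel patch, faucet knob).
In the default `distinct` appearance mode the props also make classes
separable from single frames, which is what lets small static-frame CNNs
reach high accuracy quickly. Datasets are split at participant level
(defaults mirroring a 66/12/22 protocol), so no participant contributes to
both training and testing.

The `motion_only` mode is a controlled experiment: every class shares one
palette and geometry (two oscillating ellipses on a flat background) and
differs *only* in oscillation frequency. Each segment starts at a seeded
uniform-random phase; this matters because at a fixed frame rate a
rational frequency visits only a small discrete set of positions, and
without the random phase that lattice itself would identify the class from
a single frame. With it, the single-frame position distribution is
identical across classes by construction, so an RGB-only classifier cannot
beat chance on held-out data while the MHI stream — which sees motion
density — separates the classes easily. This is the package's built-in
demonstration that the MHI fusion captures genuinely temporal information.

What the generator does *not* emulate: photorealistic appearance, human
pose articulation, camera shake, illumination change, occlusions, or
inter-participant style variation beyond duration sampling. Passing tests
on this data therefore demonstrate that the pipeline's logic, training
loop and evaluation are correct and that the architecture can exploit the
intended cues; they do not certify real-world accuracy.

## Evaluation protocol

Rubbing actions are assessed by duration: the per-action Jaccard index
$J = |R \cap B| / |R \cup B|$ over ground-truth and predicted unit sets
(computed on unit sets, which equals the interval form when predictions
are contiguous; $J(\varnothing,\varnothing) = 1$ so an absent, unpredicted
action scores perfectly), plus the absolute duration error in seconds.
Soap, drying and the faucet actions are assessed by existence accuracy
across videos. Classifier quality is reported as frame- and unit-level
accuracy, and the dry-hands detector by precision/recall with dry frames
positive; when no positive is predicted, precision is reported as missing
with a warning, never silently zero. All metrics are pinned against
brute-force recomputations in the test suite.

## Problem sizes and numerical choices

The test suite trains the full system at desk scale: 40 training and 10
held-out test sessions (distinct participants) for the learned end-to-end
check, 24/8 sessions for the motion-only experiment, channel widths
(8, 16, 16, 32, 32), the `desk` preset, and two sampled frames per clip
(three for motion-only). The acceptance script uses 20 training and 6
test sessions. These sizes are the package's chosen balance between
statistical headroom and a comfortable single-CPU run; the easy
separability of `distinct`-mode classes means accuracy saturates well
below them.

Other fixed choices: BT.601 luminance weights for frame differencing;
area averaging for integer-factor downsampling (monotone, keeps MHI values
in $[0, \tau]$) and bilinear interpolation otherwise; batch-norm epsilon
1e-5 and momentum 0.1; He-style weight initialisation; the 288-dimensional
colour feature is the *joint* 8 x 3 x 3 value/hue/saturation histogram on
a 2 x 2 region grid (four marginal histograms would give 56 dimensions,
contradicting the 288 total, so the joint reading is the only consistent
one); HOG uses 9 unsigned orientation bins, 8 x 8 cells and L2-normalised
2 x 2 blocks; LBP uses uniform radius-1 8-neighbour codes (59 bins).
Expansion processes seed runs left to right, left side before right, which
fixes the (rare) order-dependent outcomes; the exhaustive rule-equivalence
test enumerates all $3^8$ coarse tracks against an independent simulator.

## Known limitations

* The synthetic world is geometric; no claim about transfer to real video
  is made or tested.
* The wall and chest views are assumed frame-aligned; no temporal
  registration is performed.
* One person per scene; streaming/online operation is out of scope.
* Optical-flow input streams are deliberately not implemented; the MHI
  stream is the package's only temporal feature, reflecting the selected
  design.
* The `vgg11_style` backbone is buildable and trainable but not exercised
  at full scale by the test suite; desk-scale checks use
  `small_backbone`.
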
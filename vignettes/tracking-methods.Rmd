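---
title: "Methods: kinematic tracking, posture, visual fields, and uniqueness-guided identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematic tracking, posture, visual fields, and uniqueness-guided identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(btx)
```

`btx` tracks many visually similar individuals in grayscale video and, when
kinematics alone cannot keep identities straight, corrects them with a
classifier trained on automatically selected, provably switch-free stretches
of the video. This vignette explains the models and the decisions behind
them; the README shows the workflow.

## Segmentation

A static background model is built by pixelwise `min`, `max`, `mode` or
`mean` over a uniform sample of frames; the mode uses the 8-bit histogram
with ties broken toward the larger (brighter) value, which favours the
background when dark objects pass through. Foreground is
`|frame - background| >= threshold` (default 25 gray levels, exposed as
`track_threshold`), optionally after scaling the frame so its global mean
matches the background's (`equalize_luminance`, for flickering lighting).
External binary masks ("individuals in white") replace the difference test
entirely when supplied. Connected components use 8-connectivity -- thin
diagonal extremities such as tail tips stay attached -- and components
outside `blob_size_range` are dropped. Each blob keeps the original
grayscale values of its pixels; everything downstream (splitting, posture,
identification) reads those, never the raw frame.

## Kinematic tracking

Per frame, each active trajectory predicts its next position with an
exponentially weighted mean of its last five velocities (half-life two
frames) rotated by the mean angular speed -- a cheap stand-in for a Kalman
prediction that handles curved paths. The probability that blob $b$
continues trajectory $i$ is a Gaussian kernel on the prediction error $d$
with a hard search radius,

$$p(i,b) = \exp\!\left(-\frac{d^2}{2\sigma^2}\right) \cdot
           0.5^{\,\mathrm{gap}/T_{\mathrm{reassign}}},\qquad
  \sigma = \tfrac{1}{3}\,v_{\max}\,\Delta t,$$

zero beyond $v_{\max}\Delta t$, where the gap is the time since the last
assignment in excess of one nominal frame. $v_{\max}$
(`track_max_speed`, px/s) is the one parameter worth tuning per dataset: it
should comfortably exceed the fastest plausible per-frame displacement
including turns (we use 8x the mean speed in the synthetic studies).

Edges below `matching_probability_threshold` (0.1) are dropped and the
bipartite graph decomposes into local cliques, matched independently:

* **tree**: depth-first branch-and-bound over trajectories sorted by best
  edge, exact optimum of the probability sum over conflict-free partial
  assignments, with an optimistic-bound prune and a node budget
  (`clique_node_cap`, 1e5);
* **hungarian**: Kuhn-Munkres with potentials on the zero-padded square
  matrix -- the fallback when the tree search exceeds its budget, and an
  independent route to the same optimum;
* **approximate**: greedy per blob, never better than the optimum; for
  extreme densities only.

Ties everywhere resolve toward the lower identity index, then the lower
blob position, so reruns are bit-identical. Assignment uncertainty is
$1 - p$; a new *segment* opens when it exceeds 0.5, when the individual was
lost for at least one frame, or when the inter-frame timestamp exceeds 1.5x
the running median interval. Lost individuals stay eligible for
re-assignment for `max_reassign_time` (0.5 s), then retire; in known-count
mode new identities are created only while fewer than
`track_max_individuals` are active.

When fewer blobs than recently present individuals appear and several
predictions land on one blob, that blob is re-thresholded in steps of one
gray level until at least the expected number of similarly sized components
emerges (each at least 60% of the median component size -- one concrete
reading of "similarly sized"); pixels lost to the higher threshold are
re-attached to the nearest surviving component so no evidence is discarded.
Pixels lost to the higher threshold are regenerated by growing the
surviving components in order of decreasing background difference, so the
dividing line settles in the intensity valley between the bodies.  If no
threshold up to 254 separates the blob it is flagged unsplittable, nobody is
assigned to it, and the involved individuals stay lost until they separate
-- shaded bodies split reliably, flat-intensity overlaps do not, and
pretending otherwise would corrupt trajectories.

## Posture

Outlines are traced along pixel *cracks*, clockwise, with vertices at
integer pixel corners; a single pixel is a unit square, and the shoelace
area of the polygon equals the pixel count exactly for simply connected
masks (that identity is a test). Smoothing is either a truncated elliptic
Fourier series -- `n_efd = 2` keeps one harmonic and is exactly an ellipse
fit, the default 8 keeps seven -- or a circular triangular moving average.
The pointiest vertex (largest turning angle over a window of 5% of the
perimeter, discounted by the normalized enclosed triangle area) is the tail
by default (`pointiest_is`); the head is the vertex at maximal arc
distance. Near-circular shapes have no meaningful endpoints: they are
flagged ambiguous, posture is still returned, and the visual field refuses
them. The midline walks two cursors from the head along both outline
directions in steps of equal arc length with 25% wiggle room, choosing the
step pair that minimizes the left-right chord; midpoints form the midline,
chord lengths the thickness profile, resampled to `midline_resolution`
(25) points. On a 100x20 rectangle this recovers length within 5% and
thickness within a pixel or two -- note that elliptic smoothing should be
off for polygonal test shapes, since it rounds corners into an ellipse
whose extremes move.

Identification crops are pose-normalized: a rigid map puts the head at a
fixed anchor (25% from the left, vertical centre) with the initial midline
direction along +x, sampled bilinearly, background zeroed. A
`normalized_zoom` magnification (default 1.6 for 30-px bodies) makes the
body fill the crop; without it, down-sampling for the classifier destroys
the texture signal. When the midline fails the crop falls back to
image-moment alignment (`0.5 atan2(2*mu11, mu20 - mu02)`, defined only up
to 180 degrees -- the flip ambiguity is why posture normalization exists).

## Visual fields

Eyes sit `eye_offset_ratio` (0.1) of the midline length behind the snout,
offset laterally by `eye_separation_ratio` (0.9) of half the local
thickness, gazing sideways; `eye_rotation` tilts the gazes forward. With a
260-degree field of view per eye the two fields overlap in a frontal and a
rear binocular region totalling `2*260 - 360 = 160` degrees. Rays are cast
at the centres of `rays` (512) angular bins relative to the body axis;
intersections with every outline polygon, the focal individual's own
included, are sorted by distance, and the first hit per distinct occluder
fills occlusion orders 1..`max_orders`. Channels per bin: occluder
identity, distance (px), and body part hit (arc percent from the
occluder's head). Own-body hits closer than the local body thickness at the
eye are ignored -- the eye sits on the body surface and its immediate
surroundings are below the line of sight; without that rule every forward
ray would first exit through the focal body and the entire first-order
field would be self.

## Visual identification

Trajectories are cut into *consecutive segments* at every problematic event
(lost, uncertainty > 50%, timestamp gap); within a segment the tracker is
assumed switch-free. Frames where every individual sits inside one segment
form *global segments* -- the only safe source of training labels. Their
quality is the minimum over individuals of grid-cell transitions (spatial
coverage on a 10-cell-wide grid scaled to the arena aspect; a tightly
circling individual scores low even with a large distance travelled) and
the average sample count; candidates are binned by middle frame into video
quarters, the best four per bin kept, and bins interleaved round-robin.

Training quality is monitored by per-frame *uniqueness*: each tracked
object claims its argmax identity, collisions shrink the unique fraction,
and the score is

$$U(x) = \frac{|\mathrm{uids}|}{|f(x)|}\; E\!\left(\overline{p}\right),
 \qquad E(v) = \frac{1 + e^{-\pi}}{1 + e^{-\pi v}},$$

evaluated on evenly spaced frames; $U = 1$ exactly when all claims are
distinct with probability 1. The initial unit trains on the best candidate
(classes balanced to ~1.2x the smallest class, 4:1 train:validation,
categorical focal loss, Adam, at most 150 epochs, stopping on plateau at
high accuracy / overfitting / perfect training accuracy). Accumulation then
repeatedly picks the next candidate by (uniqueness rounded to 5% steps,
valleys first; distance to trained regions rounded down to a power of two;
coverage; samples), requires predicted identities to be unique across
individuals before trusting them, sub-samples prior segments with a stride
that caps each one's contribution under the memory budget (1 GB of
nominal crop bytes), retrains, and keeps the result only if mean uniqueness
stays within 99% of the best; after five steps candidates below half the
previous best uniqueness are disqualified. Training stops when mean
uniqueness exceeds $1 - 0.5/N$ or every identity's uncovered frames drop
below 25% of the video; a final unit refits on everything (no held-out
validation, at most `max(3, 0.25 * max_epochs)` epochs) and is kept only if
uniqueness improves.

Assignment averages predictions per consecutive segment (after splitting at
persistent running-median identity changes, window 25 frames). When
overlapping segments claim the same identity, the ratio of their maximal
probabilities (inverted into (0,1]) above 0.6 defers the conflict to the
kinematic tracker; below, the winner maximizes
$S(p, x) = \mathrm{sig}(p) + \mathrm{sig}(x)$ with
$\mathrm{sig}(x) = (1 + e^{2\pi(0.5 - x)})^{-1}$ and $x$ the relative
sample count -- long segments with slightly weaker probabilities beat short
noisy ones. Four robustness rules proved necessary and are deliberate
design choices: pieces with fewer than `min_claim_images` (25, the
switch-detection window) crops never claim identities themselves -- a short
crossing fragment's averaged vector is noise, and one noisy claim can defer
a 300-frame correct piece through the ratio rule; deferred or unclaimed
pieces inherit only from assigned pieces of the *same* consecutive segment,
never across lost/uncertain/timestamp boundaries, which is exactly where
switches happen; fragments that can neither claim nor inherit are omitted
from the corrected table (and listed in the segment report) instead of
carrying made-up labels; and candidates that fail the plausibility check
re-enter the queue behind untried ones rather than being retried
immediately.

With visually identical individuals (`texture_contrast = 0`) the initial
unit cannot beat chance and the pipeline terminates with an explicit
`failed` status -- identities are never silently shuffled.

## The classifier backend

The backend contract is minimal: `fit(X, y, ...)` and `predict(X)` with
softmax rows summing to 1, deterministic given a seed, plus
`get_state`/`set_state` for the accept/reject snapshots. The shipped
reference backend is a linear softmax on 32x32 block-averaged crops scaled
to [-1, 1] (`x/127.5 - 1`), trained full-batch with Adam on the categorical
focal loss (gamma 2), with internal feature centring for conditioning and
optional one-pixel x-shift augmentation. It fits in seconds on a CPU and
reaches ~98% held-out per-image accuracy on eight textured synthetic
agents; because assignment averages over whole segments, segment-level
accuracy is effectively 1 at that level. A convolutional network honouring
the same contract can be substituted without touching the accumulation
machinery. 16x16 inputs, tried first, lose the texture signal of 30-px
bodies -- hence the 32x32 default and the crop zoom above.

## The synthetic scene generator

Agents are correlated random walks (clipped-normal speeds, normal heading
increments, reflecting borders) rendered as teardrop bodies -- blunt head,
pointed tail, so the posture module's default `pointiest_is = "tail"` is
correct -- carrying a per-identity texture in body coordinates (so it
rotates with the animal and survives pose normalization). The first eight
identities form a binary attribute code over lateral stripe frequency,
stripe phase and mean shade, making any two strongly separable whenever
`texture_contrast` exceeds the pixel noise; at `texture_contrast = 0` all
agents are pixel-identical by construction. Crossings are Poisson-scheduled
steering events at `overlap_rate` per agent-minute: the two agents head
straight at each other and momentum carries them through, so contact stays
brief as in a real crossing; outside events a soft repulsion keeps pairs
separated, so "no crossings" scenes are structurally clean rather than
lucky. Visibility is a two-state Markov chain (hide with
`disappear_prob`, reappear with `0.25 (1 - disappear_prob)`). Bodies are
rendered so their pixel centroid coincides with the ground-truth
coordinate.

What the generator does *not* emulate: body bending (agents are rigid, so
posture normalization is easier than for a turning fish), shadows,
reflections, lighting drift, camera distortion, and appearance change over
time. Passing tests therefore demonstrate the correctness of the machinery
under the stated statistical structure, not performance on any particular
real video.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty masks and all-zero frames
error or warn; single pixels trace to unit squares; isotropic blobs return
orientation 0 with an ambiguity flag; circles flag ambiguous endpoints;
vertex-exact ray hits count once. All randomness flows from explicit seeds
(scene seed, backend seed); library code saves and restores the caller's
RNG state.

The test-suite study sizes: clean-scene tracking uses 4 agents x 120
frames; the identification acceptance scenario uses 8 agents, 1500 frames
at 25 Hz in a 360-px arena, 30x10-px bodies, crossing rate 6 per
agent-minute (~38 contact events), disappearance probability 0.002 -- large
enough that the kinematic tracker makes genuine mistakes (similarity ~0.45
against truth) which identification repairs to >= 0.99. Matcher optimality
is checked against factorial enumeration on 500 random cliques up to 7x7,
and the uniqueness and Eq.-2 scores against direct evaluations of their
definitions.

## Known limitations

Identities beyond eight reuse texture attributes with only a frequency
shift, so very large groups are less separable than real animals would be.
The linear backend is texture-driven: it cannot exploit subtle shape cues a
CNN would find. The 2D visual field inherits the usual planar limitation:
every body is an occluder, with occlusion orders as the only mitigation.
The container stores 8-bit grayscale, single channel, and offsets below
2^53 bytes.
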
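---
title: "Models and methods behind blurtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind blurtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

blurtrack analyses long-exposure night imagery of low-flying insects.
This vignette explains the underlying models, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
design decisions taken where more than one reasonable choice existed.

## The image model

Under a night exposure of duration $T$ (typically $1/9$ s for stills,
one frame interval for video) with an infra-red flash, a flying insect
traces a bright streak across a dark, noisy background. Three
assumptions drive everything downstream:

1. **Simple paths.** Within one exposure the flight path is well
   described by a low-order polynomial of time per axis (order $\le 2$).
   This justifies inferring the streak's path by polynomial regression
   and is the reason a second-order fit is the default.
2. **Bright on dark.** Streak pixels are far brighter than the
   background, so a robust global threshold (median $+ k\cdot$MAD)
   separates them.
3. **Wingbeat photometry.** The insect's apparent brightness is
   modulated at its wingbeat frequency $f_w$; a streak traversed at
   roughly constant speed therefore carries $f_w T$ intensity cycles
   along its arc.

## Geometry

Coordinates follow the VIA pixel convention: $x$ is the column, $y$ the
row, origin at the centre of the top-left pixel, 0-based, sub-pixel
positions allowed (the convention is a package choice; annotation tools
agree on it in practice). All point-to-segment distances are exact
(projection clamped to the segment).

The linking cost between two polylines $P_a$ (vertices $a_0 \dots
a_{n-1}$) and $P_b$ (vertices $b_0 \dots b_{m-1}$) is the **matching
distance**: the second-smallest element of the multiset

$$\{\,d(a_0,P_b),\; d(a_{n-1},P_b),\; d(b_0,P_a),\; d(b_{m-1},P_a)\,\}.$$

Two blurs that continue one another share (or nearly share) two of these
four endpoint distances at zero, while two blurs that merely cross at an
angle keep all four large. The rank statistic is well defined under ties,
and the function is symmetric — but deliberately **not a metric**: two
distinct streaks that abut end-to-end score 0, which is precisely the
tracking-relevant notion of "continuation". The Hausdorff distance (used
for evaluation only) is computed by resampling both polylines at a 0.5 px
arc-length step and taking exact point-to-polyline distances from each
sample set; exact polyline Hausdorff computation would require a
segment-arrangement analysis that annotation-scale accuracy does not
justify, so results carry a documented $\pm 0.5$ px bound.

## The detector

The detector is a deterministic classical pipeline standing behind the
same contract a learned instance-segmentation backend would use (masks
in, scored annotations out), so a trained model can replace it without
touching anything downstream.

* **Binarization**: background median and MAD are estimated on a
  stride-4 pixel subsample (the noise is i.i.d. and streaks are sparse,
  so the subsample is statistically equivalent and four times cheaper);
  threshold $= \mathrm{median} + k \cdot \mathrm{MAD}$ with $k = 8$ —
  far enough into the Gaussian tail that false pixels are essentially
  impossible at typical noise levels. A uniform frame (zero MAD) yields
  zero detections by definition rather than an error.
* **Morphology and labelling**: closing with a disc of radius 1 px
  bridges 1 px gaps at modulation troughs; components are 8-connected
  (4-connected labels merged across diagonal adjacencies); components
  under `min_area` (20 px) are discarded.
* **Polyline inference**: mask pixels are rotated into their
  principal-axis frame (largest coordinate variance; isotropic ties
  break toward the x-axis, sign fixed toward $+x$ for determinism), a
  polynomial $v = \sum_k c_k u^k$ is least-squares fitted and evaluated
  at 10 equally spaced positions. If the mask supports fewer distinct
  abscissae than `order + 1` the order falls back; a single-abscissa
  mask raises a typed degenerate-mask condition and the caller falls
  back to a point annotation.
* **Classification**: border-touching masks (within 2 px of the edge)
  become circle annotations — the blur may be clipped, so its path
  cannot be trusted — using the exact minimum enclosing circle (Welzl on
  the convex hull). Interior fits shorter than `min_polyline_length`
  (10 px; the "too short to show a wingbeat" threshold, a package
  default since no canonical value exists) become points at the mask
  centroid.
* **Score**: $(\overline{I}_{on} - \mathrm{median}_{bg}) / (255 -
  \mathrm{median}_{bg})$, clipped to $[0,1]$. $\overline{I}_{on}$ is the
  mean frame intensity sampled along the mask's fitted centerline, not
  the mask-pixel mean: the segmented mask necessarily includes the
  streak's anti-aliased rim, whose half-bright pixels would cap even a
  saturated streak's mask mean near 200 (score $\approx$ 0.78). The
  score is meant to measure the streak, and a saturated streak should
  score 1; sampling the centerline achieves exactly that while keeping
  the score monotone in contrast. RGB input collapses to grayscale by
  channel maximum by default (streaks are near-white under IR flash;
  Rec. 709 luminance is available).

## Tracking

A batch of $N$ frames yields $N-1$ pairwise maximum images; detection
runs on those, so one insect's consecutive blurs overlap and successive
detections share half their extent (matching distance $\approx 0$).
Linking solves the linear sum assignment problem with a shortest
augmenting path / dual potential algorithm in the Jonker–Volgenant
family, implemented in the package and verified against exhaustive
permutation search in the tests. Rectangular cost matrices are squared by
padding with the threshold cost so that "start a new trajectory"
competes fairly with an expensive link; after solving, links with
$d_M$ strictly above the threshold are removed (a link exactly at the
threshold is kept — "above ... removed" reads as strict).

Defaults: `dM_threshold` 40 px at 1080p (no canonical value exists; it
scales with frame size and flight speed and is configurable),
`min_detections` 3 and `min_mean_score` 0.8 (the conventional filter
values for this pipeline). Filters are applied in a pinned order —
length, then score, then region of interest — for reproducible stage
logs; the result is order-independent because each filter is a pure
predicate. Circle and point detections never participate in linking
(the matching distance is defined on polylines only); each forms a
singleton trajectory that the length filter then removes. Trajectories
never bridge across batches: a clip is one batch, bounded by memory.

The ROI filter keeps a trajectory iff every polyline vertex lies at
distance $\le r$ (inclusive) from the ROI centre; convexity makes the
vertex test sufficient for whole segments. Displacement direction
orients each detection chain consistently (each detection's start is the
endpoint nearer the previous oriented end, the first is oriented toward
the second's chain) and reports $\mathrm{atan2}(\Delta y, \Delta x)$ in
image coordinates, degrees in $(-180, 180]$; conversion to compass
bearings needs the camera orientation, which is field metadata the
package does not see.

## Wingbeat estimation

The intensity profile along a polyline is sampled at 1 px arc steps,
averaging `width` (default 3, the typical blur width) bilinear samples
along the local normal. The cycle counter detrends with a centred moving
average (window $=$ arc length / 4, clamped $\ge 8$ px, partial at the
edges), applies a Hann window, and reads the peak of a zero-padded
periodogram with parabolic interpolation between bins;
`n_cycles = arc_length × peak frequency` and
`wingbeat_hz = n_cycles / exposure`. Frequencies below 1.5 cycles per
profile are excluded from the peak search: less than about one full
cycle cannot be counted, and the detrend makes slower content
unreliable. Confidence is the fraction of detrended power inside the
peak's main lobe; below 0.2 the profile is flagged `no_periodic_signal`
rather than raising an error. The estimator is deliberately minimal and
isolated behind `count_cycles()`, so a more elaborate procedure (e.g.
one correcting for body length or turning points) can replace it without
interface changes. Estimation is only attempted on polylines — circles
and points mark blurs that are clipped or too short to carry a readable
wingbeat, which is the annotation scheme's point.

Exposure time comes from the EXIF `ExposureTime` rational when present,
else from configuration; a missing exposure is a hard error because the
cycles-to-Hz conversion is meaningless without it.

## Evaluation

Matching is greedy in descending prediction score with bounding-box IoU
$\ge$ 0.5 (one-to-one; standard detection-evaluation practice — the
matching rule has no canonical alternative worth the complexity of
optimal matching at these densities). Matched polyline pairs additionally
report the Hausdorff distance and the signed length difference
(prediction minus truth; the sign convention is pinned and documented).
Circle or point predictions may match polyline truths via IoU — shape
kinds legitimately differ near frame edges — but path metrics are
reported only for polyline-polyline pairs. A `bbox_pad` option pads both
sides' boxes before IoU: a perfectly straight centreline polyline has a
zero-area box, and padding by the physical blur half-width restores a
meaningful overlap test. Precision is 1 by convention when no
predictions survive a threshold; recall is 0 when there is no ground
truth.

## The synthetic generator

The generator renders what the pipeline assumes: 1080p night frames
(Gaussian background, level 10, sd 2), anti-aliased streaks of width 3 px
along order-$\le 2$ paths, intensity modulated as a raised sinusoid
$I(t) = \mathrm{baseline} + \mathrm{amplitude}\,(0.5 + 0.5\sin 2\pi f_w
t)$ so the blur never goes fully dark and the rendered cycle count is
exactly $f_w T$. Stills default to $T = 1/9$ s; sequences run at 30
frames/s with $T = 1/\mathrm{fps}$, which makes consecutive blurs abut
end-to-end — the geometric fact the tracker exploits. (A still exposure
of 1/9 s is longer than a 30 fps frame interval; the
exposure-vs-frame-rate constraint therefore applies only to sequences.)

The clean preset draws speeds uniformly in 100–1500 px/s floored so each
per-exposure blur is at least 12 px (shorter blurs are point annotations
by the package's own rules and can neither carry a wingbeat nor link),
headings uniformly, gentle curvature (stills: sag up to 5% of the chord;
sequences: accelerations up to 20 px/s²), wingbeats in 20–80 Hz, and
near-saturated contrast (baseline 180–220, amplitude $255 -$ baseline):
IR-flash moths render near-white, and the conventional 0.8 score filter
presumes captures of that quality. Rejection sampling enforces that each
track passes through the view once with at least 8 fully-interior
frames, and that no two tracks approach within 80 px (twice the linking
threshold) at time offsets up to 0.1 s — offsets matter because a
follower insect at a small lag could otherwise place blurs within
linking range of the leader's inside a maximum image. The hard preset
drops the separation constraint and lowers contrast.

What the generator does **not** emulate: Poisson/shot noise and hot
pixels (the background is Gaussian, adequate for 8-bit night frames),
photometric wing-glint structure beyond the raised sinusoid, defocus,
lens distortion, rolling shutter, occlusions by vegetation, and
heterogeneous backgrounds (stars, clouds). Green tests on clean synthetic
scenes therefore demonstrate algorithmic correctness — geometry,
assignment optimality, bookkeeping, signal recovery under the stated
image model — not field-grade robustness; a learned detector slotted
into the same interface is the expected path to the latter.

## Numerical choices and degenerate inputs

* Assignment costs must be finite and non-negative; the padded square
  uses the threshold cost (or max cost $+1$ when the threshold is
  infinite, where the pad value provably cannot change the retained
  links).
* Welzl's recursion runs on convex-hull vertices in deterministic order;
  collinear boundary triples fall back to the farthest pair.
* The periodogram zero-pads to $2^{\lceil \log_2 8n \rceil}$ so the
  frequency grid is at least 8 times finer than the resolution limit
  before parabolic refinement.
* VIA coordinates serialize with 17 significant digits, making
  write-then-read the identity on IEEE doubles; unknown file sizes are
  $-1$ internally and 0 on disk (VIA keys need a number), mapped back on
  read.
* Ties everywhere (sorting detections, principal-axis signs, greedy
  matching) are broken by fixed deterministic rules so identical inputs
  give bit-identical outputs.

## Problem sizes used in the test and acceptance suites

The shipped suites exercise: 1000 random polyline pairs against an
independent minimization oracle; 500 random cost matrices up to 7×7
against exhaustive permutations; 20 clean 150-frame clips at 854×480
(the 1080p geometry scaled to 480p, with speeds scaled accordingly) with
5 insects each for tracking; 100 clean 1080p stills with 1–5 streaks of
30–300 px chord for the detector; and 200 streaks of 3–10 cycles and
120–400 px arc for wingbeat recovery. These sizes make the full suite
run in minutes on a single CPU while keeping every statistical check
comfortably powered.

## Known limitations

* The wingbeat estimator assumes roughly constant traversal speed along
  the blur; strong acceleration within one exposure smears the
  periodogram peak.
* Trajectories split at occlusions or missed detections are not
  repaired (accepted behaviour; the ROI filter often removes them).
* d_M-based linking cannot involve circle/point annotations, so an
  insect detected only near the frame edge is never tracked.
* JPEG pixel data is not decoded (PNG/TIFF are); EXIF exposure can still
  be read from JPEG files.
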
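---
title: "Methods: detection, tracking and integrative motility analysis in cellmotr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, tracking and integrative motility analysis in cellmotr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cellmotr analyses the motility of cells — T lymphocytes in particular — in
co-registered multi-channel 2D time-lapse microscopy. This vignette is the
package's account of the science: the models and procedures implemented,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was open.

## The analysis problem

Leukocytes move fast (upwards of 10 µm/min), switch between attached and
unattached motility, and are heterogeneous within a population. Studying
this requires following each cell through time and attaching per-cell
information from several image channels to its track: a transmitted-light
channel (bright-field, DIC or phase contrast) in which every cell presents
some boundary contrast even in crowds, an interference-reflection channel
(IRM) in which close cell–glass apposition appears dark and reports the
attachment footprint, and up to two fluorescence channels carrying vital-dye
labels or probe signals. The channels share one field of view, so positions
found in the transmitted channel index directly into the others.

A central practical obstacle is that IRM series have spatiotemporally
drifting background and foreground intensities, which rules out global
thresholding. cellmotr therefore never segments a whole frame: each tracked
centroid gets a small local box in each secondary channel and segmentation
happens inside that box only.

## Detection: Canny edges + circular Hough voting

Cells in transmitted light are roughly circular with edge contrast at their
boundary, so detection looks for circle-like edge patterns rather than
intensity blobs:

1. **Canny edge extraction** (`compute_edge_map()`): Gaussian smoothing at
   `canny_sigma` (default 2 px), Sobel gradients, non-maximum suppression
   along the quantised gradient direction, hysteresis thresholding with
   `canny_low`/`canny_high` (defaults 0.1/0.25) applied to the gradient
   magnitude *normalised by its frame maximum*, which makes the edge map
   invariant under affine intensity changes.
2. **Gradient-directed circular Hough transform** (`circular_hough()`):
   every edge pixel casts votes along both senses of its gradient direction
   at offsets `radius_min..radius_max` (defaults 6–18 px). Voting along the
   gradient only — not around full circles — costs O(edge pixels × radii)
   and matches how radial symmetry detectors are usually implemented. A
   circle centre accumulates votes from its entire boundary, so detection
   survives partial, non-contiguous edges, which is exactly what low-contrast
   or touching cells produce. The accumulator is smoothed with
   `accumulator_sigma` (default 2 px).
3. **Centroid selection** (`select_centroids()`): local maxima with votes at
   or above `vote_fraction` (default 0.35) of the global maximum are
   accepted greedily in descending vote order, suppressing any candidate
   within `maxima_min_separation` (default `radius_min`) of an accepted one.
   The suppression radius is what lets one imperfectly circular (polarised)
   cell yield a single detection instead of several. Ties are processed in
   raster order so results are deterministic. The per-detection radius is
   the radius collecting the most votes near the peak.

Images whose cells do not fit the default radius range should be resampled
with `scale_factor` rather than re-tuned: detection runs at the rescaled
resolution and centroids are mapped back to original coordinates. No
sub-pixel refinement is attempted; tracking tolerates the ≤ 2 px
quantisation this leaves.

Numerical notes: Gaussian smoothing uses replicate (not circular) boundary
handling — FFT wrap-around would invent edges at frame borders — and a
gradient-magnitude floor of 1e-9 keeps FFT round-off on constant frames
from being mistaken for structure.

## Tracking: confident segments, then global joining

Tracking is two-tiered, trading a cheap greedy pass for a global
optimisation only where the greedy pass is unsure.

**Tier 1, nearest-neighbour linking** (`link_nearest_neighbor()`): a segment
end at frame *t−1* is extended to a detection at frame *t* only when that
detection is the single candidate within distance `r` (default 30 px) *and*
the end is the single segment competing for it. Any ambiguity terminates the
involved segments and opens fresh one-point segments at the contested
detections. Segments are therefore frame-contiguous stretches over which
identity is essentially certain.

**Tier 2, segment joining** (`join_segments()`): a similarity in [0, 1] is
computed for every ordered segment pair (a, b):

- infeasible (0) if b starts at or before a's end, the frame gap exceeds
  `max_gap` (default 4), or the end-to-start distance exceeds
  `v_max × gap`;
- otherwise `w_time·s_time + w_space·s_space + w_speed·s_speed` with
  weights (0.25, 0.5, 0.25), where `s_time = 1 − (gap−1)/(max_gap−1)`,
  `s_space = 1 − d/(v_max·gap)`, and
  `s_speed = 1 − |v̄_a − v̄_b| / max(v̄_a, v̄_b)` compares mean per-frame
  displacements. A single-point segment has no speed of its own, so
  `s_speed` takes the uninformative value 0.5 there.

The Hungarian algorithm (via `clue::solve_LSAP`) solves the
predecessor-by-successor assignment, augmented with per-predecessor "no
join" columns valued at `join_threshold` (default 0.4) so the assignment
itself can reject weak continuations; accepted pairs additionally must
exceed the threshold strictly. Accepted joins are chained transitively.
Joined tracks keep their frame gaps — interpolated positions would bias
speeds — and all motility arithmetic divides by the actual elapsed time.

`v_max` defaults to 1.5 × the 95th percentile of per-step displacements.
These displacements are observed as *consecutive-frame nearest-neighbour
distances over all detections*, not as within-segment steps: segment steps
are censored at `r`, and a bound estimated from them would shrink exactly
when `r` is small — the regime in which joining must bridge what linking
could not. The nearest-neighbour form is independent of `r`, which is what
makes tracking accuracy robust across a wide band of `r` values.

Tracks shorter than `min_track_len` (default 5 frames) are discarded.
Manual corrections are applied by `edit_tracks()` from a split/join list,
splits before joins.

## Feature extraction: local segmentation per track position

For every track point a square box of half-size 2.5 × `radius_max`
(default 45 px) is cropped in each requested channel
(`crop_local_box()`), clipped at borders with offsets recorded so outlines
map back to global coordinates.

**Reflection and fluorescence** (`segment_local_intensity()`): Otsu's
threshold splits the box; the foreground is the sub-threshold (dark) class
for IRM and the supra-threshold class for fluorescence. Two refinements
matter in practice:

- the threshold is estimated from a centre subwindow of the box (the
  tracked cell sits at the centre by construction), so a bright neighbour
  elsewhere in the box cannot dominate the histogram and hide a dim cell of
  interest;
- an Otsu split of pure background noise is rejected by requiring the
  foreground/background mean contrast to exceed `min_contrast` (default
  0.08 intensity units) — IRM footprints and dye disks are far above this,
  noise partitions far below.

The watershed transform of the foreground's distance map separates touching
cells, and the region whose centroid lies nearest the box centre (within
`max_center_distance`, default `radius_max`) is kept. Contact area is the
mask pixel count × pixel area; a footprint below `min_area_um2` (default
3 µm², matching the few-micron scale of real contacts) counts as noise, not
attachment. A track is attached if *any* of its positions is. Mean dye
intensity is the plain mean under the mask; note that Otsu tends to choose
slightly high thresholds on fluorescence, biasing the mask toward bright
pixels and hence the mean slightly upward. This known bias is left in place
deliberately — correcting it would make the reported values incomparable
with the standard procedure.

**Transmitted light** (`segment_local_transmitted()`): Canny edges in the
box are voted through the circular Hough transform; the edge-enclosed
foreground (morphological closing of the edges, hole filling) is split into
per-cell territories grown from accumulator peaks, and the largest region
whose centroid is admissible is the cell. Because the boundary-relief band
is smoothed by `canny_sigma`, its outer hysteresis edge sits about
`canny_sigma + 1` px outside the true boundary; the filled mask is eroded
by that much. Aspect ratio — the polarity readout — is the ratio of the
major to minor axis of the mask's second-moment ellipse; masks under 5 px
or degenerate (collinear) masks yield no value. Moment ellipse was chosen
over Feret-type measures because it is differentiable against the
generator's ground truth and standard in shape analysis; its accuracy is
fair rather than excellent, consistent with how polarity readouts from
transmitted light generally behave.

Cell types are assigned per track from the mean dye ratio
`(fluor1 + ε)/(fluor2 + ε)`: at or above `ratio_high` (default 2) type A,
at or below `ratio_low` (default 0.5) type B, otherwise unassigned.

## Motility characteristics

Per step: instantaneous speed (µm/min, actual Δt) and turn angle (degrees
in [0, 180], undefined when either displacement is numerically zero). Per
track: mean speed, median turn angle, arrest coefficient (fraction of
instantaneous speeds strictly below 0.5 µm/min, the conventional threshold
for arrested T cells), confinement index, path length, net displacement.
The confinement index is defined as net displacement divided by path
length, in [0, 1] with 1 = perfectly straight; of the variants in use this
one is bounded and testable, and the package documents rather than hides
the choice. Group tables normalise population medians to a named control
group, the usual heat-map representation for perturbation panels; a zero
control median yields a ratio of 1 only for exactly-zero group medians and
NA otherwise.

## Evaluation (SFDA / ATA)

Ground truth is a set of per-frame bounding boxes grouped into tracks
(ViPER-dialect XML). Detections become boxes as the axis-aligned square of
side 2 × radius. Frame detection accuracy is the Hungarian-matched Jaccard
sum normalised by the average object count; SFDA averages it over frames
where either side has objects. Track pair scores average per-frame Jaccard
over the union of the two tracks' frames (gaps contribute 0 to the
numerator but stay in the denominator); ATA is the Hungarian-matched pair
score sum over the average track count. The thresholded variant counts a
per-frame Jaccard of 0.4 or more as 1, so a well-matched but slightly
offset track is not penalised for localisation jitter; both raw and
thresholded values are always reported. Feature extraction is evaluated by
per-frame centroid matching (Hungarian, gated at `radius_max`) against
ground-truth features, reporting per-pair absolute and relative errors and
the median absolute relative error per feature.

## The synthetic movie generator

`synth_movie()` renders movies with exhaustive ground truth so that every
stage is testable without external data. Defaults emulate chemokine-driven
T-cell chemokinesis on a 225 µm square field: 512 px at 0.439 µm/px,
33.3 s frame interval, 30 cells, two vital-dye-labelled populations mixed
1:1 with mean speeds 5 and 10 µm/min (log-normal between-cell spread 0.25,
within-track step spread 0.35), half of the cells attached with contact
footprints around 20 µm².

Motion is a persistent random walk whose heading increment SD shrinks
exponentially with relative step speed (`speed_turn_coupling`, default
−1.2), reproducing the amoeboid alternation of fast straight runs and slow
turns and hence an inverse speed–turn-angle correlation. Boundaries reflect
the *heading* and retake the full step, so realised chord lengths equal the
programmed ones (folding the position would systematically slow fast
cells); a soft pairwise repulsion maintains `min_separation_px` (default
36 px = 2 × `radius_max`), keeping the default density in the
well-separated regime. Rendering: transmitted = mid-gray background,
slightly dark elliptical bodies (per-cell aspect up to 2, oriented along
the heading) with a bright boundary ring; reflection = slowly drifting
background with dark irregular (wobbly-radius) blobs whose *drawn pixel
count* is recorded as the ground-truth area; fluorescence = per-type disk
intensities; Gaussian noise (SD 0.015) everywhere, then quantisation to the
16-bit grid so TIFF round-trips are bit-exact. Identical parameters and
seed give bit-identical movies.

What the generator does **not** emulate: optics (no DIC shear shading, no
IRM interference fringes), photobleaching, cell division, entry/exit
through field borders, shape dynamics beyond a fixed per-cell ellipse, and
genuinely overlapping cells at default density. Tests passing on generator
movies therefore demonstrate the pipeline's logic and calibration handling,
not robustness to every artefact of real microscopy; the detection and
local-segmentation stages are the components most flattered by the clean
rendering.

## Problem sizes and runtime choices

The shipped test-suite studies use sizes chosen to exercise the statistics
without waste: the feature-accuracy study uses 30 cells × 50 frames; the
detection study 20 cells × 100 frames; the link-radius robustness sweep 50
cells × 40 frames across r ∈ {15, 22.5, 30, 37.5, 45} px; parameter
recovery pools four 30-cell × 40-frame movies (≥ 100 tracks). Brute-force
voting oracles run on 64 × 64 instances; exhaustive assignment oracles on
up to 6 segments / 4 tracks, where enumeration is exact.

## Known limitations

- The nearest-neighbour tier degrades at high density or very long frame
  intervals; the joining tier compensates only within `max_gap` frames.
- Aspect-ratio accuracy is moderate; treat it as a relative polarity
  readout, not a morphometric measurement.
- Fluorescence means inherit the Otsu high-threshold bias described above.
- Segment joining considers position, time and speed but not appearance;
  two cells of identical speed crossing during a mutual detection gap can
  still be swapped.
- The statistical comparison of populations (rank tests, correlations) is
  intentionally out of scope; the per-track summary tables are written so
  any statistics package can consume them.
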
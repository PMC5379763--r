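---
title: "Segmenting and analysing dense bacterial colony movies with bactrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and analysing dense bacterial colony movies with bactrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Time-lapse microscopy of growing bacterial micro-colonies ("cell movies")
records how single rod-shaped cells elongate, divide and pack into dense
two-dimensional communities, possibly several colonies per field of view
that can grow into each other and merge. Extracting per-cell measurements
from such movies requires (i) finding the colonies, (ii) cutting each
colony's foreground into single cells even when hundreds of cells touch,
(iii) linking cells across frames into lineage trees, and (iv) turning the
per-frame measurements into growth statistics. `bactrace` implements this
pipeline end to end and ships a synthetic-movie generator with exact ground
truth so that every stage can be validated quantitatively.

## Pipeline and model

**Preprocessing.** Frames are denoised with an a-trous (starlet) stationary
wavelet decomposition and BayesShrink soft thresholding, then contrast is
equalized with CLAHE (clip limit 0.01, 8x8 tiles by default). The denoiser
is deliberately pluggable (`denoise(method =)`): any edge-preserving noise
suppressor satisfies the downstream contract, and `"none"` slots in an
external tool. The fluorescence channel, when present, is never
preprocessed, so intensity measurements stay raw.

**Colony masks and tracking.** A rolling-ball (morphological
closing/opening with a disc of 5x the cell width) background estimate
flattens illumination; the colony mask is the union of the Otsu foreground
of the background-corrected frame (computed on the deviation from the
median level, so dark cell bodies and bright halos both count) and filled
Canny contours, followed by closing and hole filling. Colonies are matched
across frames by the centroid-in-bounding-box rule; two previous centroids
inside one current box mean the colonies merged (surviving track =
lowest id, history retained), an unmatched current colony is new, an
unmatched previous colony has left the field. The one ambiguity the rule
leaves open - one centroid inside two boxes - is resolved by maximal mask
overlap.

**From colonies to cells.** Inside each colony the foreground is recovered
by adaptive (local-mean) thresholding with a window of twice the expected
cell length and an offset of 2% of the dynamic range. The per-pixel
threshold is additionally clamped at the colony's global Otsu level: around
small colonies the local mean is dominated by background, and without the
clamp the threshold rises into the intensity band of the bright boundaries
*between* touching cells, which fuses them into neckless blobs. Multiplying
by the colony mask removes the salt-and-pepper artifacts adaptive
thresholding produces outside colonies; one-pixel tendrils are despurred.
8-connected components of the result are *cell objects*: single cells or
sets of touching cells. Two further, stiffer thresholds at the cell-width
scale (offsets 5% and 8%) extract conservative *cell cores* - the dark
cell bodies with the between-cell boundaries excluded - which seed the
complex-object analysis below; a core that splits at the stiffer level is
treated as a fused pair and partitioned by proximity.

**Shape classification.** Each object's skeleton (Zhang-Suen thinning) is
pruned of spur branches shorter than one cell width; if junction pixels
(more than two skeleton neighbours) remain, the object is *complex*,
otherwise *collinear* (a single cell or an end-to-end chain).

**Collinear objects** are measured along their ordered centerline: at each
centerline point the local width is the length of the in-mask chord normal
to the local tangent (antipodal boundary pairs). A local minimum of the
smoothed width curve is a *deep valley* (a "bow-tie" point, the optical
signature of a division septum) iff its ratio to the nearest flanking local
maximum is at most T on both sides. T defaults to 0.70 and physically lives
in [0.65, 0.75]; when a pre-first-division frame is available,
`estimate_t_valley()` sets it from the min/max width ratio of the largest
collinear object, clamped to that range. The object is cut at the valleys
along the local normals; cuts that would produce fragments below the
minimum area A (below) are refused.

**Complex objects** go through four stages. (1) The watershed transform of
the negated Euclidean distance map (h-minima suppression, h = 1 px)
over-segments the object into fragments. In dense colonies, where fused
slabs have no internal distance valleys and the plain watershed would
*under*-segment, the conservative cell cores act as watershed markers and
are grown over the object by Voronoi propagation on the distance map,
restoring the over-segmentation premise the next stages rely on. (2)
"Puzzle solving" repairs the over-segmentation: two touching fragments
merge iff the merged region is still collinear, shows no deep valley near
the shared boundary, and its median local width stays below 1.5x the
expected cell width; among feasible partners the merge maximizing the
resulting solidity (area / convex hull area) wins, and merged fragments
re-enter the queue. The width guard is our addition: the valley criterion
looks along the merged centerline and is blind to two parallel rods lying
side by side, which merge into a high-solidity but two-cells-wide region
without it. Surviving fragments are then re-examined with the same
evidence in the opposite direction: a fragment whose own width profile
still contains a deep valley is split there, and a fragment wider than
1.5 cell widths across its principal axis is split transversely
(superfluous splits are re-merged later). (3) The C fragment centroids
seed a Gaussian mixture over a synthetic point cloud: N =
ceil(1/2 C CellLength CellWidth / CalFactor^2) points are apportioned to
the object pixels by largest remainder in proportion to their distance-
transform values (so the cloud is densest along medial axes) and each pixel
emits its share from an isotropic Gaussian with variance 0.3, below the
half-distance between pixel centres so no spurious density hills appear
between pixels. When cores exist, the distance transform is taken on the
core mask, so the between-cell interfaces - boundaries in their own right -
stay point-poor and anchor the mixture components. (4) Component-wise EM
with the minimum-message-length weight update (w_m proportional to
max(0, n_m - 5/2); five free parameters per 2-D full-covariance component)
prunes components that do not pay for themselves; after convergence the
weakest component is forcibly removed and the model re-converged, and the
minimum-message-length model over the visited component counts is kept.
Covariance eigenvalues are floored at the point-generator variance - no
real cell structure can be tighter than the resolution of the cloud -
which removes the classic EM degeneracy of near-singular "sliver"
components. Pixels take the majority component of the points they
generated, with the core pixels of each fragment voting as a block so that
component ellipses cannot slide across observed cell bodies.

Cleanup applies the minimum-area rule in both directions. Any region
smaller than A = pi/4 (CellWidth/CalFactor)^2 - the area of the two
semicircular poles of a well-formed cell - merges into the touching
neighbour maximizing solidity (isolated undersized regions are kept but
flagged). A second pass nominates detections below half the expected cell
footprint and merges them with a neighbour only when the union is a
valley-free collinear chain within 1.4 expected footprints - reuniting
split halves of one cell while a true small cell keeps its septum cusp.
Finally each region grows by one pixel into unclaimed colony foreground
(nearest region wins): the bright halo biases the threshold contour about
one pixel into the cell, and reference masks - like real cell extents -
tile the cell-cell interfaces.

**Lineage.** The published tracker this pipeline descends from is external
to this package; `track_cells()` is a documented stand-in with a pluggable
interface: consecutive frames are matched per colony by pixel overlap
after translating by the colony displacement, and a cell covered at least
60% by two next-frame cells (each at least 20%) has divided. On noise-free
fixtures this recovers essentially all ground-truth divisions, which is
what its tests assert. The divisions tree is the condensation of the
lineage (one node per life span, edges parent to daughter).

**Analytics.** Per-cell elongation is fit as l(t) = l0 exp(k t) by
nonlinear least squares (log-linear initialisation); elongation
E = ln(lf/l0) = k T_div. Colony counts are fit with the Baranyi-Roberts
primary model y(t) = y0 + mu_max A(t), with the lag-adjustment
A(t) = t + (n mu_max)^-1 ln(e^(-n mu_max t) + e^(-n mu_max lambda) -
e^(-n mu_max (t+lambda))) computed in log space; the curvature parameters
are fixed at m = 0 (no stationary-phase damping) and n = 20, which makes
the lag-to-exponential transition abrupt. Life attributes pool into gamma
distribution fits (maximum likelihood via `fitdistrplus`); cells whose
life is cut by the movie boundaries are flagged censored and excluded from
life-attribute distributions, a choice the data force rather than the
model.

**Evaluation.** Detections are matched to truth labels by *mutual centroid
containment*: a detection is a true positive iff its centroid lies in an
unclaimed truth label whose centroid lies in the detection; each truth
label is claimed once. This penalizes splits (extra fragments become false
positives) and merges (swallowed cells become false negatives) exactly the
way the recall/precision/F-measure semantics intend. The matching rule is a
package decision - manual-annotation protocols rarely state one - and is
flagged as such in reports.

## The synthetic generator as the study condition

`sim_params()` defaults describe the regime the pipeline targets: three
founder cells seeding three dense phase-contrast micro-colonies at
0.125 um/pixel and a 5-min sampling period; cell width 1.1 um; expected
length 3.5 um (division near 5 um, cv 7%); per-cell elongation rates gamma
distributed with mean ln(2)/25 per minute (25-min doubling) and cv 15%;
septum constriction to 0.6x width over the middle 15% of the centerline in
the pre-division frame; PSF sigma 1 px, additive noise sigma 0.05, 10%
illumination gradient. Cells are 2-D spherocylinders (tip-to-tip length
convention), divide 50/50 with 2% jitter, and are packed by iterative
pairwise repulsion until overlaps fall below 5% of the width - the
simplest mechanism that produces the dense touching-cell regime, rather
than rigid-body physics. Rendering draws dark cell bodies, a bright halo
ring, and *intermediate-intensity interface lines where cells touch*: in
real phase-contrast images the cell-cell boundaries scatter light and
appear brighter than the cell bodies, and this cue is precisely what
adaptive thresholding exploits; a renderer without it would present the
segmenter with information-free flat blobs no method could cut. A movie
whose colony reaches the image border is truncated there and flagged.

What the generator does **not** emulate: third-dimension growth of thick
colonies (the known failure regime of 2-D segmentation), motility,
filamentous morphologies, realistic phase-contrast optics beyond
halo + blur, and fluorescence bleed-through. Passing the synthetic
benchmark therefore demonstrates the geometry/statistics machinery on
dense 2-D colonies, not robustness to every optical artifact of a real
microscope.

## Numerical choices and degenerate inputs

- Frames, label masks and all reports are 1-based ("frame 74" style);
  pixels are (row, col) with the origin top left.
- Point budget N uses ceiling rounding; point apportionment uses largest
  remainder so the shares sum to N exactly.
- Deep-valley detection treats plateaus as single extrema (centre index);
  equal-solidity puzzle merges prefer the smaller neighbour, then the
  smaller fragment id; all queues are ordered, so segmentation is
  bit-for-bit reproducible given `rng_seed`.
- EM runs in log space with a 1e-4 ridge plus the covariance floor; message
  length is compared at a relative tolerance of 1e-5 with at most 200
  sweeps per component count (fixtures converge in far fewer).
- Degenerate objects (< 4 px), centerlines shorter than 5 px and cyclic
  skeletons are treated as intact single cells; a failing object is
  quarantined with a warning, never aborting the frame.
- `fit_exponential_growth` falls back to the log-linear estimate when the
  nonlinear step cannot improve on a perfect or constant series;
  `fit_baranyi_roberts` restarts from a 17-point lag grid and keeps the
  best least-squares fit.
- No SQL engine is bundled: the relational schema (Experiment, Frame,
  Colony, Cell Instant, Cell) is written as CSV tables with an explicit
  referential-integrity audit (`audit_database()`), which keeps outputs
  greppable and diffable.

## Problem sizes used in validation

The shipped tests exercise: deep-valley detection against a brute-force
extrema oracle on 1000 random curves; mixture component recovery for
K = 1..6 planted clusters (4-sigma separation, 300 points per cluster,
k-means initialisation at K+3 centres, 50 seeds per K); parameter recovery
for the exponential model (500 replicates at 3% noise), Baranyi-Roberts
(lambda = 30 min, mu_max = 0.03/min, sigma = 0.02) and gamma maximum
likelihood (n = 10^4); and an end-to-end benchmark movie grown to at least
200 cells in the final frame, segmented over its last five frames and
scored against exact ground truth. These sizes are the package's chosen
validation conditions; the generator scales to larger fields if heavier
experiments are wanted.

## Known limitations

- The cell tracker is an overlap-based stand-in; crossing cells or large
  inter-frame displacements defeat it sooner than a motion-estimation
  tracker.
- Filamentous cells violate both the deep-valley geometry and the expected
  cell-size priors.
- Once colonies grow into the third dimension the 2-D partition property
  itself breaks down; errors concentrate there, as the evaluation module
  makes visible.
- The Baranyi-Roberts fit treats counts as exact; it does not propagate
  segmentation error into the kinetic parameter uncertainty.
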
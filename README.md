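# bactrace

Automated single-cell analysis of bacterial colony time-lapse movies:
segmentation of dense, touching, possibly merging micro-colonies down to
single rod-shaped cells, colony and cell tracking, lineage trees, growth
analytics, and quantitative evaluation against ground truth — with a
seeded synthetic cell-movie generator providing that ground truth.

## Who this is for

Microbiologists and image-analysis developers working with phase-contrast
or bright-field movies of growing micro-colonies (e.g. *Salmonella*,
*E. coli*) who need per-cell measurements (area, length, width,
fluorescence, position), per-colony growth curves, and life attributes
(division time, elongation rate, division length) without manual
annotation. The user supplies only the spatial calibration (um/pixel), the
imaging modality, and the species' expected cell length and width.

## The method in brief

1. **Preprocess**: stationary-wavelet (starlet) BayesShrink denoising +
   CLAHE.
2. **Colonies**: rolling-ball background correction; colony mask = Otsu
   foreground ∪ filled Canny contours; colonies tracked by
   centroid-in-bounding-box with merge detection.
3. **Cells**: adaptive thresholding inside each colony cuts the foreground
   into *cell objects*; skeleton junctions classify each object as
   *collinear* or *complex*.
   - Collinear chains are cut at *deep valleys* of the width curve: a local
     minimum qualifies iff `localMin/leftLocalMax <= T` and
     `localMin/rightLocalMax <= T` (T ≈ 0.70, the bow-tie signature of a
     division septum).
   - Complex objects are over-segmented by watershed on the distance
     transform, repaired by solidity-guided "puzzle solving", then refined
     by a Gaussian mixture fitted to a point cloud drawn from the distance
     transform — `N = ceil(1/2 C·CellLength·CellWidth/CalFactor²)` points
     for `C` candidate centres — using component-wise EM with the
     minimum-message-length criterion, which annihilates components that do
     not pay for themselves. Fragments smaller than
     `A = pi/4 (CellWidth/CalFactor)²` are merged into their best
     neighbour.
4. **Lineage**: overlap-based frame-to-frame matching (60%/20% division
   rule) builds per-colony lineage forests and condensed divisions trees
   (GraphML export).
5. **Analytics**: per-cell exponential fits `l(t) = l0·e^{kt}`, elongation
   `E = ln(lf/l0) = k·T`, Baranyi–Roberts colony kinetics (lag λ and
   maximum specific growth rate μ_max; curvature parameters fixed m = 0,
   n = 20), gamma life-attribute distributions, Pearson correlations.
6. **Evaluation**: detections vs ground-truth masks by mutual centroid
   containment → TP/FP/FN, recall (TPR), precision (PPV) and
   F = 2·PPV·TPR/(PPV+TPR).

Results land in a five-table relational store (Experiment, Frame, Colony,
Cell Instant, Cell) written as CSV with referential-integrity auditing.

## Worked example

```r
library(bactrace)

## a dense synthetic phase-contrast movie with exact ground truth
movie <- simulate_movie(sim_params(seed = 5, n_founders = 1, n_frames = 14,
                                   field_px = c(220, 220)))
sp  <- species_config(cell_length = 3.5, cell_width = 1.1,
                      cal_factor = 0.125, modality = "phase-contrast")
res <- segment_movie(stack_from_movie(movie), sp,
                     segmentation_config(rng_seed = 1))

ev <- evaluate_segmentation(
  lapply(seq_along(movie$frames), function(i) res$segmentation[[i]]$label),
  movie$label_masks)
ev$pooled
#>   scope TP FP FN TPR       PPV       F TPR_pct PPV_pct F_pct
#> 1 movie 31  2  0   1 0.9393939 0.96875     100    93.9  96.9

forest <- track_cells(res$segmentation,
                      frames = as.integer(names(res$segmentation)),
                      sampling_period = 5)
life <- life_attribute_table(forest, res$cells)
head(life[!life$censored, c("cell_id", "T_div", "l0", "lf", "E", "k")])
#>   cell_id T_div   l0   lf     E      k
#> 1       1    15 3.07 3.98 0.257 0.0258
#> 2       2    30 2.44 4.46 0.602 0.0243
#> 3       3    40 2.41 5.15 0.759 0.0204
```

The pooled row reads: all 31 true cell instants across the movie were
detected (recall 100%); two detections were over-segmented fragments
(precision 93.9%), giving a pooled F-measure of 96.9%. `life` holds one row per tracked
cell: `T_div` its life span in minutes, `l0`/`lf` birth/division length in
um, `E = ln(lf/l0)` its elongation and `k` its fitted elongation rate per
minute; censored rows (lives cut by the movie window) are excluded from
distribution fits.

`run_pipeline()` wraps all stages and writes the database, config and logs
under one run directory; `inst/cli/bactrace` exposes `run`, `simulate`,
`evaluate` and `overlay` subcommands for shell use.

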
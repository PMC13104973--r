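---
title: "Quantifying branched-actin membrane protrusions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying branched-actin membrane protrusions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Branched-actin membrane protrusions (BAMPs) — membrane ruffles and
lamellipodia built by Arp2/3-nucleated actin — are sheet-like, fast-moving
structures at the cell periphery. `bampq` implements the image-quantification
procedures used to characterize them: a ruffling-rate score for live-cell
actin movies, a subcellular-enrichment readout for two-channel optogenetic
movies, a 3D proximity-ligation (PLA) spot pipeline, a simplified 3D cell
segmentation, and the scalar assays (EdU proliferation, integrated density,
blot densitometry) that accompany such studies. This vignette explains each
model, its assumptions and tunable parameters, the numerical choices made
where the procedure left them open, and what the synthetic-scene tests do and
do not demonstrate.

## Ruffling rate from live-cell actin movies

Thresholding raw actin intensity cannot isolate ruffles because stress
fibers and the cell cortex are equally actin-rich. Ruffles, however, move
fast: at a fixed pixel they appear as transient intensity spikes. The
pipeline exploits this temporal signature.

1. **Temporal baseline.** Per pixel and frame, the median over a rolling
   window of ±25 frames (±50 s at the 2-s frame interval of the live
   acquisitions; `half_window_frames`). The median is robust to transient
   spikes as long as a ruffle occupies a pixel for less than half the
   window — the method's central assumption. At the movie ends the window
   is truncated rather than reflected, so the baseline remains an order
   statistic of observed data.
2. **Percent-ratio.** `100 * raw / baseline`. Static structure cancels to
   100; ruffles stand out as values well above 100. Division by near-zero
   background baselines is guarded by `ratio_floor`: baselines below it are
   flagged background and carry ratio 0. The default floor is 10% of the
   movie's median foreground intensity (foreground by global Otsu), chosen
   so that dark extracellular pixels are excluded while dim cytoplasm is
   not.
3. **Multi-scale locally adaptive segmentation.** The original multi-scale
   automatic segmentation is published elsewhere and not restated in the
   procedure, so this package implements a fully specified stand-in that
   preserves its stated properties: the ratio frame is smoothed at several
   Gaussian scales (`scale_sigmas`, default 1, 2, 4 px), each scale is
   thresholded by a per-tile Otsu threshold (`tile_px`, default 32), and
   candidates are united across scales. Two guards make the threshold
   meaningful in flat regions: a pixel must also exceed `min_ratio`
   (default 120, i.e. 20% above the static level — 4 standard deviations at
   the 5% noise typical of these movies), and the multi-scale union is
   intersected with the *unsmoothed* ratio at `min_ratio`, which trims the
   halo the coarser blurs would otherwise add (on planted scenes the
   untrimmed union overstates area by ~25%; trimmed, recovery is within
   ~0.3 points). Components below `min_object_px` (default 8 px) are
   discarded.
4. **Scoring.** The cell is segmented separately in the raw movie (global
   Otsu on a 3-frame temporally averaged, lightly smoothed frame, hole
   filling, size filter — a contrast guard returns an empty mask plus a
   warning for frames without a cell). The per-frame score is
   `100 * |ruffle ∩ cell| / |cell|`, and the ruffling rate is the mean over
   frames. Frames with an empty cell mask are excluded from the mean rather
   than scored 0, so segmentation failures do not dilute the rate. Areas
   are pooled over the field of view, matching a per-video calibration
   where a frame contains one to a few cells.

## Subcellular enrichment in protrusions

For two-channel movies (a reporter plus a uniform membrane marker), each
reporter frame is divided by the matching membrane frame; the marker cancels
membrane-fold geometry so that ratio differences reflect genuine enrichment.
The three user-set quantities are the segmentation threshold (tuned per
acquisition to separate individual cells), the first activation frame T0 and
the maximal-protrusion frame T1 (a user assessment; `suggest_t1()` proposes
the frame with the largest footprint gain). Protrusive pixels belong to the
cell at T1 but not at T0; pixels present at both are non-protrusive; pixels
lost between T0 and T1 belong to neither class. The result compares mean
normalized intensity between the classes.

Two points the procedure leaves open are resolved as follows. The class
means are taken over the normalized frame at T1 — the frame at which the
protrusive class is defined — with `stat_frames = "t0_to_t1"` available to
average the activation window instead. Segmentation is applied to the
membrane channel, which defines cell extent independently of the reporter;
`seg_channel = "normalized"` switches. Multi-cell fields should be cropped
to single cells before analysis; the package does not track cell instances.

## 3D PLA spot detection

The spot channel is resampled to isotropic voxels (linear interpolation to
the smallest spacing; detection runs on the isotropized grid, in the quoted
order), percentile-normalized so that the 2nd and 99.8th percentiles map to
0 and 1, and passed to a difference-of-Gaussian detector with
`min_sigma = 3`, `max_sigma = 6` voxels and response threshold 0.01. The
scale ladder is geometric with ratio 1.6 (a standard step; the procedure
fixes only the endpoints), each layer is scale-normalized by
`1 / (ratio − 1)`, and detections are local maxima of the 4D scale stack.
Overlapping detections (spheres of radius `sigma * sqrt(3)` overlapping by
more than half) are resolved by keeping the higher response.

The cell mask gating spurious detections comes from the actin channel:
3-class Otsu keeping voxels above the upper threshold, then — in an order
that is part of the contract and pinned by a regression test — largest
component, binary closing (ball radius 3), hole filling, binary erosion
(ball radius 1). Structuring elements are discrete Euclidean balls in
isotropized voxel units. Spots whose rounded centre voxel falls outside the
mask are removed. Compartment densities divide spot counts by user-supplied
compartment areas (lamella outlines are drawn manually in practice;
automatic lamella detection is out of scope).

At the detector's published threshold of 0.01, rare noise maxima inside the
cell are expected when spot amplitude is only ~10x the noise floor; the
recovery tests therefore require exact counts in at least 19 of 20 scenes
rather than all 20.

## Simplified 3D cell segmentation

Preprocessing applies, in order: gamma correction with gamma 0.8 (on
min-max-rescaled intensities, so the exponent is well defined for any AU
range), 3×3×3 median filtering, isotropization, percentile normalization
(2nd/99.8th), and isotropic 1/4 downsampling. Each 2D slice of the x-y, x-z
and y-z orthoviews is then Otsu-thresholded and intersected with a 0.2
normalized-intensity floor (the floor is applied as a post-mask; a
contrast-free slice is segmented by the floor alone).

The published consensus machinery that follows (gradient-flow label
aggregation, label diffusion, guided filtering) is a separate tool and is
deliberately **not** re-implemented. In its place a majority vote (default 2
of 3 views) combines the orthoview stacks, the largest component is
retained, and the mask is upsampled back to the input grid by nearest
neighbour. This simplification recovers a planted ellipsoid with IoU ≈ 0.89
at default parameters; it does not recover fine surface protrusions, which
is precisely what the published postprocessing adds on real data.

## Scalar readouts

* **EdU proliferation**: EdU-positive pixels over DAPI-positive pixels, as
  a percentage. The readout is pixel-based, not nucleus-instance-based. The
  procedure requires only that thresholds be equal across compared samples;
  identical absolute thresholds are the default (an Otsu suggestion helper
  is provided), and a fixed automatic procedure per sample is the
  alternative reading.
* **Integrated density**: sum projection over z, then the sum inside a
  user-outlined ROI.
* **Blot densitometry**: band density normalized to the solvent-control
  band and to the loading control,
  `(band / control_band) / (loading / control_loading)`. Band densities
  from 1D lane profiles subtract a straight-line baseline through the band
  window endpoints (the ImageJ "Gels" convention) and clip negative
  integrals to 0.

## The synthetic scenes

Every stage is validated against generated scenes whose ground truth is
recorded before noise is applied, so the truth is exact by construction:

* Ruffling movies: an elliptical cell (defaults: 64×64 px, 100 frames at
  2 s, cell 200 AU on 10 AU background, Gaussian noise 2 AU ≈ 1% of signal,
  optional Poisson shot noise) with static fibers and transient half-disk
  ruffle caps that drift along the edge. The cap radius is solved per frame
  by bisection on the pixel grid, so planted area fractions are exact to
  ~1 px rather than relying on the curvature-biased analytic half-disk
  area. Test schedules keep events inside the frame range where the median
  window is full and per-pixel occupancy under half a window — i.e. the
  regime the method assumes; movies violating it (ruffles parked for
  minutes) would be misscored by design.
* Protrusion movies: a footprint growing from a base mask to a full mask
  (added pixels appear in order of distance from the base), membrane channel
  at 100 AU, reporter = membrane × planted region ratio, 5% noise in the
  recovery tests.
* Spot volumes: 64³ voxels, an ellipsoidal cell, isotropic Gaussian spots
  (sigma 3–5, amplitude 100 = 10× the 10 AU noise) planted ≥ 12 voxels
  apart, 5 inside and 2 outside the cell.
* Nuclei fields: non-overlapping disks; EdU positivity assigned to the
  first `floor(n * fraction + 0.5)` nuclei in seeded shuffle order, so the
  planted count is exact.

The generators emulate the statistical structure the analyses rely on —
temporal transience vs static structure, ratio contrasts, separated point
sources, bimodal intensity histograms — with additive Gaussian and optional
Poisson noise. They do not emulate PSF anisotropy, bleaching, motion of the
cell body, partial-volume effects at object boundaries, or instance-level
clutter (touching cells, overlapping nuclei). Passing tests therefore
demonstrate correctness of the computations and recovery under the stated
noise model, not robustness to every property of real microscopy data.

## Numerical choices and problem sizes

Intensities are floating point internally; TIFF export quantizes to 16-bit
integer counts (1 AU = 1 count, clamped to [0, 65535]) — documented,
lossless for integer-valued AU. Percentiles use linear interpolation between
order statistics. Gaussian smoothing is separable with symmetric (reflect)
padding and kernels truncated at 4 sigma. Even-length truncated median
windows use the midpoint of the two middle order statistics. Connected
components use 8-connectivity in 2D and 26-connectivity in 3D; hole filling
flood-fills the background from the border with 6-connectivity. Erosion
treats out-of-bounds voxels as background. Ties in the DoG scale stack
(plateau maxima) yield multiple candidates that the overlap-resolution step
collapses.

The test and acceptance scenes use 64×64×100 movies, 80×80×20 two-channel
movies, and 64³ volumes (20 seeded replicates for the spot benchmark) —
sizes chosen so each planted structure spans tens of pixels, as in the
downsampled real acquisitions, while a full suite run completes in a few
minutes.
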
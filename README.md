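# bampq

Quantification of branched-actin membrane protrusions (BAMPs) — membrane
ruffles and lamellipodia — in fluorescence microscopy, for cell biologists
studying protrusion dynamics and their signaling consequences.

Raw actin intensity cannot isolate ruffles: stress fibers and the cortex
are just as bright. Ruffles are distinguished by *motion* — at a fixed
pixel they are transient spikes in the intensity time course. The core
statistic is the **ruffling rate** of a live-cell movie $I(x, t)$:

$$B_t(x) = \mathrm{median}\{\, I(x, s) : |s - t| \le h \,\}, \qquad
R_t(x) = 100\, \frac{I(x, t)}{B_t(x)},$$

with $h = 25$ frames (±50 s at 2-s intervals). High-ratio regions are
segmented per frame by multi-scale locally adaptive (tile-Otsu)
thresholding into ruffle masks $M_t$, the cell footprint $C_t$ is segmented
separately in the raw movie, and

$$\text{ruffling rate} = \frac{1}{T}\sum_t 100\,
\frac{|M_t \cap C_t|}{|C_t|} \quad (\%).$$

Around this the package implements the accompanying readouts:

* **Subcellular enrichment** of a membrane-bound reporter: reporter divided
  by a membrane marker channel; mean normalized intensity compared between
  pixels gained from T0 to T1 (protrusive) and pixels present at both
  (non-protrusive).
* **3D PLA spot detection**: isotropization, 2nd/99.8th-percentile
  normalization, difference-of-Gaussian detection (sigma 3–6, threshold
  0.01), gated by an actin-derived 3-class-Otsu cell mask (largest
  component, closing ball 3, hole fill, erosion ball 1); spot densities per
  compartment.
* **Simplified 3D cell segmentation**: gamma 0.8, 3×3×3 median,
  isotropize, percentile-normalize, 1/4 downsample, per-slice Otsu in three
  orthoviews, majority-vote consensus.
* **Scalar assays**: EdU/DAPI positive-pixel proliferation percentage,
  integrated density on sum projections, western-blot relative
  densitometry.
* A **synthetic-scene generator** planting exact ground truth (ruffle
  masks, region ratios, spot centres, EdU labels) so every stage is
  verifiable offline.

## Worked example

```r
library(bampq)

# a 100-frame movie of a cell with drifting ruffles covering, on average,
# 8% of the cell area
scene  <- scene_spec(n_frames = 100, noise_sd = 2, seed = 1)
events <- ruffle_events_for_fraction(0.08, n_frames = 100)
sim    <- generate_ruffle_movie(scene, events)

res <- ruffle_rate_pipeline(sim$movie)
res
#> <ruffle_rate_result> mean rate 7.74% over 100 scored frames
100 * sim$truth$mean_fraction
#> [1] 7.992788
```

The planted time-averaged ruffle fraction (7.99% of the cell area) is
recovered as 7.74% — the per-frame masks miss a thin boundary layer of each
cap, a deficit of ~0.25 percentage points at this fraction. The same
movies written to disk and processed through the file-level runner
(`run_ruffle_rate("movie.tif", out_dir = "out/")`) additionally produce a
per-frame CSV (`frame, ruffle_px, cell_px, percent`), a one-row summary and
a JSON manifest recording parameters and seed.

The numbered drivers under `analysis/` run the whole study on simulated
data: `01_simulate.R` writes movies/volumes with planted truth under
`results/data/`, and `02`–`06` quantify them (ruffling rates, enrichment
ratios, spot counts and densities, 3D segmentation QC, EdU and blot
tables), each printing the recovered-vs-planted comparison, e.g.:

```
                    file truth_mean_percent measured_mean_percent abs_error_pp
1       movie_static.tif               0.00                  0.00        0.000
2 movie_ruffle_02pct.tif               1.99                  1.85        0.141
3 movie_ruffle_08pct.tif               7.99                  7.74        0.248
4 movie_ruffle_15pct.tif              15.00                 14.87        0.128
```

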
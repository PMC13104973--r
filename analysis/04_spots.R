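#!/usr/bin/env Rscript
# Detect proximity-ligation spots in the simulated volumes, gate them by the
# actin-derived cell mask, and report counts plus an example compartment
# density. Expected outcome: 5 in-cell spots per volume, outside detections
# removed by the mask.

suppressPackageStartupMessages(library(bampq))
scenes <- read.csv("results/data/spot_scenes.csv")
out <- "results/spots"

rows <- lapply(seq_len(nrow(scenes)), function(i) {
  k <- scenes$scene[i]
  res <- run_spots(file.path("results/data", sprintf("spots_%02d.tif", k)),
                   file.path("results/data", sprintf("actin_%02d.tif", k)),
                   out_dir = file.path(out, sprintf("scene_%02d", k)),
                   seed = 1L)
  dens <- compartment_density(nrow(res$spots), sum(res$mask$mask),
                              "whole cell")
  data.frame(scene = k, planted_inside = scenes$n_inside[i],
             detected_total = nrow(res$spots_all),
             detected_in_cell = nrow(res$spots),
             density_per_voxel = dens$density)
})
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "summary.csv"), row.names = FALSE)
print(tab, digits = 3)
cat(sprintf("%d/%d volumes recovered the planted in-cell count exactly.\n",
            sum(tab$detected_in_cell == tab$planted_inside), nrow(tab)))
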
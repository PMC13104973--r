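#!/usr/bin/env Rscript
# Scalar readouts on the simulated data: EdU/DAPI proliferation percentage,
# integrated density of the reference cell, and blot relative densities.
# Expected outcome: proliferation ~40% (the planted positive fraction), and
# the CK666 lane at ~0.4 of the DMSO control.

suppressPackageStartupMessages(library(bampq))
out <- "results/bulk"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rate <- run_edu("results/data/edu.tif", "results/data/dapi.tif",
                threshold_edu = 50, threshold_dapi = 50,
                out_dir = file.path(out, "edu"), seed = 1L)
truth <- read.csv("results/data/nuclei_truth.csv")
cat(sprintf("EdU proliferation: measured %.2f%%, planted %.2f%%\n",
            rate, truth$truth_pixel_percent))

ref <- generate_spot_volume(spot_scene_spec(noise_sd = 0, seed = 1))
roi <- apply(ref$truth$cell_mask, c(2, 3), any)
dens <- integrated_density(ref$actin, roi)
cat(sprintf("Integrated density of the reference cell ROI: %.4g AU*px\n",
            dens))

blot <- run_densitometry("results/data/lanes.csv", "DMSO",
                         out_dir = file.path(out, "blot"), seed = 1L)
print(blot, digits = 3)

write.csv(data.frame(measure = c("edu_rate_percent", "integrated_density"),
                     value = c(rate, dens)),
          file.path(out, "summary.csv"), row.names = FALSE)
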
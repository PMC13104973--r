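#!/usr/bin/env Rscript
# Simulate every dataset the downstream analyses consume: ruffling movies
# (static control + three planted area fractions), two-channel protrusion
# movies at four planted enrichment ratios, two-channel spot volumes, an
# EdU/DAPI nuclei field and a western-blot lane table. Images go to
# results/data/ as 16-bit TIFFs with JSON sidecars; the planted truth each
# analysis will be compared against is summarized in scene tables.

suppressPackageStartupMessages(library(bampq))
seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Ruffling movies ------------------------------------------------------------
fibers <- static_structure_spec(r0 = c(25, 35), c0 = c(20, 25),
                                r1 = c(40, 30), c1 = c(45, 40),
                                width = c(2, 2), intensity = c(100, 80))
static <- generate_ruffle_movie(scene_spec(n_frames = 60, noise_sd = 10,
                                           seed = seed),
                                ruffle_spec(), fibers)
write_movie(static$movie, file.path(out, "movie_static.tif"))

ruffle_tab <- data.frame(file = "movie_static.tif", planted_fraction = 0,
                         truth_mean_percent = 0)
for (f in c(0.02, 0.08, 0.15)) {
  g <- generate_ruffle_movie(scene_spec(n_frames = 100, noise_sd = 2,
                                        seed = seed),
                             ruffle_events_for_fraction(f, 100))
  fn <- sprintf("movie_ruffle_%02dpct.tif", round(100 * f))
  write_movie(g$movie, file.path(out, fn))
  ruffle_tab <- rbind(ruffle_tab,
                      data.frame(file = fn, planted_fraction = f,
                                 truth_mean_percent = 100 * g$truth$mean_fraction))
}
write.csv(ruffle_tab, file.path(out, "ruffle_scenes.csv"), row.names = FALSE)

## Protrusion movies ----------------------------------------------------------
base <- matrix(FALSE, 80, 80); base[20:60, 20:45] <- TRUE
full <- base; full[20:60, 46:70] <- TRUE
prot_tab <- NULL
for (r in c(1.0, 1.5, 2.0, 3.0)) {
  g <- generate_protrusion_movie(protrusion_scene_spec(
    base, full, reporter_ratio_protrusive = r, noise_sd = 5,
    seed = seed + round(10 * r)))
  tag <- sprintf("ratio_%.1f", r)
  write_movie(g$reporter, file.path(out, sprintf("reporter_%s.tif", tag)))
  write_movie(g$membrane, file.path(out, sprintf("membrane_%s.tif", tag)))
  prot_tab <- rbind(prot_tab, data.frame(tag = tag, planted_ratio = r))
}
write.csv(prot_tab, file.path(out, "protrusion_scenes.csv"),
          row.names = FALSE)

## Spot volumes ---------------------------------------------------------------
spot_tab <- NULL
for (k in 1:5) {
  scn <- random_spot_scene(seed + k)
  g <- generate_spot_volume(scn)
  write_volume(g$spots, file.path(out, sprintf("spots_%02d.tif", k)))
  write_volume(g$actin, file.path(out, sprintf("actin_%02d.tif", k)))
  spot_tab <- rbind(spot_tab,
                    data.frame(scene = k, seed = seed + k,
                               n_inside = nrow(g$truth$spots_inside),
                               n_outside = nrow(g$truth$spots_outside)))
}
write.csv(spot_tab, file.path(out, "spot_scenes.csv"), row.names = FALSE)

## Nuclei field and lane table ------------------------------------------------
gn <- generate_nuclei_images(nuclei_scene_spec(n_nuclei = 20,
                                               positive_fraction = 0.4,
                                               radius_sd = 0,
                                               seed = seed + 3))
invisible(tiff::writeTIFF(round(gn$edu) / 65535, file.path(out, "edu.tif"),
                          bits.per.sample = 16L))
invisible(tiff::writeTIFF(round(gn$dapi) / 65535, file.path(out, "dapi.tif"),
                          bits.per.sample = 16L))
write.csv(data.frame(positive_fraction = 0.4,
                     truth_pixel_percent = 100 * gn$truth$positive_pixel_fraction),
          file.path(out, "nuclei_truth.csv"), row.names = FALSE)

lane_profile <- function(height) {
  prof <- seq(4, 10, length.out = 40)
  prof[15:25] <- prof[15:25] + height
  prof
}
band <- function(height) lane_profile_density(lane_profile(height), c(12, 28))
lanes <- data.frame(condition_label = c("DMSO", "CK666", "CK689"),
                    band_density = c(band(10), band(4), band(9.5)),
                    loading_density = c(band(15), band(15), band(15)))
write.csv(lanes, file.path(out, "lanes.csv"), row.names = FALSE)

cat("Simulated", nrow(ruffle_tab), "ruffling movies,", nrow(prot_tab),
    "protrusion movie pairs,", nrow(spot_tab),
    "spot volumes, one EdU/DAPI field and a 3-lane blot table under",
    out, "\n")
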
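#!/usr/bin/env Rscript
# Measure reporter enrichment in light-induced protrusions for the four
# planted reporter:membrane ratios. Expected outcome: the measured
# enrichment ratio tracks the planted ratio within a few percent and the
# ratio-1 control is compatible with no enrichment.

suppressPackageStartupMessages(library(bampq))
scenes <- read.csv("results/data/protrusion_scenes.csv")
out <- "results/enrichment"
params <- enrichment_params(seg_threshold = 50, t0_frame = 1, t1_frame = 20)

rows <- lapply(seq_len(nrow(scenes)), function(i) {
  tag <- scenes$tag[i]
  res <- run_enrichment(
    file.path("results/data", sprintf("reporter_%s.tif", tag)),
    file.path("results/data", sprintf("membrane_%s.tif", tag)),
    params, out_dir = file.path(out, tag), seed = 1L)
  data.frame(planted_ratio = scenes$planted_ratio[i],
             measured_ratio = res$enrichment_ratio,
             mean_protrusive = res$mean_protrusive,
             mean_non_protrusive = res$mean_non_protrusive)
})
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "summary.csv"), row.names = FALSE)
print(tab, digits = 4)
cat(sprintf("Max relative recovery error: %.2f%%\n",
            100 * max(abs(tab$measured_ratio / tab$planted_ratio - 1))))
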
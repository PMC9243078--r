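#!/usr/bin/env Rscript
# Simulate the synthetic genome-scale adhesion screen used throughout the
# analysis: a 200-gene library (3 duplexes/gene) with 4 planted receptor
# genes, arrayed on 384-well plates with 32 control wells each, and draw the
# per-well object counts the microscope pipeline would report.
#
# Outputs (results/): library.csv, layout_round1.csv, ground_truth.csv,
# quant_round1.csv.

library(adhescreen)

seed <- 20260922L
out <- "results"
dir.create(out, showWarnings = FALSE)

lib <- build_library(200, 3)
truth <- sample_ground_truth(lib, receptor_fraction = 4 / 200,
                             seed = child_seed(seed, 1L))
lay <- layout_plates(lib, pooled = TRUE, controls_per_plate = 32)
quant <- simulate_screen_counts(lay, truth, seed = child_seed(seed, 10L))

write.csv(lib, file.path(out, "library.csv"), row.names = FALSE)
write.csv(lay, file.path(out, "layout_round1.csv"), row.names = FALSE)
write.csv(data.frame(gene_id = names(truth$gene_effect),
                     gene_effect = truth$gene_effect),
          file.path(out, "ground_truth.csv"), row.names = FALSE)
write.csv(quant, file.path(out, "quant_round1.csv"), row.names = FALSE)

cat(sprintf("simulated %d wells on %d plates; planted receptors: %s\n",
            nrow(quant), length(unique(lay$plate_id)),
            paste(truth$receptor_genes, collapse = ", ")))
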
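#!/usr/bin/env Rscript
# Per-plate control QC of the simulated round-1 screen: summarize the four
# control classes per plate and apply the transfection / block / reagent
# rules.
#
# Inputs: results/quant_round1.csv, results/layout_round1.csv (from 01).
# Outputs: results/plate_stats.csv, results/qc.csv.

library(adhescreen)

quant <- read.csv("results/quant_round1.csv")
class(quant) <- c("well_quant", "data.frame")
layout <- read.csv("results/layout_round1.csv")
class(layout) <- c("plate_layout", "data.frame")

stats <- summarize_controls(quant, layout)
qc <- qc_plate(stats, qc_rules())

write.csv(stats, "results/plate_stats.csv", row.names = FALSE)
write.csv(qc, "results/qc.csv", row.names = FALSE)

cat(sprintf("%d/%d plates pass control QC\n", sum(qc$pass), nrow(qc)))
neg <- stats[stats$content_class == "neg_ctrl_scrambled", ]
blk <- stats[stats$content_class == "ab_block", ]
cat(sprintf("negative-control ratio medians: %s\n",
            paste(round(neg$ratio_median, 2), collapse = ", ")))
cat(sprintf("antiserum floor medians: %s\n",
            paste(round(blk$ratio_median, 3), collapse = ", ")))
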
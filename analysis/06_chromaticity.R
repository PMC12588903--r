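#!/usr/bin/env Rscript
# Stage 6: chromaticity analysis. Per-site color readings are aggregated
# hierarchically to batch summaries (E*ab, normalized RGB from batch-mean
# channels), batches are clustered on the color descriptors, and each
# normalized channel is regressed against the group IC50s to test the
# color-toxicity link (expected: positive B slope, negative R slope).

suppressMessages(library(pmtox))

recs <- utils::read.csv("results/synthetic/chromaticity.csv")
truth <- utils::read.csv("results/synthetic/group_labels.csv")
tiers <- utils::read.csv("results/toxicity_tiers.csv")

summ <- batch_color_summaries(recs)
utils::write.csv(summ, "results/color_summaries.csv", row.names = FALSE)

grp <- truth$group[match(summ$batch_id, truth$batch_id)]
keep <- grp %in% c("B", "C", "D")                 # the toxicity-tiered groups
cl <- color_hca(summ[keep, ], k = 3)
cat("Color HCA vs composition group (B/C/D batches):\n")
print(table(cluster = cl$labels, group = grp[keep]))

ic50 <- stats::setNames(tiers$ic50[match(grp, tiers$group)], summ$batch_id)
reg <- color_toxicity_regression(summ[keep, ], ic50[keep])
utils::write.csv(reg, "results/color_regression.csv", row.names = FALSE)
for (i in seq_len(nrow(reg)))
  cat(sprintf("IC50 ~ %s: slope %.0f, r2 = %.2f, p = %.2g\n",
              reg$channel[i], reg$slope[i], reg$r_squared[i], reg$p_value[i]))
cat("Wrote results/color_summaries.csv, results/color_regression.csv\n")
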
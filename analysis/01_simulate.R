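#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — a 61-batch x 26-compound
# concentration table in four latent composition groups, per-group CCK-8
# viability plates, and per-batch chromaticity readings — and write it under
# results/synthetic/. All later stages read these files, so the whole
# workflow is reproducible from one seed.

suppressMessages(library(pmtox))
seed <- 1L

cfg <- synthetic_config(seed = seed)
paths <- write_synthetic_bundle(cfg, "results/synthetic")

tab <- read_compound_table(paths$compound_table, paths$compound_metadata)
ct <- class_totals(tab)
cat(sprintf("Simulated %d batches x %d compounds (seed %d)\n",
            nrow(tab$concentrations), ncol(tab$concentrations), seed))
cat(sprintf("Stilbene-glycoside class totals: %.1f-%.1f mg/g; THSG carries %.1f%% of the class\n",
            min(ct$totals[, "stilbene_glycoside"]),
            max(ct$totals[, "stilbene_glycoside"]),
            100 * ct$shares$stilbene_glycoside[["THSG"]]))
cat(sprintf("Anthraquinone class totals: %.2f-%.2f mg/g\n",
            min(ct$totals[, "anthraquinone"]), max(ct$totals[, "anthraquinone"])))
cat("Files written to results/synthetic/\n")
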
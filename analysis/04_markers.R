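#!/usr/bin/env Rscript
# Stage 4: identify differential hepatotoxicity markers between the least
# toxic (B) and most toxic (C) composition groups: OPLS-DA with one
# orthogonal component, 200x permutation validation, per-compound Welch
# t-tests with Benjamini-Hochberg FDR, and the conjunction rule
# VIP > 1 and q < 0.05.

suppressMessages(library(pmtox))
seed <- 1L

tab <- read_compound_table("results/synthetic/compound_table.csv",
                           "results/synthetic/compound_metadata.csv")
truth <- utils::read.csv("results/synthetic/group_labels.csv")

run_contrast <- function(g1, g2) {
  sel <- truth$group %in% c(g1, g2)
  X <- tab$concentrations[sel, ]
  y <- truth$group[sel]
  m <- fit_oplsda(autoscale(X), y, n_orthogonal = 1, seed = seed)
  perm <- permutation_test(autoscale(X), y, n_orthogonal = 1,
                           n_permutations = 200, seed = seed)
  mk <- marker_table(X, y, m$vip)
  cat(sprintf("\n%s vs %s: R2X = %.3f, R2Y = %.3f, Q2 = %.3f; permutation %s (Q2 intercept %.3f)\n",
              g1, g2, m$r2x, m$r2y, m$q2,
              if (perm$valid) "valid" else "NOT valid", perm$q2_intercept))
  flagged <- mk[mk$is_marker, ]
  cat(sprintf("  markers (VIP > 1, q < 0.05): %s\n",
              paste(sprintf("%s (VIP %.2f)", flagged$compound_id, flagged$vip),
                    collapse = ", ")))
  mk
}

mk_bc <- run_contrast("B", "C")
utils::write.csv(mk_bc, "results/markers_B_vs_C.csv", row.names = FALSE)
mk_bd <- run_contrast("B", "D")
utils::write.csv(mk_bd, "results/markers_B_vs_D.csv", row.names = FALSE)
cat("\nWrote results/markers_B_vs_C.csv, results/markers_B_vs_D.csv\n")
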
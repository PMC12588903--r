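#!/usr/bin/env Rscript
# Stage 3: CCK-8 viability, Hill/4PL fits, and the three-tier toxicity
# classification. Each group's simulated plate is reduced to viability
# fractions, fitted, and the IC50 mapped to its tier (low > 450, high < 390,
# medium in between, ug/mL).

suppressMessages(library(pmtox))

groups <- c("A", "B", "C", "D")
fits <- lapply(groups, function(g) {
  plate <- utils::read.csv(sprintf("results/synthetic/plate_group_%s.csv", g))
  v <- viability(plate$absorbance_dosing, plate$absorbance_blank,
                 plate$absorbance_control)
  fit_hill(plate$dose, v)
})

tiers <- data.frame(
  group = groups,
  ic50 = vapply(fits, function(f) f$params$ic50, numeric(1)),
  slope = vapply(fits, function(f) f$params$slope, numeric(1)),
  sse = vapply(fits, function(f) f$residual_sse, numeric(1)),
  extrapolated = vapply(fits, function(f) f$extrapolated, logical(1)))
tiers$tier <- classify_toxicity_tier(tiers$ic50)
utils::write.csv(tiers, "results/toxicity_tiers.csv", row.names = FALSE)

for (i in seq_along(groups))
  cat(sprintf("Group %s: IC50 = %.1f ug/mL (slope %.2f) -> %s toxicity\n",
              groups[i], tiers$ic50[i], tiers$slope[i], tiers$tier[i]))
cat("Wrote results/toxicity_tiers.csv\n")
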
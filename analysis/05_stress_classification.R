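#!/usr/bin/env Rscript
# Stage 5 -- stress indices, 10-grade scoring, RCI/PCI and group A-D
# classification per stress treatment, with Welch comparison of the
# extreme groups A and D on every trait.
#
# Yields are dry-biomass (BDw) genotype BLUPs: Yp from the control, Ys from
# the stress treatment under scrutiny.

library(phenotrial)

bl <- read.csv("results/blups.csv")
yield <- "BDw"
yb <- bl[bl$trait == yield, ]
Yp <- setNames(yb$value[yb$treatment == "C"], yb$genotype[yb$treatment == "C"])

for (trt in setdiff(unique(bl$treatment), "C")) {
  Ys <- setNames(yb$value[yb$treatment == trt],
                 yb$genotype[yb$treatment == trt])[names(Yp)]
  idx <- compute_stress_indices(Yp, Ys)
  scores <- classify_groups(compute_rci_pci(idx))
  cmp <- compare_extreme_groups(bl[bl$treatment == trt, ], scores)
  safe <- gsub("[^A-Za-z0-9]", "_", trt)
  write.csv(idx, sprintf("results/stress_indices_%s.csv", safe),
            row.names = FALSE)
  write.csv(scores, sprintf("results/scores_%s.csv", safe),
            row.names = FALSE)
  write.csv(cmp, sprintf("results/group_comparison_%s.csv", safe),
            row.names = FALSE)
  cat(sprintf("%-4s: SI = %.2f; groups:", trt, attr(idx, "SI")))
  print(table(scores$group))
  sig <- cmp$trait[cmp$stars != ""]
  cat("  A vs D significant traits:",
      if (length(sig)) paste(sig, collapse = ", ") else "(none)", "\n")
  cat("  group A:", paste(scores$genotype[scores$group == "A"],
                          collapse = ", "), "\n")
  cat("  group D:", paste(scores$genotype[scores$group == "D"],
                          collapse = ", "), "\n")
}
cat("wrote results/stress_indices_*, scores_*, group_comparison_*\n")
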
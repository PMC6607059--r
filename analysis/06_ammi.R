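#!/usr/bin/env Rscript
# Stage 6 -- AMMI stability analysis of the genotype x treatment dry-weight
# table: double-center, decompose by SVD, report IPC scores (symmetric
# biplot scaling), variance explained and per-genotype stability distances.

library(phenotrial)

bl <- read.csv("results/blups.csv")
tw <- two_way_table(bl, "BDw")
res <- ammi_decompose(double_center(tw), n_components = 2)
stab <- stability_summary(res)

scores <- rbind(
  data.frame(entity = "genotype", label = rownames(res$genotype_scores),
             IPC1 = res$genotype_scores[, 1], IPC2 = res$genotype_scores[, 2],
             distance = stab$distance, row.names = NULL),
  data.frame(entity = "treatment", label = rownames(res$treatment_scores),
             IPC1 = res$treatment_scores[, 1], IPC2 = res$treatment_scores[, 2],
             distance = sqrt(rowSums(res$treatment_scores^2)),
             row.names = NULL))
write.csv(scores, "results/ammi_scores.csv", row.names = FALSE)
jsonlite::write_json(list(singular_values = res$d,
                          variance_explained = res$variance_explained,
                          rank = res$rank),
                     "results/ammi_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("IPC1 + IPC2 explain %.1f%% of the interaction\n",
            sum(res$variance_explained[1:2])))
ord <- stab[order(stab$distance), ]
cat("most stable genotypes (smallest biplot distance):",
    paste(head(ord$genotype, 5), collapse = ", "), "\n")
cat("least stable:", paste(tail(ord$genotype, 3), collapse = ", "), "\n")
cat("wrote results/ammi_scores.csv, results/ammi_summary.json\n")
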
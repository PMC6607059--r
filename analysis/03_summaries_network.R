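#!/usr/bin/env Rscript
# Stage 3 -- descriptive summaries and correlation networks.
#
# Replicate-level means, CVs and percent reductions versus control, then
# Pearson correlation matrices and significance-filtered networks on the
# genotype BLUPs within each treatment (n = genotypes per correlation).

library(phenotrial)

tbl <- read_trait_table("results/trait_table.csv")
bl <- read.csv("results/blups.csv")

sm <- summarize_traits(tbl, control = "C")
write.csv(sm, "results/summary.csv", row.names = FALSE)
red <- aggregate(percent_reduction ~ treatment, sm[sm$reduction_defined, ], mean)
cat("average trait reduction vs control (%):\n")
print(red, row.names = FALSE, digits = 3)

for (trt in unique(bl$treatment)) {
  cm <- correlation_matrix(bl[bl$treatment == trt, ])
  net <- build_network(cm, alpha = 0.05)
  safe <- gsub("[^A-Za-z0-9]", "_", trt)
  write.csv(cm$r, sprintf("results/correlations_%s.csv", safe))
  jsonlite::write_json(list(nodes = net$nodes, edges = net$edges),
                       sprintf("results/network_%s.json", safe),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  r_bio <- cm$r["Tr01", c("BFw", "BDw")]  # Tr01 is a planted contributor
  cat(sprintf("%-4s: %3d significant edges; r(Tr01, BFw) = %.2f, r(Tr01, BDw) = %.2f\n",
              trt, nrow(net$edges), r_bio[1], r_bio[2]))
}
cat("wrote results/summary.csv, correlations_*.csv, network_*.json\n")
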
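#!/usr/bin/env Rscript
# Stage 2 -- variance components, heritability and BLUPs.
#
# For every trait, fits the two-way random-effects model (random treatment,
# genotype and genotype x treatment; fixed replicate) by REML under both a
# pooled and a per-treatment residual variance, keeps the AIC winner, tests
# the genotype term by a boundary-corrected likelihood-ratio test, and
# predicts genotype values per treatment. The BLUP table is the substrate
# for every later stage.

library(phenotrial)

tbl <- read_trait_table("results/trait_table.csv")
traits <- unique(tbl$trait)

rows <- list(); blups <- list()
for (tr in traits) {
  hom <- fit_reml(tbl, model_spec(tr, "homogeneous"))
  het <- fit_reml(tbl, model_spec(tr, "heterogeneous"))
  fit <- select_residual_model(hom, het)
  herit <- heritability_and_contributions(fit)
  # LR of the heterogeneous against the pooled residual structure
  lr <- lr_test_random(het, hom)
  rows[[tr]] <- data.frame(
    trait = tr, residual_model = fit$residual_model,
    sigma2_G = fit$sigma2_G, sigma2_T = fit$sigma2_T,
    sigma2_GT = fit$sigma2_GT, sigma2_E = mean(fit$sigma2_E),
    h2 = herit$h2,
    share_treatment = herit$contributions[["treatment"]],
    share_genotype = herit$contributions[["genotype"]],
    share_gxt = herit$contributions[["gxt"]],
    share_error = herit$contributions[["error"]],
    AIC_hom = hom$AIC, AIC_het = het$AIC,
    LR_residual_structure = lr$LR, p_residual_structure = lr$p_value)
  blups[[tr]] <- genotype_blups(fit)
}
vc <- do.call(rbind, rows); rownames(vc) <- NULL
write.csv(vc, "results/variance_components.csv", row.names = FALSE)
bl <- do.call(rbind, blups); rownames(bl) <- NULL
write.csv(bl, "results/blups.csv", row.names = FALSE)

cat("fitted", length(traits), "traits;",
    sum(vc$residual_model == "heterogeneous"), "selected heterogeneous residuals\n")
top <- vc[order(-vc$h2), c("trait", "h2")][1:5, ]
cat("highest heritabilities:\n")
print(top, row.names = FALSE, digits = 3)
cat("responses: h2(BDw) =", round(vc$h2[vc$trait == "BDw"], 3),
    " h2(BFw) =", round(vc$h2[vc$trait == "BFw"], 3), "\n")
cat("wrote results/variance_components.csv, results/blups.csv\n")
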
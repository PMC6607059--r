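#!/usr/bin/env Rscript
# Stage 4 -- which traits contribute to biomass? Ridge and lasso with
# fivefold cross-validation, fit per treatment x response on genotype
# BLUPs (n = 20 per fit), coefficients reported on standardized predictors
# with exact zeros blanked.

library(phenotrial)

SEED <- 1L
bl <- read.csv("results/blups.csv")
responses <- c("BFw", "BDw")
predictors <- setdiff(unique(bl$trait), responses)

blup_matrix <- function(b, traits) {
  genos <- sort(unique(b$genotype))
  sapply(traits, function(tr) {
    d <- b[b$trait == tr, ]
    setNames(d$value, d$genotype)[genos]
  })
}

for (method in c("lasso", "ridge")) {
  fits <- list()
  for (resp in responses) {
    for (trt in unique(bl$treatment)) {
      b <- bl[bl$treatment == trt, ]
      X <- blup_matrix(b, predictors)
      y <- blup_matrix(b, resp)[, 1]
      fits[[paste(resp, trt, sep = ".")]] <-
        cross_validate_lambda(standardize(X, y), method, seed = SEED)
    }
  }
  tab <- coefficient_table(fits)
  write.csv(tab, sprintf("results/%s_coefficients.csv", method),
            row.names = FALSE)
  if (method == "lasso") {
    nz <- vapply(fits, function(f) f$nonzero_count, numeric(1))
    cat("lasso non-zero coefficients per response.treatment:\n")
    print(nz)
    sel <- tab$predictor[tab[["BDw.C"]] != ""]
    cat("selected for BDw in control:", paste(sel, collapse = ", "), "\n")
  }
}
cat("wrote results/lasso_coefficients.csv, results/ridge_coefficients.csv\n")
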
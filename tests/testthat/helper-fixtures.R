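# shared fixture builders (all data generated in code; no stored files)

# minimal hand-built balanced table with prescribed genotype effects,
# no interaction, no noise
toy_table <- function(g_eff = c(-1, 0, 1), treatments = c("C", "W"),
                      n_reps = 2, mu = 10, trait = "y") {
  d <- expand.grid(replicate = seq_len(n_reps), treatment = treatments,
                   genotype = paste0("g", seq_along(g_eff)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$trait <- trait
  d$value <- mu + g_eff[match(d$genotype, paste0("g", seq_along(g_eff)))]
  d[, c("genotype", "treatment", "replicate", "trait", "value")]
}

# dense GLS / mixed-model-equation oracle, assembled independently of the
# package internals: V-based solve for beta, u and the REML log-likelihood
dense_mme_oracle <- function(data, fit) {
  d <- data[data$trait == fit$trait, ]
  d$genotype <- factor(d$genotype)
  d$treatment <- factor(d$treatment, levels = unique(d$treatment))
  d$replicate <- factor(d$replicate)
  X <- if (fit$design$p > 1) stats::model.matrix(~replicate, d) else
    matrix(1, nrow(d), 1)
  Zt <- stats::model.matrix(~0 + treatment, d)
  Zg <- stats::model.matrix(~0 + genotype, d)
  Zgt <- stats::model.matrix(~0 + genotype:treatment, d)
  vE <- if (length(fit$sigma2_E) > 1)
    as.numeric(fit$sigma2_E)[as.integer(d$treatment)] else
      rep(fit$sigma2_E, nrow(d))
  V <- fit$sigma2_T * tcrossprod(Zt) + fit$sigma2_G * tcrossprod(Zg) +
    fit$sigma2_GT * tcrossprod(Zgt) + diag(vE)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% d$value)
  G <- diag(c(rep(fit$sigma2_T, ncol(Zt)), rep(fit$sigma2_G, ncol(Zg)),
              rep(fit$sigma2_GT, ncol(Zgt))))
  Z <- cbind(Zt, Zg, Zgt)
  u <- G %*% t(Z) %*% Vi %*% (d$value - X %*% beta)
  P <- Vi - Vi %*% X %*% solve(XtVi %*% X) %*% XtVi
  ll <- -0.5 * ((nrow(d) - ncol(X)) * log(2 * pi) +
                  as.numeric(determinant(V)$modulus) +
                  as.numeric(determinant(XtVi %*% X)$modulus) +
                  drop(t(d$value) %*% P %*% d$value))
  nT <- ncol(Zt); nG <- ncol(Zg)
  gt <- matrix(u[(nT + nG + 1):length(u)], nG, nT)
  mu_fix <- beta[1] + if (length(beta) > 1) mean(c(0, beta[-1])) else 0
  grid <- expand.grid(genotype = levels(d$genotype),
                      treatment = levels(d$treatment),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(grid$genotype, levels(d$genotype))
  tj <- match(grid$treatment, levels(d$treatment))
  grid$value <- mu_fix + u[tj] + u[nT + gi] + gt[cbind(gi, tj)]
  list(logREML = ll, blups = grid)
}

# genotype-level trait matrix (means across replicates) for one treatment
genotype_means_matrix <- function(tbl, treatment) {
  d <- tbl[tbl$treatment == treatment, ]
  ag <- stats::aggregate(value ~ genotype + trait, d, mean)
  m <- stats::reshape(ag, idvar = "genotype", timevar = "trait",
                      direction = "wide")
  rownames(m) <- m$genotype
  m <- as.matrix(m[, -1, drop = FALSE])
  colnames(m) <- sub("^value\\.", "", colnames(m))
  m
}
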
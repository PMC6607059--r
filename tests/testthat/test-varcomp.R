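test_that("method-of-moments matches hand EMS arithmetic on the toy fixture", {
  # genotype effects (-1,0,1), T=2, R=2, no interaction, no noise:
  # MS_G = R*T*sum((g-gbar)^2)/(G-1) = 4, MS_GT = MS_E = 0
  d <- toy_table()
  m <- fit_moments(d, "y")
  expect_equal(m$mean_squares[["MS_G"]], 4)
  expect_equal(m$sigma2_G, 1)
  expect_equal(m$sigma2_GT, 0)
  expect_equal(m$sigma2_E, 0)
})

test_that("constant data gives all-zero components; truncation never goes negative", {
  d <- toy_table(g_eff = c(0, 0, 0))
  m <- fit_moments(d, "y")
  expect_equal(m$sigma2_G + m$sigma2_GT + m$sigma2_E + m$sigma2_T, 0)
  # noise-only data: raw EMS solutions can be negative, estimates must not be
  for (s in 1:10) {
    tbl <- simulate_trial(sim_config(n_genotypes = 4, n_reps = 3,
                                     sigma2_G = 0, sigma2_GT = 0,
                                     sigma2_E = 1, seed = 300 + s))
    m <- fit_moments(tbl, "BDw")
    expect_true(all(c(m$sigma2_G, m$sigma2_GT, m$sigma2_T, m$sigma2_E) >= 0))
  }
})

test_that("fit_moments rejects unbalanced data, fit_reml rejects degenerate designs", {
  d <- toy_table()
  expect_error(fit_moments(d[-1, ], "y"), "fit_reml")
  one_geno <- d[d$genotype == "g1", ]
  expect_error(fit_reml(one_geno, model_spec("y")), ">= 2 genotypes")
})

test_that("REML equals the MoM oracle on balanced interior fixtures", {
  worst <- 0
  for (s in 1:5) {
    tbl <- simulate_trial(sim_config(n_genotypes = 8, n_reps = 4,
                                     sigma2_G = 2, sigma2_GT = 1,
                                     sigma2_E = 1, seed = 40 + s))
    m <- fit_moments(tbl, "BDw")
    if (isTRUE(m$boundary)) next
    f <- fit_reml(tbl, model_spec("BDw", include_replicate_fixed = FALSE,
                                  tol = 1e-12))
    worst <- max(worst,
                 abs(f$sigma2_G - m$sigma2_G) / m$sigma2_G,
                 abs(f$sigma2_GT - m$sigma2_GT) / m$sigma2_GT,
                 abs(f$sigma2_E - m$sigma2_E) / m$sigma2_E)
  }
  expect_lt(worst, 1e-6)
})

test_that("REML on the degenerate no-noise fixture reaches the boundary solution", {
  # zero residual variance puts the optimum on the 1e-10 bound where the
  # restricted likelihood is dominated by cancellation noise; ~1% precision
  # in sigma2_G is the attainable floating-point limit there
  d <- toy_table()
  f <- fit_reml(d, model_spec("y", include_replicate_fixed = FALSE,
                              tol = 1e-12))
  expect_equal(f$sigma2_G, 1, tolerance = 0.02)
  expect_lt(f$sigma2_GT, 1e-8)
  expect_lt(f$sigma2_E, 1e-8)
})

test_that("REML agrees with an independently assembled dense GLS oracle", {
  tbl <- simulate_trial(sim_config(n_genotypes = 5, treatments = c("C", "N", "W"),
                                   n_reps = 3, sigma2_G = 2, sigma2_GT = 0.5,
                                   sigma2_E = 1, seed = 7))
  f <- fit_reml(tbl, model_spec("BDw", tol = 1e-12))
  oracle <- dense_mme_oracle(tbl, f)
  expect_equal(f$logREML, oracle$logREML, tolerance = 1e-8)
  bl <- genotype_blups(f)
  key <- paste(bl$genotype, bl$treatment)
  okey <- paste(oracle$blups$genotype, oracle$blups$treatment)
  expect_equal(bl$value, oracle$blups$value[match(key, okey)],
               tolerance = 1e-6)
})

test_that("AIC identity and model selection rules", {
  tbl <- simulate_trial(sim_config(seed = 2))
  hom <- fit_reml(tbl, model_spec("BDw", "homogeneous"))
  het <- fit_reml(tbl, model_spec("BDw", "heterogeneous"))
  expect_equal(hom$AIC, -2 * hom$logREML + 2 * 4)
  expect_equal(het$AIC, -2 * het$logREML + 2 * 7)
  sel <- select_residual_model(hom, het)
  expect_identical(sel$residual_model,
                   if (het$AIC < hom$AIC) "heterogeneous" else "homogeneous")
  # tie goes to the simpler model: equal logREML, 4 vs 7 parameters
  hom2 <- hom; het2 <- het
  het2$logREML <- hom2$logREML
  het2$AIC <- -2 * het2$logREML + 2 * 7
  expect_identical(select_residual_model(hom2, het2)$residual_model,
                   "homogeneous")
  # 10 log-likelihood units buy 3 parameters easily (delta AIC = -14)
  het3 <- het2
  het3$logREML <- hom2$logREML + 10
  het3$AIC <- -2 * het3$logREML + 2 * 7
  expect_identical(select_residual_model(hom2, het3)$residual_model,
                   "heterogeneous")
  other <- hom2; other$trait <- "other"
  expect_error(select_residual_model(other, het2), "different traits")
})

test_that("likelihood-ratio test uses the boundary chi-square mixture", {
  tbl <- simulate_trial(sim_config(seed = 2))
  full <- fit_reml(tbl, model_spec("BDw", "heterogeneous"))
  red <- fit_reml(tbl, model_spec("BDw", "homogeneous"))
  # equal likelihoods -> LR 0, p 1
  same <- full; same$logREML <- red$logREML
  expect_equal(lr_test_random(same, red)$LR, 0)
  expect_equal(lr_test_random(same, red)$p_value, 1)
  # LR = 3.84 -> p = 0.5 * P(chi2_1 >= 3.84)
  shifted <- full; shifted$logREML <- red$logREML + 3.84 / 2
  expect_equal(lr_test_random(shifted, red)$p_value,
               0.5 * pchisq(3.84, 1, lower.tail = FALSE))
  # numerically lower full likelihood clips at 0
  worse <- full; worse$logREML <- red$logREML - 0.3
  expect_equal(lr_test_random(worse, red)$LR, 0)
  expect_error(lr_test_random(red, full), "non-nested")
})

test_that("heritability formula, limits and contribution shares", {
  f <- fit_moments(toy_table(), "y")
  f$sigma2_G <- 2; f$sigma2_GT <- 1; f$sigma2_E <- 1; f$sigma2_T <- 0.5
  h <- heritability_and_contributions(f)
  expect_equal(h$h2, 0.5)
  expect_equal(sum(h$contributions), 1, tolerance = 1e-12)
  f$sigma2_GT <- 0; f$sigma2_E <- 0
  expect_equal(heritability_and_contributions(f)$h2, 1)
  f$sigma2_G <- 0; f$sigma2_E <- 1
  expect_equal(heritability_and_contributions(f)$h2, 0)
  f$sigma2_E <- 0; f$sigma2_T <- 0
  expect_error(heritability_and_contributions(f), "undefined")
  # heterogeneous residuals enter as their unweighted mean
  f$sigma2_G <- 2; f$sigma2_GT <- 1; f$sigma2_E <- c(0.5, 1.5); f$sigma2_T <- 1
  expect_equal(heritability_and_contributions(f)$h2, 2 / 4)
})

test_that("more residual noise never increases heritability on average", {
  h2_at <- function(s2e) {
    mean(vapply(1:20, function(s) {
      tbl <- simulate_trial(sim_config(n_genotypes = 10, n_reps = 4,
                                       sigma2_G = 2, sigma2_GT = 0.5,
                                       sigma2_E = s2e, seed = 900 + s))
      f <- fit_moments(tbl, "BDw")
      f$sigma2_G / (f$sigma2_G + f$sigma2_GT + mean(f$sigma2_E))
    }, numeric(1)))
  }
  curve <- vapply(c(0.5, 2, 8), h2_at, numeric(1))
  expect_true(all(diff(curve) < 0))
})

test_that("BLUPs shrink toward the treatment mean and hit the no-noise limit", {
  # no-noise limit: predictions equal observed cell means
  d <- toy_table(g_eff = c(-2, 0, 2))
  f <- fit_reml(d, model_spec("y", include_replicate_fixed = FALSE,
                              tol = 1e-12))
  bl <- genotype_blups(f)
  cell <- aggregate(value ~ genotype + treatment, d, mean)
  key <- paste(bl$genotype, bl$treatment)
  expect_equal(bl$value,
               cell$value[match(key, paste(cell$genotype, cell$treatment))],
               tolerance = 1e-6)
  # shrinkage: within each treatment, predicted genotype values are less
  # dispersed than the raw cell means
  tbl <- simulate_trial(sim_config(n_genotypes = 8, n_reps = 3,
                                   sigma2_G = 1, sigma2_GT = 0.3,
                                   sigma2_E = 2, seed = 77))
  f2 <- fit_reml(tbl, model_spec("BDw"))
  bl2 <- genotype_blups(f2)
  cell2 <- aggregate(value ~ genotype + treatment, tbl, mean)
  for (trt in unique(bl2$treatment)) {
    expect_lte(var(bl2$value[bl2$treatment == trt]),
               var(cell2$value[cell2$treatment == trt]) + 1e-10)
  }
})

test_that("a planted gross outlier is flagged and only that observation", {
  tbl <- simulate_trial(sim_config(n_genotypes = 10, n_reps = 4,
                                   sigma2_G = 1, sigma2_GT = 0.2,
                                   sigma2_E = 0.5, seed = 13))
  tbl$value[100] <- tbl$value[100] + 10 * sqrt(0.5)
  f <- fit_reml(tbl, model_spec("BDw"))
  fl <- flag_outliers(tbl, f, threshold = 3)
  expect_gte(nrow(fl), 1)
  expect_true(any(fl$genotype == tbl$genotype[100] &
                    fl$treatment == tbl$treatment[100] &
                    fl$replicate == tbl$replicate[100]))
  expect_lte(nrow(fl), 3)  # no mass false flagging
  expect_identical(nrow(flag_outliers(tbl, f, threshold = Inf)), 0L)
})

test_that("clean Gaussian data yields the expected few studentized flags", {
  n_flags <- vapply(1:5, function(s) {
    tbl <- simulate_trial(sim_config(seed = 500 + s))
    f <- fit_reml(tbl, model_spec("BDw"))
    nrow(flag_outliers(tbl, f, threshold = 3))
  }, numeric(1))
  # 640 * P(|Z| > 3) ~ 1.7 expected per trial
  expect_true(all(n_flags >= 0 & n_flags <= 8))
})

test_that("replicate fixed-effect z-test detects a planted replicate shift", {
  cfg <- sim_config(n_genotypes = 10, n_reps = 4,
                    replicate_effects = c(0, 0, 0, 3),
                    sigma2_G = 1, sigma2_GT = 0.2, sigma2_E = 0.5, seed = 21)
  tbl <- simulate_trial(cfg)
  f <- fit_reml(tbl, model_spec("BDw"))
  w <- wald_test_replicate(f)
  expect_equal(nrow(w), 3)
  expect_lt(w$p_value[w$term == "replicate4"], 1e-6)
  expect_gt(min(w$p_value[w$term != "replicate4"]), 0.01)
})

test_that("REML components and likelihood agree with lme4 on the homogeneous model", {
  skip_if_not_installed("lme4")
  tbl <- simulate_trial(sim_config(n_genotypes = 10, n_reps = 4, seed = 31))
  f <- fit_reml(tbl, model_spec("BDw", "homogeneous", tol = 1e-12))
  d <- tbl
  d$replicate <- factor(d$replicate)
  lf <- lme4::lmer(value ~ replicate + (1 | treatment) + (1 | genotype) +
                     (1 | genotype:treatment),
                   data = d, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(lf))
  get <- function(g) vc$vcov[vc$grp == g]
  expect_equal(f$sigma2_G, get("genotype"), tolerance = 1e-4)
  expect_equal(f$sigma2_GT, get("genotype:treatment"), tolerance = 1e-4)
  expect_equal(f$sigma2_E, get("Residual"), tolerance = 1e-4)
  expect_equal(-2 * f$logREML, lme4::REMLcrit(lf), tolerance = 1e-6)
})
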
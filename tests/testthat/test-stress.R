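test_that("stress indices match direct formula arithmetic", {
  # Yp=16, Ys=4 -> MP=10, GMP=8, TOL=12
  idx <- compute_stress_indices(Yp = c(16, 10), Ys = c(4, 9))
  expect_equal(idx$MP[1], 10)
  expect_equal(idx$GMP[1], 8)
  expect_equal(idx$TOL[1], 12)
  # SI routed through SSI: Yp=(10,10), Ys=(5,10) -> SI=0.25, SSI=(2,0)
  idx2 <- compute_stress_indices(Yp = c(10, 10), Ys = c(5, 10))
  expect_equal(attr(idx2, "SI"), 0.25)
  expect_equal(idx2$SSI, c(2, 0))
  # stress-neutral genotype
  expect_equal(idx2$TOL[2], 0)
  expect_equal(idx2$GMP[2], idx2$MP[2])
})

test_that("index identities hold on random positive yield vectors", {
  set.seed(15)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    Yp <- rlnorm(n, 3, 0.4)
    Ys <- Yp * runif(n, 0.3, 0.95)
    idx <- compute_stress_indices(Yp, Ys)
    expect_true(all(idx$GMP <= idx$MP + 1e-12))
    expect_equal(idx$STI, idx$GMP^2 / attr(idx, "Yp_bar")^2,
                 tolerance = 1e-12)
    expect_true(all((idx$TOL == 0) == (idx$Yp == idx$Ys)))
    # a genotype with exactly the population-average loss ratio has SSI = 1
    Yp2 <- c(Yp, 100)
    Ys2 <- c(Ys, 100 * mean(Ys) / mean(Yp))
    si2 <- 1 - mean(Ys2) / mean(Yp2)
    idx2 <- compute_stress_indices(Yp2, Ys2)
    expect_equal(idx2$SSI[n + 1],
                 (1 - Ys2[n + 1] / Yp2[n + 1]) / si2, tolerance = 1e-12)
  }
  expect_error(compute_stress_indices(c(1, 2), c(2, 3)),
               "no population-level stress")
  expect_error(compute_stress_indices(c(1, -1), c(0.5, 0.5)), "positive")
})

test_that("10-grade scoring endpoints, rounding and orientation", {
  # higher_better: min -> 1, max -> 10; (0, 4.5, 9) -> (1, 6, 10) (half-up)
  expect_identical(score_indices(c(0, 4.5, 9), "higher_better"),
                   c(1L, 6L, 10L))
  x <- c(3, 8, 1, 5)
  s <- score_indices(x, "higher_better")
  expect_identical(s[which.min(x)], 1L)
  expect_identical(s[which.max(x)], 10L)
  # lower_better flips: lowest SSI scores 10
  ssi <- c(1.2, 0.3, 2.0)
  expect_identical(score_indices(ssi, "lower_better")[2], 10L)
  expect_identical(score_indices(rep(4, 6), "higher_better"), rep(5L, 6))
  expect_error(score_indices(numeric(0)), "empty")
})

test_that("scores are invariant under increasing affine transforms", {
  set.seed(16)
  for (method in c("minmax", "decile")) {
    x <- rnorm(15)
    expect_identical(score_indices(x, "higher_better", method),
                     score_indices(3 * x + 7, "higher_better", method))
  }
})

test_that("decile-rank scoring variant spans 1..10 on distinct values", {
  x <- 1:20
  s <- score_indices(x, "higher_better", method = "decile")
  expect_identical(range(s), c(1L, 10L))
  expect_true(all(diff(s) >= 0))
})

test_that("RCI/PCI aggregation matches the stated means", {
  idx <- compute_stress_indices(Yp = c(20, 15, 10, 8), Ys = c(18, 9, 8, 3))
  sc <- compute_rci_pci(idx)
  expect_equal(sc$RCI, (sc$score_SSI + sc$score_TOL) / 2)
  expect_equal(sc$PCI, (sc$score_MP + sc$score_GMP + sc$score_STI) / 3)
  expect_true(all(sc$RCI >= 1 & sc$RCI <= 10))
  expect_true(all(sc$PCI >= 1 & sc$PCI <= 10))
})

test_that("quadrant classification: corners, tie rule and completeness", {
  sc <- data.frame(genotype = paste0("g", 1:4),
                   RCI = c(9, 2, 9, 2), PCI = c(9, 2, 2, 9))
  cl <- classify_groups(sc)
  expect_identical(as.character(cl$group), c("A", "D", "C", "B"))
  # value exactly at the mean goes to the high side
  sc2 <- data.frame(genotype = c("a", "b"), RCI = c(5, 5), PCI = c(5, 5))
  expect_identical(as.character(classify_groups(sc2)$group), c("A", "A"))
  # B/C orientation is configurable
  cl2 <- classify_groups(sc, mixed_orientation = "B_resilient")
  expect_identical(as.character(cl2$group), c("A", "D", "B", "C"))
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  cl_perm <- classify_groups(sc[perm, ])
  expect_identical(as.character(cl_perm$group),
                   as.character(cl$group)[perm])
})

test_that("planted A/D archetypes are recovered end to end at vanishing noise", {
  planted <- rep(c("A", "B", "C", "D"), times = c(5, 5, 5, 5))
  sim <- sim_config(n_genotypes = 20, n_reps = 4, seed = 17)
  pan <- panel_config(n_traits = 4, beta = c(1e-6, 0, 0, 0), noise_sd = 1e-9,
                      block_structure = rep(1:2, each = 2),
                      sigma_G_trait = 1e-6, sigma_E_trait = 1e-6,
                      planted_groups = planted)
  tbl <- simulate_trait_panel(sim, pan)
  mC <- genotype_means_matrix(tbl, "C")
  mW <- genotype_means_matrix(tbl, "W")
  idx <- compute_stress_indices(mC[, "BDw"], mW[, "BDw"],
                                genotypes = rownames(mC))
  cl <- classify_groups(compute_rci_pci(idx))
  got <- setNames(as.character(cl$group), cl$genotype)
  pl <- setNames(planted, phenotrial:::genotype_labels(20))
  expect_identical(got[pl == "A"], pl[pl == "A"])
  expect_identical(got[pl == "D"], pl[pl == "D"])
})

test_that("Welch comparison reproduces summary-statistic arithmetic", {
  # A: mean 154, se 4, n 5; D: mean 139, se 1, n 4 -> t = 15/sqrt(17)
  make_vec <- function(n, m, se) {
    v <- scale(rnorm(n))  # exact mean 0, sd 1
    drop(m + v * se * sqrt(n))
  }
  set.seed(18)
  vA <- make_vec(5, 154, 4)
  vD <- make_vec(4, 139, 1)
  tv <- data.frame(genotype = c(paste0("a", 1:5), paste0("d", 1:4)),
                   trait = "EBv", value = c(vA, vD))
  groups <- setNames(rep(c("A", "D"), c(5, 4)), tv$genotype)
  cmp <- compare_extreme_groups(tv, groups)
  expect_equal(cmp$mean_A, 154)
  expect_equal(cmp$se_A, 4)
  expect_equal(cmp$t, 15 / sqrt(17), tolerance = 1e-10)
  expect_true(cmp$p_value < 0.05)
  expect_true(cmp$stars %in% c("*", "**"))
  # identical groups -> t = 0, p = 1
  cmp3 <- compare_extreme_groups(
    data.frame(genotype = c("a1", "a2", "d1", "d2"), trait = "x",
               value = c(1, 2, 1, 2)),
    setNames(c("A", "A", "D", "D"), c("a1", "a2", "d1", "d2")))
  expect_equal(cmp3$t, 0)
  expect_equal(cmp3$p_value, 1)
  # undersized group is skipped with a warning
  expect_warning(
    out <- compare_extreme_groups(tv, setNames(c("A", rep("D", 8)),
                                               tv$genotype)),
    "skipped")
  expect_identical(nrow(out), 0L)
})

test_that("derived indices are computed, validated and non-destructive", {
  d <- data.frame(genotype = c("g1", "g2"), BDw = c(15, 20),
                  PHg = c(100, 120), NC = c(2, 2.5), water = c(7.5, 8))
  out <- compute_derived_indices(d, list(WUE = "BDw / water"))
  expect_equal(out$WUE, c(2, 2.5))
  expect_identical(out$BDw, d$BDw)
  expect_error(compute_derived_indices(d, list(SPW = "BDw / missing_col")),
               "missing_col")
  d0 <- d; d0$water[1] <- 0
  expect_error(compute_derived_indices(d0, list(WUE = "BDw / water")),
               "non-finite")
  # swapping a formula only changes the derived column
  out2 <- compute_derived_indices(d, list(WUE = "BDw / (2 * water)"))
  expect_identical(out2[, names(d)], d)
  expect_equal(out2$WUE, out$WUE / 2)
})
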
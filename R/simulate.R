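#' Configuration for a synthetic balanced phenotyping trial
#'
#' Defines the sampling counterpart of the two-way random-effects model used
#' throughout the package: for genotype i, treatment j and replicate k,
#' \deqn{y_{ijk} = \mu + r_k + t_j + g_i + (gt)_{ij} + \epsilon_{ijk}}
#' with \eqn{g_i \sim N(0, \sigma^2_G)}, \eqn{(gt)_{ij} \sim N(0, \sigma^2_{GT})}
#' and \eqn{\epsilon_{ijk} \sim N(0, \sigma^2_E(j))}. Treatment effects
#' \eqn{t_j} and replicate effects \eqn{r_k} are fixed shifts.
#'
#' Defaults emulate the study design the package targets: 20 genotypes
#' (inbred lines) x 4 treatments (control C, nitrogen stress N, water stress
#' W, combined N+W) x 8 replicates = 640 plants, with treatment means
#' ordered C > N > W > N+W. The default treatment effects reduce the control
#' mean by 3.2\%, 19.3\% and 21.8\% for N, W and N+W, matching the average
#' stress-induced trait reductions in the trial the generator emulates.
#'
#' @param n_genotypes Number of genotypes (>= 2).
#' @param treatments Character vector of treatment labels; the first is the
#'   control. At least 2.
#' @param n_reps Replicates per genotype x treatment cell (>= 2).
#' @param mu Global mean on the trait scale.
#' @param treatment_effects Numeric vector of fixed treatment shifts, one per
#'   treatment (recycled names from `treatments`).
#' @param replicate_effects Optional fixed replicate shifts (length
#'   `n_reps`); default all zero.
#' @param sigma2_G Genotype variance (>= 0).
#' @param sigma2_GT Genotype-by-treatment interaction variance (>= 0).
#' @param sigma2_E Residual variance; scalar (homogeneous) or one value per
#'   treatment (heterogeneous). A scalar is broadcast.
#' @param log_normal If `TRUE`, the model is simulated on the log scale and
#'   exponentiated, guaranteeing positive trait values (for weights/areas).
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' head(simulate_trial(cfg))
sim_config <- function(n_genotypes = 20,
                       treatments = c("C", "N", "W", "N+W"),
                       n_reps = 8,
                       mu = 20,
                       treatment_effects = mu * c(0, -0.032, -0.193, -0.218),
                       replicate_effects = NULL,
                       sigma2_G = 2,
                       sigma2_GT = 0.5,
                       sigma2_E = 1,
                       log_normal = FALSE,
                       seed = NULL) {
  if (length(treatments) < 2 || anyDuplicated(treatments)) {
    stop("need at least 2 distinct treatments", call. = FALSE)
  }
  if (n_genotypes < 2) stop("need at least 2 genotypes", call. = FALSE)
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  if (length(treatment_effects) != length(treatments)) {
    # default above is calibrated for 4 treatments; recycle a zero vector
    # for other layouts unless the user supplied effects explicitly
    if (missing(treatment_effects)) {
      treatment_effects <- rep(0, length(treatments))
    } else {
      stop("treatment_effects must have one value per treatment", call. = FALSE)
    }
  }
  if (is.null(replicate_effects)) replicate_effects <- rep(0, n_reps)
  if (length(replicate_effects) != n_reps) {
    stop("replicate_effects must have length n_reps", call. = FALSE)
  }
  if (length(sigma2_E) == 1) sigma2_E <- rep(sigma2_E, length(treatments))
  if (length(sigma2_E) != length(treatments)) {
    stop("sigma2_E must be scalar or one value per treatment", call. = FALSE)
  }
  if (any(c(sigma2_G, sigma2_GT, sigma2_E) < 0)) {
    stop("variances must be non-negative", call. = FALSE)
  }
  structure(list(
    n_genotypes = as.integer(n_genotypes),
    treatments = as.character(treatments),
    n_reps = as.integer(n_reps),
    mu = mu,
    treatment_effects = stats::setNames(treatment_effects, treatments),
    replicate_effects = replicate_effects,
    sigma2_G = sigma2_G,
    sigma2_GT = sigma2_GT,
    sigma2_E = stats::setNames(sigma2_E, treatments),
    log_normal = isTRUE(log_normal),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' Configuration for a correlated multi-trait panel
#'
#' Describes the predictor-trait panel layered on top of [sim_config()]:
#' traits are partitioned into blocks with within-block correlation `rho_b`
#' (cross-block correlation 0), and two biomass responses (`BFw`, `BDw`) are
#' built at replicate level as a sparse linear combination `X beta` of the
#' predictor traits plus Gaussian noise. Optionally, genotypes are assigned
#' to planted A/B/C/D archetypes that control their non-stress (Yp) and
#' stress (Ys) biomass profiles, so downstream classification has a known
#' truth to recover.
#'
#' @param n_traits Number of predictor traits.
#' @param block_structure Integer vector of length `n_traits` assigning each
#'   trait to a correlation block.
#' @param rho_b Within-block correlation, |rho_b| < 1.
#' @param beta Coefficient vector (length `n_traits`) linking traits to the
#'   biomass responses; must contain at least one zero and one non-zero.
#' @param noise_sd Response noise standard deviation.
#' @param trait_mu Baseline level of the predictor traits (keeps them on a
#'   positive scale, like areas or intensities, so CVs and percent
#'   reductions are meaningful).
#' @param response_mu Baseline response level added before `X beta` (keeps
#'   biomass positive on the expected scale).
#' @param sigma_G_trait,sigma_E_trait Genotype / residual SDs of the
#'   predictor traits.
#' @param planted_groups Optional character vector (length `n_genotypes`,
#'   values in A/B/C/D) of planted response archetypes, or `NULL`.
#' @param archetype_dev 2-column matrix (control, stress deviations) with
#'   rows A, B, C, D defining the planted Yp/Ys profiles.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_traits = 25,
                         block_structure = rep(seq_len(3), length.out = n_traits),
                         rho_b = 0.6,
                         beta = c(rep(0.4, 3), rep(0, n_traits - 3)),
                         noise_sd = 1,
                         trait_mu = 10,
                         response_mu = 20,
                         sigma_G_trait = 1,
                         sigma_E_trait = 1,
                         planted_groups = NULL,
                         archetype_dev = rbind(A = c(5, 6), B = c(5, -2),
                                               C = c(-5, 2), D = c(-5, -6))) {
  if (abs(rho_b) >= 1) stop("|rho_b| must be < 1", call. = FALSE)
  if (length(beta) != n_traits) {
    stop("beta length must equal n_traits", call. = FALSE)
  }
  if (!any(beta == 0) || !any(beta != 0)) {
    stop("beta must contain at least one zero and one non-zero entry",
         call. = FALSE)
  }
  if (length(block_structure) != n_traits) {
    stop("block_structure must assign every trait to a block", call. = FALSE)
  }
  if (!is.null(planted_groups) &&
      !all(planted_groups %in% rownames(archetype_dev))) {
    stop("planted_groups must use archetype labels ",
         paste(rownames(archetype_dev), collapse = "/"), call. = FALSE)
  }
  structure(list(
    n_traits = as.integer(n_traits),
    block_structure = as.integer(block_structure),
    rho_b = rho_b,
    beta = beta,
    noise_sd = noise_sd,
    trait_mu = trait_mu,
    response_mu = response_mu,
    sigma_G_trait = sigma_G_trait,
    sigma_E_trait = sigma_E_trait,
    planted_groups = planted_groups,
    archetype_dev = archetype_dev
  ), class = "panel_config")
}

genotype_labels <- function(n) sprintf("IL%02d", seq_len(n))

#' Simulate one trait of a balanced trial
#'
#' Draws a complete balanced genotype x treatment x replicate table for a
#' single trait under the model described in [sim_config()]. Identical
#' configurations (including `seed`) give bitwise-identical tables.
#'
#' @param config A [sim_config()] object.
#' @param trait_name Name recorded in the `trait` column.
#' @return A `data.frame` with columns `genotype`, `treatment`, `replicate`,
#'   `trait`, `value` (one row per plant).
#' @export
simulate_trial <- function(config, trait_name = "BDw") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  G <- config$n_genotypes
  Tn <- length(config$treatments)
  R <- config$n_reps
  g <- stats::rnorm(G, 0, sqrt(config$sigma2_G))
  gt <- matrix(stats::rnorm(G * Tn, 0, sqrt(config$sigma2_GT)), G, Tn)
  grid <- expand.grid(
    replicate = seq_len(R),
    treatment = config$treatments,
    genotype = genotype_labels(G),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("genotype", "treatment", "replicate")]
  gi <- match(grid$genotype, genotype_labels(G))
  tj <- match(grid$treatment, config$treatments)
  eps <- stats::rnorm(nrow(grid), 0, sqrt(config$sigma2_E[tj]))
  value <- config$mu + config$treatment_effects[tj] +
    config$replicate_effects[grid$replicate] +
    g[gi] + gt[cbind(gi, tj)] + eps
  if (config$log_normal) value <- exp(value)
  data.frame(grid, trait = trait_name, value = unname(value),
             stringsAsFactors = FALSE)
}

#' Simulate a correlated multi-trait panel with biomass responses
#'
#' Generates `n_traits` predictor traits with the block-correlation structure
#' of [panel_config()], plus two biomass responses `BFw` and `BDw` built at
#' replicate level as `response_mu + X beta + archetype profile + noise`.
#' Predictor traits carry genotype effects (correlated within blocks with the
#' same `rho_b`) so that genotype-level correlations mirror the planted
#' structure.
#'
#' @param sim A [sim_config()] object (design dimensions, treatment effects,
#'   seed).
#' @param panel A [panel_config()] object.
#' @return A long `data.frame` (`genotype`, `treatment`, `replicate`,
#'   `trait`, `value`) containing the predictor traits named `Tr01`... plus
#'   `BFw` and `BDw`. The planted group assignment (if any) is attached as
#'   attribute `planted_groups`, the planted coefficient vector as `beta`.
#' @export
simulate_trait_panel <- function(sim, panel) {
  stopifnot(inherits(sim, "sim_config"), inherits(panel, "panel_config"))
  if (!is.null(sim$seed)) set.seed(sim$seed)
  G <- sim$n_genotypes
  Tn <- length(sim$treatments)
  R <- sim$n_reps
  n_obs <- G * Tn * R
  p <- panel$n_traits
  blocks <- panel$block_structure
  nb <- max(blocks)
  rho <- panel$rho_b
  mix <- function(f, e) sqrt(abs(rho)) * f[, blocks, drop = FALSE] +
    sqrt(1 - abs(rho)) * e
  # genotype effects for the predictor traits (G x p), block-correlated
  gf <- matrix(stats::rnorm(G * nb), G, nb)
  ge <- matrix(stats::rnorm(G * p), G, p)
  g_eff <- panel$sigma_G_trait * mix(gf, ge)
  # observation-level residuals (n_obs x p), block-correlated
  of <- matrix(stats::rnorm(n_obs * nb), n_obs, nb)
  oe <- matrix(stats::rnorm(n_obs * p), n_obs, p)
  e_eff <- panel$sigma_E_trait * mix(of, oe)

  grid <- expand.grid(
    replicate = seq_len(R),
    treatment = sim$treatments,
    genotype = genotype_labels(G),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("genotype", "treatment", "replicate")]
  gi <- match(grid$genotype, genotype_labels(G))
  tj <- match(grid$treatment, sim$treatments)

  trt_shift <- sim$treatment_effects[tj]             # shared treatment profile
  X <- panel$trait_mu + g_eff[gi, , drop = FALSE] + e_eff + trt_shift

  arch <- rep(0, n_obs)
  if (!is.null(panel$planted_groups)) {
    pg <- panel$planted_groups
    if (length(pg) != G) stop("planted_groups must cover all genotypes",
                              call. = FALSE)
    dev <- panel$archetype_dev[pg, , drop = FALSE]
    is_ctrl <- tj == 1L
    arch <- ifelse(is_ctrl, dev[gi, 1], dev[gi, 2])
  }
  resp_core <- panel$response_mu + trt_shift + drop(X %*% panel$beta) + arch
  BFw <- resp_core * 10 + stats::rnorm(n_obs, 0, panel$noise_sd * 10)
  BDw <- resp_core + stats::rnorm(n_obs, 0, panel$noise_sd)

  traits <- cbind(X, BFw = BFw, BDw = BDw)
  colnames(traits) <- c(sprintf("Tr%02d", seq_len(p)), "BFw", "BDw")
  out <- data.frame(
    grid[rep(seq_len(n_obs), times = ncol(traits)), ],
    trait = rep(colnames(traits), each = n_obs),
    value = as.vector(traits),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "planted_groups") <-
    if (is.null(panel$planted_groups)) NULL else
      stats::setNames(panel$planted_groups, genotype_labels(G))
  attr(out, "beta") <- stats::setNames(panel$beta, sprintf("Tr%02d", seq_len(p)))
  out
}

#' Read / write long-format trait tables
#'
#' CSV round-trip with the canonical header
#' `genotype,treatment,replicate,trait,value` (UTF-8, "." decimal; treatment
#' labels written verbatim, e.g. `N+W`).
#'
#' @param x A trait table (`data.frame`).
#' @param path File path.
#' @return `read_trait_table` returns the table; `write_trait_table` returns
#'   `path` invisibly.
#' @export
write_trait_table <- function(x, path) {
  stopifnot(all(c("genotype", "treatment", "replicate", "trait", "value")
                %in% names(x)))
  utils::write.csv(x[, c("genotype", "treatment", "replicate", "trait",
                         "value")],
                   path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

check_balanced <- function(data) {
  counts <- table(data$genotype, data$treatment, data$trait)
  length(unique(as.vector(counts))) == 1L && all(counts > 0)
}
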
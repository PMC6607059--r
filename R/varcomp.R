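#' Model specification for a variance-component fit
#'
#' The trait-wise mixed model is \eqn{y = X\beta + Zu + \epsilon} with fixed
#' replicate effects (plus intercept) in \eqn{X\beta} and random treatment,
#' genotype and genotype-by-treatment terms in \eqn{Zu}. The residual
#' variance is either a single pooled \eqn{\sigma^2_E} (`"homogeneous"`) or
#' one \eqn{\sigma^2_E(j)} per treatment (`"heterogeneous"`).
#'
#' @param trait_name Trait to fit (must appear in the data's `trait` column).
#' @param residual_model `"homogeneous"` or `"heterogeneous"`.
#' @param include_replicate_fixed Include fixed replicate effects (crossed
#'   with treatment).
#' @param max_iter Maximum optimizer iterations (>= 1).
#' @param tol Convergence tolerance on the restricted log-likelihood (> 0).
#' @return A `model_spec` list.
#' @export
model_spec <- function(trait_name,
                       residual_model = c("homogeneous", "heterogeneous"),
                       include_replicate_fixed = TRUE,
                       max_iter = 500L,
                       tol = 1e-8) {
  residual_model <- match.arg(residual_model)
  stopifnot(max_iter >= 1, tol > 0)
  structure(list(trait_name = trait_name, residual_model = residual_model,
                 include_replicate_fixed = isTRUE(include_replicate_fixed),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "model_spec")
}

subset_trait <- function(data, trait) {
  d <- data[data$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("trait '", trait, "' not found in data", call. = FALSE)
  if (any(!is.finite(d$value))) stop("non-finite trait values", call. = FALSE)
  d$genotype <- factor(d$genotype)
  d$treatment <- factor(d$treatment, levels = unique(data$treatment))
  d$replicate <- factor(d$replicate)
  d
}

#' Method-of-moments variance components for a balanced trial
#'
#' Expected-mean-squares estimator for the balanced two-way design with R
#' replicates per cell: \eqn{\hat\sigma^2_G = (MS_G - MS_{GT})/(RT)},
#' \eqn{\hat\sigma^2_{GT} = (MS_{GT} - MS_E)/R}, \eqn{\hat\sigma^2_E = MS_E},
#' and analogously \eqn{\hat\sigma^2_T = (MS_T - MS_{GT})/(RG)}. Negative
#' solutions are truncated at zero (recorded in `boundary`). Deterministic;
#' serves as the closed-form oracle for [fit_reml()] on balanced data.
#'
#' @param data A trait table (long format).
#' @param trait Trait name.
#' @return A `vc_fit` object (no likelihood: `logREML`/`AIC` are `NA`).
#' @export
fit_moments <- function(data, trait) {
  d <- subset_trait(data, trait)
  cell_n <- table(d$genotype, d$treatment)
  if (length(unique(as.vector(cell_n))) != 1L || any(cell_n < 2)) {
    stop("fit_moments requires a balanced complete table; use fit_reml",
         call. = FALSE)
  }
  G <- nlevels(d$genotype); Tn <- nlevels(d$treatment)
  R <- nrow(d) / (G * Tn)
  if (R != round(R)) stop("fit_moments requires a balanced complete table; use fit_reml",
                          call. = FALSE)
  gm <- mean(d$value)
  mg <- tapply(d$value, d$genotype, mean)
  mt <- tapply(d$value, d$treatment, mean)
  mgt <- tapply(d$value, list(d$genotype, d$treatment), mean)
  MS_G <- R * Tn * sum((mg - gm)^2) / (G - 1)
  MS_T <- R * G * sum((mt - gm)^2) / (Tn - 1)
  MS_GT <- R * sum((sweep(sweep(mgt, 1, mg), 2, mt) + gm)^2) /
    ((G - 1) * (Tn - 1))
  resid <- d$value - mgt[cbind(d$genotype, d$treatment)]
  MS_E <- sum(resid^2) / (G * Tn * (R - 1))
  # per-treatment within-cell variance (heterogeneous oracle)
  ss_j <- tapply(resid^2, d$treatment, sum)
  s2e_j <- ss_j / (G * (R - 1))
  raw <- c(G = (MS_G - MS_GT) / (R * Tn),
           T = (MS_T - MS_GT) / (R * G),
           GT = (MS_GT - MS_E) / R)
  est <- pmax(raw, 0)
  new_vc_fit(
    trait = trait,
    sigma2_G = est[["G"]], sigma2_T = est[["T"]], sigma2_GT = est[["GT"]],
    sigma2_E = MS_E, residual_model = "homogeneous",
    logREML = NA_real_, n_params = 4L, AIC = NA_real_,
    converged = TRUE, n_iter = 0L,
    extra = list(method = "moments", boundary = any(raw < 0),
                 mean_squares = c(MS_G = MS_G, MS_T = MS_T, MS_GT = MS_GT,
                                  MS_E = MS_E),
                 sigma2_E_by_treatment = s2e_j)
  )
}

new_vc_fit <- function(trait, sigma2_G, sigma2_T, sigma2_GT, sigma2_E,
                       residual_model, logREML, n_params, AIC, converged,
                       n_iter, extra = list()) {
  structure(c(list(
    trait = trait,
    sigma2_G = unname(sigma2_G), sigma2_T = unname(sigma2_T),
    sigma2_GT = unname(sigma2_GT), sigma2_E = sigma2_E,
    residual_model = residual_model,
    logREML = logREML, n_params = as.integer(n_params), AIC = AIC,
    converged = converged, n_iter = as.integer(n_iter)
  ), extra), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Variance component fit -- trait:", x$trait,
      "(", x$residual_model, "residuals )\n")
  cat(sprintf("  sigma2_G  = %.6g\n  sigma2_T  = %.6g\n  sigma2_GT = %.6g\n",
              x$sigma2_G, x$sigma2_T, x$sigma2_GT))
  cat("  sigma2_E  =", paste(signif(x$sigma2_E, 6), collapse = ", "), "\n")
  if (!is.na(x$logREML)) {
    cat(sprintf("  logREML = %.4f  AIC = %.4f  converged = %s (%d iter)\n",
                x$logREML, x$AIC, x$converged, x$n_iter))
  }
  invisible(x)
}

# Design matrices and per-treatment sufficient cross-products.
# Likelihood evaluations only touch (p+q)x(p+q) matrices:
#   -2 logREML = (n-p) log 2pi + log|R| + log|G| + log|C| + y'Py
# with C the mixed-model-equation coefficient matrix
#   C = W' R^-1 W + diag(0_p, G^-1),  W = [X Z]
# and y'Py = y'R^-1 y - theta_hat' W'R^-1 y.
build_design <- function(d, include_replicate_fixed = TRUE) {
  n <- nrow(d)
  X <- if (include_replicate_fixed && nlevels(d$replicate) > 1) {
    stats::model.matrix(~replicate, d)
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  Zt <- Matrix::sparse.model.matrix(~0 + treatment, d)
  Zg <- Matrix::sparse.model.matrix(~0 + genotype, d)
  Zgt <- Matrix::sparse.model.matrix(~0 + genotype:treatment, d)
  W <- cbind(Matrix::Matrix(X, sparse = TRUE), Zt, Zg, Zgt)
  p <- ncol(X)
  q <- c(Tn = ncol(Zt), G = ncol(Zg), GT = ncol(Zgt))
  groups <- split(seq_len(n), d$treatment)
  suff <- lapply(groups, function(idx) {
    Wj <- W[idx, , drop = FALSE]
    yj <- d$value[idx]
    list(C = as.matrix(Matrix::crossprod(Wj)),
         b = as.numeric(Matrix::crossprod(Wj, yj)),
         s = sum(yj^2), n = length(idx))
  })
  list(W = W, X = X, p = p, q = q, suff = suff, n = n,
       y = d$value, group = as.integer(d$treatment),
       treatments = levels(d$treatment),
       genotypes = levels(d$genotype))
}

# restricted log-likelihood at variance components v = list(T, G, GT, E[j])
reml_loglik <- function(des, v) {
  p <- des$p; q <- des$q
  k <- p + sum(q)
  A <- matrix(0, k, k); a <- numeric(k); s <- 0; logdetR <- 0
  for (j in seq_along(des$suff)) {
    w <- 1 / v$E[j]
    A <- A + w * des$suff[[j]]$C
    a <- a + w * des$suff[[j]]$b
    s <- s + w * des$suff[[j]]$s
    logdetR <- logdetR + des$suff[[j]]$n * log(v$E[j])
  }
  ginv <- c(rep(1 / v$T, q[1]), rep(1 / v$G, q[2]), rep(1 / v$GT, q[3]))
  ridx <- (p + 1):k
  diag(A)[ridx] <- diag(A)[ridx] + ginv
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf, theta = NULL))
  logdetC <- 2 * sum(log(diag(ch)))
  theta <- backsolve(ch, forwardsolve(t(ch), a))
  # stable residual form of y'Py (a sum of non-negative terms):
  # (y - W theta)' R^-1 (y - W theta) + u' G^-1 u
  e <- des$y - as.numeric(des$W %*% theta)
  yPy <- sum(e^2 / v$E[des$group]) + sum(theta[ridx]^2 * ginv)
  logdetG <- q[1] * log(v$T) + q[2] * log(v$G) + q[3] * log(v$GT)
  ll <- -0.5 * ((des$n - p) * log(2 * pi) + logdetR + logdetG + logdetC + yPy)
  list(ll = as.numeric(ll), theta = theta, chol = ch)
}

unpack_theta <- function(par, n_E) {
  v <- exp(par)
  list(T = v[1], G = v[2], GT = v[3], E = v[4:(3 + n_E)])
}

#' REML variance components by direct likelihood maximization
#'
#' Maximizes the restricted log-likelihood over log-variance parameters
#' (quasi-Newton with box constraints; variances bounded below at 1e-10).
#' Supports pooled or per-treatment residual variances. On balanced data
#' with interior solutions the estimates agree with [fit_moments()].
#'
#' @param data A trait table.
#' @param spec A [model_spec()].
#' @return A `vc_fit` with components, `logREML`, `AIC`
#'   (\eqn{-2 \log REML + 2 k}, k = number of variance parameters),
#'   convergence info, and the internal design (for BLUPs/residuals).
#' @export
fit_reml <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  d <- subset_trait(data, spec$trait_name)
  if (nlevels(d$genotype) < 2 || nlevels(d$treatment) < 2) {
    stop("need >= 2 genotypes and >= 2 treatments", call. = FALSE)
  }
  if (min(table(d$genotype, d$treatment)) < 1) {
    stop("empty genotype x treatment cells", call. = FALSE)
  }
  des <- build_design(d, spec$include_replicate_fixed)
  het <- spec$residual_model == "heterogeneous"
  n_E <- if (het) length(des$suff) else 1L

  # starting values: method-of-moments when balanced, else crude variance split
  vy <- stats::var(d$value)
  start <- tryCatch({
    m <- fit_moments(data, spec$trait_name)
    c(T = max(m$sigma2_T, 0.05 * vy), G = max(m$sigma2_G, 0.05 * vy),
      GT = max(m$sigma2_GT, 0.05 * vy), E = rep(max(m$sigma2_E, 0.05 * vy), n_E))
  }, error = function(e) c(T = vy / 4, G = vy / 4, GT = vy / 4,
                           E = rep(vy / 2, n_E)))
  par0 <- log(pmax(start, 1e-8))
  nll <- function(par) {
    v <- unpack_theta(par, n_E)
    if (!het) v$E <- rep(v$E, length(des$suff))
    val <- -reml_loglik(des, v)$ll
    if (!is.finite(val)) 1e10 else val
  }
  ctrl <- list(maxit = spec$max_iter,
               factr = max(spec$tol / .Machine$double.eps, 10))
  opt <- stats::optim(par0, nll, method = "L-BFGS-B",
                      lower = log(1e-10), upper = log(1e12), control = ctrl)
  if (opt$convergence != 0) {
    # line searches can terminate abnormally at tight tolerances; restart
    # once and accept if the restricted likelihood is stationary
    opt2 <- stats::optim(opt$par, nll, method = "L-BFGS-B",
                         lower = log(1e-10), upper = log(1e12),
                         control = ctrl)
    if (opt2$value <= opt$value) {
      improved <- opt$value - opt2$value
      opt2$convergence <- if (opt2$convergence == 0 || improved < spec$tol)
        0L else opt2$convergence
      opt2$counts <- opt$counts + opt2$counts
      opt <- opt2
    }
  }
  # coordinate-wise polish: the surface is stiff when components sit at the
  # 1e-10 bound (quasi-Newton line searches stall there); cycle exact 1-D
  # maximizations until the restricted likelihood is stationary
  at_bound <- any(abs(opt$par - log(1e-10)) < 1e-6)
  if (at_bound || opt$convergence != 0 || spec$tol < 1e-9) {
    par <- opt$par
    val <- opt$value
    for (sweep in seq_len(20L)) {
      for (i in seq_along(par)) {
        o1 <- stats::optimize(function(x) {
          pp <- par; pp[i] <- x; nll(pp)
        }, interval = c(log(1e-10), log(1e12)), tol = 1e-10)
        if (o1$objective < val) {
          par[i] <- o1$minimum
          val <- o1$objective
        }
      }
      if (sweep > 1 && prev_val - val < spec$tol) break
      prev_val <- val
    }
    if (val <= opt$value) {
      opt$par <- par
      opt$value <- val
      opt$convergence <- 0L
    }
    # damped Newton refinement (numeric derivatives) for high-precision
    # interior solutions; skipped at the variance bound, where cancellation
    # noise in the likelihood defeats finite differences
    if (spec$tol < 1e-9 && !any(abs(opt$par - log(1e-10)) < 1e-6)) {
      par <- opt$par
      val <- opt$value
      h <- 1e-4
      k <- length(par)
      for (step in seq_len(5L)) {
        fp <- vapply(seq_len(k), function(i) {
          e <- numeric(k); e[i] <- h; nll(par + e)
        }, numeric(1))
        fm <- vapply(seq_len(k), function(i) {
          e <- numeric(k); e[i] <- h; nll(par - e)
        }, numeric(1))
        g <- (fp - fm) / (2 * h)
        H <- diag((fp - 2 * val + fm) / h^2, k)
        for (i in seq_len(k - 1)) for (j in (i + 1):k) {
          ei <- numeric(k); ei[i] <- h
          ej <- numeric(k); ej[j] <- h
          H[i, j] <- H[j, i] <-
            (nll(par + ei + ej) - nll(par + ei - ej) -
               nll(par - ei + ej) + nll(par - ei - ej)) / (4 * h^2)
        }
        delta <- tryCatch(solve(H, g), error = function(e) NULL)
        if (is.null(delta) || !all(is.finite(delta))) break
        moved <- FALSE
        for (damp in c(1, 0.5, 0.25)) {
          cand <- pmin(pmax(par - damp * delta, log(1e-10)), log(1e12))
          cval <- nll(cand)
          if (cval < val) {
            par <- cand; val <- cval; moved <- TRUE
            break
          }
        }
        if (!moved || max(abs(delta)) < 1e-9) break
      }
      if (val <= opt$value) {
        opt$par <- par
        opt$value <- val
        opt$convergence <- 0L
      }
    }
  }
  v <- unpack_theta(opt$par, n_E)
  sigma2_E <- if (het) stats::setNames(v$E, des$treatments) else unname(v$E)
  v_full <- v; if (!het) v_full$E <- rep(v$E, length(des$suff))
  ll <- reml_loglik(des, v_full)
  n_params <- 3L + n_E
  fit <- new_vc_fit(
    trait = spec$trait_name,
    sigma2_G = v$G, sigma2_T = v$T, sigma2_GT = v$GT,
    sigma2_E = sigma2_E,
    residual_model = spec$residual_model,
    logREML = ll$ll, n_params = n_params,
    AIC = -2 * ll$ll + 2 * n_params,
    converged = opt$convergence == 0,
    n_iter = opt$counts[["function"]],
    extra = list(method = "reml", spec = spec, design = des, theta = ll$theta)
  )
  if (!fit$converged) {
    warning("REML did not converge within max_iter for trait ",
            spec$trait_name, call. = FALSE)
  }
  fit
}

#' Select the residual-variance model by AIC
#'
#' Returns whichever fit has the lower AIC; ties go to the homogeneous
#' (fewer-parameter) model.
#'
#' @param fit_hom,fit_het `vc_fit` objects for the same trait.
#' @return The selected `vc_fit`.
#' @export
select_residual_model <- function(fit_hom, fit_het) {
  stopifnot(inherits(fit_hom, "vc_fit"), inherits(fit_het, "vc_fit"))
  if (!identical(fit_hom$trait, fit_het$trait)) {
    stop("fits are for different traits", call. = FALSE)
  }
  if (is.na(fit_hom$AIC) || is.na(fit_het$AIC)) {
    stop("both fits need an AIC (REML fits)", call. = FALSE)
  }
  if (fit_het$AIC < fit_hom$AIC) fit_het else fit_hom
}

#' Likelihood-ratio test of a random term
#'
#' \eqn{LR = 2(\log REML_{full} - \log REML_{reduced})}, clipped at zero.
#' Because the null puts the variance on the boundary of its parameter
#' space, the reference distribution is the mixture
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1}.
#'
#' @param fit_full,fit_reduced Nested `vc_fit` objects (same trait, same
#'   fixed effects; the reduced model drops one variance parameter).
#' @return List with `LR` and `p_value`.
#' @export
lr_test_random <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "vc_fit"), inherits(fit_reduced, "vc_fit"))
  if (!identical(fit_full$trait, fit_reduced$trait)) {
    stop("fits are for different traits (non-nested)", call. = FALSE)
  }
  if (fit_full$n_params <= fit_reduced$n_params) {
    stop("fit_full must have more parameters than fit_reduced (non-nested)",
         call. = FALSE)
  }
  LR <- max(0, 2 * (fit_full$logREML - fit_reduced$logREML))
  p <- if (LR <= 0) 1 else 0.5 * stats::pchisq(LR, df = 1, lower.tail = FALSE)
  list(LR = LR, p_value = p)
}

#' Heritability and variance contributions
#'
#' Sample-basis broad-sense heritability
#' \eqn{h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GT} + \sigma^2_E)}.
#' The treatment variance is reported in the contribution shares (treatment,
#' genotype, genotype-by-treatment, error — summing to 1) but excluded from
#' the heritability denominator. Under heterogeneous residuals the error
#' component entering both is, by default, the unweighted mean of the
#' per-treatment residual variances.
#'
#' @param fit A `vc_fit`.
#' @param resid_summary How to pool heterogeneous residuals: `"mean"`
#'   (default, unweighted) — the only option currently implemented beyond
#'   supplying a single value via a homogeneous fit.
#' @return List with `h2` and named `contributions`.
#' @export
heritability_and_contributions <- function(fit, resid_summary = "mean") {
  stopifnot(inherits(fit, "vc_fit"))
  s2e <- mean(fit$sigma2_E)
  tot_h <- fit$sigma2_G + fit$sigma2_GT + s2e
  if (tot_h <= 0 && fit$sigma2_T <= 0) {
    stop("all variance components are zero; heritability undefined",
         call. = FALSE)
  }
  if (tot_h <= 0) stop("zero phenotypic variance; heritability undefined",
                       call. = FALSE)
  h2 <- fit$sigma2_G / tot_h
  comp <- c(treatment = fit$sigma2_T, genotype = fit$sigma2_G,
            gxt = fit$sigma2_GT, error = s2e)
  list(h2 = h2, contributions = comp / sum(comp))
}

# Solve the mixed-model equations at the fitted variances; returns the full
# coefficient vector and the (dense) inverse coefficient matrix.
solve_mme <- function(fit) {
  des <- fit$design
  het <- fit$residual_model == "heterogeneous"
  vE <- if (het) as.numeric(fit$sigma2_E) else rep(fit$sigma2_E,
                                                   length(des$suff))
  v <- list(T = max(fit$sigma2_T, 1e-10), G = max(fit$sigma2_G, 1e-10),
            GT = max(fit$sigma2_GT, 1e-10), E = pmax(vE, 1e-10))
  ll <- reml_loglik(des, v)
  Cinv <- chol2inv(ll$chol)
  list(theta = ll$theta, Cinv = Cinv, v = v)
}

#' Genotype-by-treatment BLUPs
#'
#' Solves the mixed-model equations at the fitted variance components and
#' returns predicted cell values \eqn{\hat\mu + \hat t_j + \hat g_i +
#' \widehat{gt}_{ij}} (fixed part evaluated at the average replicate).
#' Predictions shrink toward the treatment mean as the genetic variances
#' shrink, and converge to observed cell means as the residual variance
#' vanishes.
#'
#' @param fit A converged REML `vc_fit` (from [fit_reml()]).
#' @param data Ignored (the design is carried by the fit); kept for call
#'   symmetry with the rest of the pipeline.
#' @return A `data.frame`: `genotype`, `treatment`, `trait`, `value`.
#' @export
genotype_blups <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "vc_fit"))
  if (is.null(fit$design)) {
    stop("fit carries no design; use a fit from fit_reml()", call. = FALSE)
  }
  des <- fit$design
  sol <- solve_mme(fit)
  p <- des$p; q <- des$q
  beta <- sol$theta[seq_len(p)]
  # average fixed part across replicate levels (treatment-contrast dummies)
  mu_fix <- beta[1] + if (p > 1) mean(c(0, beta[-1])) else 0
  t_hat <- sol$theta[p + seq_len(q[1])]
  g_hat <- sol$theta[p + q[1] + seq_len(q[2])]
  gt_hat <- matrix(sol$theta[p + q[1] + q[2] + seq_len(q[3])],
                   nrow = q[2], ncol = q[1])  # genotype-major (model.matrix order)
  grid <- expand.grid(genotype = des$genotypes, treatment = des$treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(grid$genotype, des$genotypes)
  tj <- match(grid$treatment, des$treatments)
  grid$trait <- fit$trait
  grid$value <- mu_fix + t_hat[tj] + g_hat[gi] + gt_hat[cbind(gi, tj)]
  grid
}

#' Flag anomalous observations by studentized conditional residuals
#'
#' Conditional residuals \eqn{\hat e = y - X\hat\beta - Z\hat u} are
#' studentized by their model-based standard errors
#' \eqn{\sqrt{\mathrm{diag}(R - W C^{-1} W')}}; observations exceeding the
#' threshold in absolute value are flagged (never removed).
#'
#' @param data Trait table the fit was computed from.
#' @param fit A REML `vc_fit`.
#' @param threshold Absolute studentized-residual cutoff (default 3).
#' @return `data.frame` of flagged rows with `residual` and `studentized`
#'   columns (zero rows if none).
#' @export
flag_outliers <- function(data, fit, threshold = 3) {
  stopifnot(inherits(fit, "vc_fit"))
  des <- fit$design
  d <- subset_trait(data, fit$trait)
  sol <- solve_mme(fit)
  W <- as.matrix(des$W)
  e <- d$value - drop(W %*% sol$theta)
  r_ii <- sol$v$E[as.integer(d$treatment)]
  h <- rowSums((W %*% sol$Cinv) * W)
  se <- sqrt(pmax(r_ii - h, 1e-12))
  stud <- e / se
  keep <- is.finite(stud) & abs(stud) > threshold
  out <- d[keep, c("genotype", "treatment", "replicate", "trait", "value")]
  out$residual <- e[keep]
  out$studentized <- stud[keep]
  rownames(out) <- NULL
  out
}

#' Fixed-effect z-test for the replicate term
#'
#' Simple Wald-type z-test of each replicate contrast against zero, using
#' the MME-based covariance of the fixed effects. A lightweight diagnostic,
#' not a small-sample (Kenward-Roger) treatment.
#'
#' @param fit A REML `vc_fit` with replicate fixed effects.
#' @return `data.frame` with `term`, `estimate`, `se`, `z`, `p_value`.
#' @export
wald_test_replicate <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  des <- fit$design
  if (des$p < 2) stop("fit has no replicate fixed effects", call. = FALSE)
  sol <- solve_mme(fit)
  idx <- 2:des$p
  est <- sol$theta[idx]
  se <- sqrt(diag(sol$Cinv)[idx])
  z <- est / se
  data.frame(term = colnames(des$X)[idx], estimate = est, se = se, z = z,
             p_value = 2 * stats::pnorm(-abs(z)), row.names = NULL)
}
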
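#' Standardize a predictor matrix and center the response
#'
#' Columns are centered and scaled to unit sample standard deviation
#' (denominator n-1); the response is centered. The scaling record allows
#' back-transformation of coefficients to the original trait scale.
#' Standardization makes the common penalty comparable across traits.
#'
#' @param X Numeric predictor matrix (traits in columns).
#' @param y Numeric response vector.
#' @return `std_design` list: `Xs`, `yc`, `center`, `scale`, `y_center`.
#' @export
standardize <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance predictor(s): ",
         paste(colnames(X)[scl == 0], collapse = ", "), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  structure(list(Xs = Xs, yc = y - mean(y), center = ctr, scale = scl,
                 y_center = mean(y)), class = "std_design")
}

as_std <- function(std, y = NULL) {
  if (inherits(std, "std_design")) return(std)
  # raw matrix + response: assume already standardized/centered
  structure(list(Xs = as.matrix(std), yc = y,
                 center = rep(0, ncol(std)), scale = rep(1, ncol(std)),
                 y_center = 0), class = "std_design")
}

new_penalized_model <- function(method, lambda, beta, std, cv_curve = NULL,
                                lambda_opt = NA_real_, extra = list()) {
  beta <- stats::setNames(as.numeric(beta),
                          colnames(std$Xs) %||% paste0("x", seq_along(beta)))
  structure(c(list(
    method = method, lambda = lambda, coefficients = beta,
    intercept = std$y_center,
    coefficients_original = beta / std$scale,
    nonzero_count = sum(beta != 0),
    cv_curve = cv_curve, lambda_opt = lambda_opt
  ), extra), class = "penalized_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.penalized_model <- function(x, ...) {
  cat(sprintf("%s model: lambda = %.6g, nonzero = %d of %d\n",
              x$method, x$lambda, x$nonzero_count, length(x$coefficients)))
  invisible(x)
}

#' Ridge regression (penalty on the residual-sum-of-squares scale)
#'
#' Minimizes \eqn{RSS(\beta) + \lambda \sum_j \beta_j^2} on standardized
#' predictors; closed form \eqn{\hat\beta = (X'X + \lambda I)^{-1} X'y}.
#' No 1/n rescaling of either term. The intercept is the response mean,
#' restored on output. A plain gradient-descent solver is available as an
#' independent numerical route.
#'
#' @param std A [standardize()] result (or a pre-standardized matrix, with
#'   `y` supplied).
#' @param lambda Penalty (>= 0).
#' @param y Centered response when `std` is a bare matrix.
#' @param solver `"closed_form"` (default) or `"gradient"`.
#' @return A `penalized_model`.
#' @export
fit_ridge <- function(std, lambda, y = NULL,
                      solver = c("closed_form", "gradient")) {
  solver <- match.arg(solver)
  std <- as_std(std, y)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  X <- std$Xs; yc <- std$yc
  XtX <- crossprod(X)
  beta <- if (solver == "closed_form") {
    solve(XtX + diag(lambda, ncol(X)), crossprod(X, yc))
  } else {
    # gradient descent on the strongly convex objective; step 1/L with
    # L = 2(max eigenvalue of X'X + lambda)
    L <- 2 * (max(eigen(XtX, symmetric = TRUE, only.values = TRUE)$values) +
                lambda)
    b <- rep(0, ncol(X))
    Xty <- drop(crossprod(X, yc))
    for (i in seq_len(100000L)) {
      grad <- 2 * (drop(XtX %*% b) - Xty) + 2 * lambda * b
      b_new <- b - grad / L
      if (max(abs(b_new - b)) < 1e-13) { b <- b_new; break }
      b <- b_new
    }
    b
  }
  new_penalized_model("ridge", lambda, beta, std,
                      extra = list(solver = solver))
}

#' Lasso by coordinate descent with soft-thresholding
#'
#' Minimizes \eqn{RSS(\beta) + \lambda \sum_j |\beta_j|} on standardized
#' predictors (no 1/n rescaling): cyclic coordinate descent with the
#' soft-threshold update \eqn{\beta_j \leftarrow S(x_j'r_{(j)},
#' \lambda/2)/(x_j'x_j)}, which produces exact zeros. All coefficients are
#' exactly zero once \eqn{\lambda \ge 2\max_j |x_j'y|}.
#'
#' @inheritParams fit_ridge
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum full sweeps.
#' @return A `penalized_model`.
#' @export
fit_lasso <- function(std, lambda, y = NULL, tol = 1e-8, max_iter = 100000L) {
  std <- as_std(std, y)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  res <- .lasso_cd_path(std$Xs, std$yc, lambda, tol, as.integer(max_iter),
                        rep(0, ncol(std$Xs)))
  if (!res$converged[1]) {
    warning("lasso coordinate descent did not converge; returning best iterate",
            call. = FALSE)
  }
  new_penalized_model("lasso", lambda, res$beta[, 1], std,
                      extra = list(n_iter = res$iter[1],
                                   converged = res$converged[1]))
}

#' Default lambda grid
#'
#' 100 log-spaced values from \eqn{\lambda_{max} = 2\max_j |x_j'y|} (the
#' smallest penalty with an all-zero lasso solution) down to
#' \eqn{10^{-4}\lambda_{max}}, strictly decreasing.
#'
#' @param std A `std_design`.
#' @param n_lambda Grid size.
#' @param min_ratio Smallest lambda as a fraction of `lambda_max`.
#' @return Numeric vector, decreasing.
#' @export
lambda_grid <- function(std, n_lambda = 100L, min_ratio = 1e-4) {
  lmax <- 2 * max(abs(crossprod(std$Xs, std$yc)))
  if (lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(min_ratio * lmax), length.out = n_lambda))
}

#' Fivefold cross-validation of the penalty
#'
#' Folds are formed by a seeded shuffle; for each lambda on the grid the
#' model is fit on the training folds (lasso: warm-started down the path)
#' and scored by held-out mean squared error. `lambda_opt` minimizes the
#' mean CV error (ties broken toward the larger penalty); an optional
#' one-standard-error rule picks the largest lambda within one SE of the
#' minimum. The returned model is refit on the full data at `lambda_opt`.
#'
#' @param std A [standardize()] result.
#' @param method `"lasso"` or `"ridge"`.
#' @param n_folds Number of folds (default 5).
#' @param grid Lambda grid (default [lambda_grid()]).
#' @param seed Integer seed for the fold shuffle.
#' @param one_se Use the one-standard-error rule (default `FALSE`).
#' @return A `penalized_model` with `cv_curve` (`lambda`, `mse`, `se`),
#'   `lambda_opt` and `folds`.
#' @export
cross_validate_lambda <- function(std, method = c("lasso", "ridge"),
                                  n_folds = 5L, grid = NULL, seed = NULL,
                                  one_se = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(std, "std_design"))
  n <- nrow(std$Xs)
  if (n < n_folds) stop("need n >= n_folds", call. = FALSE)
  if (is.null(grid)) grid <- lambda_grid(std)
  if (is.unsorted(rev(grid), strictly = TRUE)) {
    stop("lambda grid must be strictly decreasing", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  errs <- matrix(NA_real_, length(grid), n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    Xtr <- std$Xs[tr, , drop = FALSE]; ytr <- std$yc[tr]
    Xte <- std$Xs[!tr, , drop = FALSE]; yte <- std$yc[!tr]
    if (method == "lasso") {
      path <- .lasso_cd_path(Xtr, ytr, grid, 1e-8, 100000L,
                             rep(0, ncol(Xtr)))
      pred <- Xte %*% path$beta
      errs[, f] <- colMeans((yte - pred)^2)
    } else {
      XtX <- crossprod(Xtr); Xty <- crossprod(Xtr, ytr)
      for (l in seq_along(grid)) {
        b <- solve(XtX + diag(grid[l], ncol(Xtr)), Xty)
        errs[l, f] <- mean((yte - Xte %*% b)^2)
      }
    }
  }
  mse <- rowMeans(errs)
  se <- apply(errs, 1, stats::sd) / sqrt(n_folds)
  i_min <- which.min(mse)  # first = largest lambda among exact ties
  i_opt <- if (one_se) {
    which(mse <= mse[i_min] + se[i_min])[1]
  } else {
    i_min
  }
  lambda_opt <- grid[i_opt]
  fit <- if (method == "lasso") fit_lasso(std, lambda_opt)
         else fit_ridge(std, lambda_opt)
  fit$cv_curve <- data.frame(lambda = grid, mse = mse, se = se)
  fit$lambda_opt <- lambda_opt
  fit$folds <- folds
  fit$seed <- seed
  fit
}

#' Penalized objective value
#'
#' \eqn{RSS + \lambda \|\beta\|_1} (lasso) or \eqn{RSS + \lambda
#' \|\beta\|_2^2} (ridge) at a given coefficient vector — the quantity the
#' fitters minimize; useful for optimality checks.
#'
#' @param std A `std_design`.
#' @param beta Coefficient vector.
#' @param lambda Penalty.
#' @param method `"lasso"` or `"ridge"`.
#' @return Scalar objective value.
#' @export
penalized_objective <- function(std, beta, lambda,
                                method = c("lasso", "ridge")) {
  method <- match.arg(method)
  rss <- sum((std$yc - std$Xs %*% beta)^2)
  pen <- if (method == "lasso") sum(abs(beta)) else sum(beta^2)
  rss + lambda * pen
}

#' Coefficient table across treatments and responses
#'
#' Assembles per-(treatment x response) penalized fits into a wide table:
#' rows are predictor traits, columns `response.treatment`, with empty
#' strings for exact zeros (the presentation format of variable-selection
#' tables).
#'
#' @param fits Named list of `penalized_model`s; names like `"BDw.C"`.
#' @param digits Rounding for display (default 3).
#' @return `data.frame` of character columns (blank = exact zero).
#' @export
coefficient_table <- function(fits, digits = 3) {
  traits <- names(fits[[1]]$coefficients)
  out <- data.frame(predictor = traits, stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    b <- fits[[nm]]$coefficients[traits]
    out[[nm]] <- ifelse(b == 0, "", formatC(round(b, digits),
                                            format = "fg", flag = "#"))
  }
  out
}
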
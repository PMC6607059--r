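#' Genotype x treatment two-way table
#'
#' Pivots a BLUP (or cell-mean) table for one trait into a complete
#' genotypes x treatments matrix; errors on missing cells.
#'
#' @param blups Long table (`genotype`, `treatment`, `trait`, `value`).
#' @param trait Trait to extract.
#' @return Numeric matrix, rownames = genotypes, colnames = treatments
#'   (column order follows first appearance).
#' @export
two_way_table <- function(blups, trait) {
  d <- blups[blups$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("trait '", trait, "' not found", call. = FALSE)
  gl <- unique(d$genotype); tl <- unique(d$treatment)
  m <- matrix(NA_real_, length(gl), length(tl),
              dimnames = list(gl, tl))
  m[cbind(match(d$genotype, gl), match(d$treatment, tl))] <- d$value
  if (anyNA(m)) stop("incomplete genotype x treatment table", call. = FALSE)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 rows and columns",
                                       call. = FALSE)
  m
}

#' Double-center a two-way table
#'
#' Removes additive main effects, leaving the interaction
#' \eqn{tg_{ij} = y_{ij} - \bar y_{i.} - \bar y_{.j} + \bar y_{..}}.
#' Every row and column of the result sums to zero; the operation is
#' idempotent and invariant to adding constants to any row or column.
#'
#' @param y Complete numeric matrix (genotypes x treatments).
#' @return Matrix of interaction values, same dimnames.
#' @export
double_center <- function(y) {
  y <- as.matrix(y)
  if (anyNA(y)) stop("missing cells; complete the table first", call. = FALSE)
  sweep(sweep(y, 1, rowMeans(y)), 2, colMeans(y)) + mean(y)
}

#' AMMI decomposition of the interaction matrix
#'
#' Singular value decomposition of the double-centered genotype x treatment
#' table. Interaction principal component (IPC) scores use symmetric
#' scaling: genotype scores \eqn{u_k\sqrt{\lambda_k}}, treatment scores
#' \eqn{v_k\sqrt{\lambda_k}}, so the score inner products reconstruct the
#' interaction. Per-component variance explained is
#' \eqn{100\,\lambda_k^2/\sum\lambda^2}. The SVD sign ambiguity is resolved
#' by making the largest-magnitude genotype loading positive on each
#' component.
#'
#' @param interaction Double-centered matrix (from [double_center()]; a
#'   non-centered matrix is centered automatically with a message).
#' @param n_components Number of IPCs to report (default 2).
#' @return An `ammi_result`: `interaction`, `d` (singular values),
#'   `genotype_scores`, `treatment_scores` (n_components columns),
#'   `variance_explained` (%), `rank`, plus full `u`, `v` for
#'   reconstruction.
#' @export
ammi_decompose <- function(interaction, n_components = 2) {
  m <- as.matrix(interaction)
  if (max(abs(rowSums(m))) > 1e-8 * max(1, max(abs(m))) ||
      max(abs(colSums(m))) > 1e-8 * max(1, max(abs(m)))) {
    message("input not double-centered; centering now")
    m <- double_center(m)
  }
  k_max <- min(nrow(m) - 1, ncol(m) - 1)
  n_components <- min(n_components, min(dim(m)))
  sv <- svd(m)
  tot <- sum(sv$d^2)
  if (tot <= .Machine$double.eps * max(1, max(abs(m)))^2) {
    warning("all-zero interaction; variance explained undefined (0)",
            call. = FALSE)
    ve <- rep(0, length(sv$d))
  } else {
    ve <- 100 * sv$d^2 / tot
  }
  # deterministic sign: largest |genotype loading| positive per component
  for (k in seq_along(sv$d)) {
    i <- which.max(abs(sv$u[, k]))
    if (sv$u[i, k] < 0) {
      sv$u[, k] <- -sv$u[, k]
      sv$v[, k] <- -sv$v[, k]
    }
  }
  kc <- seq_len(n_components)
  gs <- sv$u[, kc, drop = FALSE] %*% diag(sqrt(sv$d[kc]), n_components)
  ts <- sv$v[, kc, drop = FALSE] %*% diag(sqrt(sv$d[kc]), n_components)
  dimnames(gs) <- list(rownames(m), paste0("IPC", kc))
  dimnames(ts) <- list(colnames(m), paste0("IPC", kc))
  structure(list(
    interaction = m, d = sv$d, u = sv$u, v = sv$v,
    genotype_scores = gs, treatment_scores = ts,
    variance_explained = ve, rank = k_max,
    n_components = n_components
  ), class = "ammi_result")
}

#' @export
print.ammi_result <- function(x, ...) {
  cat("AMMI decomposition:", nrow(x$interaction), "genotypes x",
      ncol(x$interaction), "treatments\n")
  cat("  variance explained (%):",
      paste(signif(x$variance_explained[seq_len(min(4, length(x$d)))], 4),
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-genotype stability summary from an AMMI fit
#'
#' Distance of each genotype from the biplot origin over the first two IPCs
#' (smaller = more stable: the genotype's interaction pattern is weak), and
#' the cosine of the angle between each genotype's score vector and each
#' treatment's score vector (positive cosine = interaction favoring that
#' treatment; acute angle in the biplot).
#'
#' @param result An `ammi_result` with >= 2 components.
#' @return `data.frame` with `genotype`, `IPC1`, `IPC2`, `distance`, and one
#'   `cos_<treatment>` column per treatment.
#' @export
stability_summary <- function(result) {
  stopifnot(inherits(result, "ammi_result"))
  if (result$n_components < 2) stop("decompose with >= 2 components",
                                    call. = FALSE)
  gs <- result$genotype_scores[, 1:2, drop = FALSE]
  ts <- result$treatment_scores[, 1:2, drop = FALSE]
  dist <- sqrt(rowSums(gs^2))
  out <- data.frame(genotype = rownames(gs), IPC1 = gs[, 1], IPC2 = gs[, 2],
                    distance = dist, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (j in seq_len(nrow(ts))) {
    denom <- dist * sqrt(sum(ts[j, ]^2))
    cosj <- ifelse(denom > 0, drop(gs %*% ts[j, ]) / denom, 0)
    out[[paste0("cos_", rownames(ts)[j])]] <- cosj
  }
  out
}
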
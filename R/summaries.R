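#' Descriptive trait summaries per treatment
#'
#' Mean, sample standard deviation, coefficient of variation
#' (\eqn{CV = 100\, sd/mean}) and percent reduction relative to the control
#' treatment (\eqn{100 (mean_C - mean_s)/mean_C}), per trait x treatment.
#' Works on replicate-level tables or BLUP tables (any long table with
#' `trait`, `treatment`, `value`).
#'
#' @param data Long table with `trait`, `treatment`, `value`.
#' @param control Control treatment label (default `"C"`).
#' @return `data.frame`: `trait`, `treatment`, `n`, `mean`, `sd`, `cv`,
#'   `percent_reduction` (`NA` for the control row or when the control mean
#'   is zero — flagged in `reduction_defined`).
#' @export
summarize_traits <- function(data, control = "C") {
  stopifnot(all(c("trait", "treatment", "value") %in% names(data)))
  if (!control %in% data$treatment) {
    stop("control treatment '", control, "' not present", call. = FALSE)
  }
  agg <- stats::aggregate(value ~ trait + treatment, data,
                          function(v) c(n = length(v), mean = mean(v),
                                        sd = stats::sd(v)))
  out <- data.frame(trait = agg$trait, treatment = agg$treatment,
                    n = agg$value[, "n"], mean = agg$value[, "mean"],
                    sd = agg$value[, "sd"], stringsAsFactors = FALSE)
  if (any(out$n < 2)) stop("need >= 2 values per trait x treatment",
                           call. = FALSE)
  out$cv <- ifelse(out$mean == 0, NA_real_, 100 * out$sd / abs(out$mean))
  ctrl <- out[out$treatment == control, c("trait", "mean")]
  names(ctrl)[2] <- "mean_C"
  out <- merge(out, ctrl, by = "trait", sort = FALSE)
  out$reduction_defined <- out$mean_C != 0 & out$treatment != control
  out$percent_reduction <- ifelse(out$reduction_defined,
                                  100 * (out$mean_C - out$mean) / out$mean_C,
                                  NA_real_)
  out$mean_C <- NULL
  out[order(out$trait, match(out$treatment, unique(data$treatment))), ,
      drop = FALSE]
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations among traits across genotypes (intended for
#' genotype BLUPs within one treatment), with two-sided p-values from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} df. Zero-variance traits
#' yield `NA` correlations and are reported in `degenerate`.
#'
#' @param blups Long table (`genotype`, `trait`, `value`) for a single
#'   treatment, or a genotypes x traits numeric matrix.
#' @return List with matrices `r`, `p`, the common sample size `n`, and
#'   `degenerate` (names of zero-variance traits).
#' @export
correlation_matrix <- function(blups) {
  if (is.data.frame(blups)) {
    if (length(unique(blups$treatment)) > 1) {
      stop("correlation_matrix expects a single treatment; split first",
           call. = FALSE)
    }
    m <- stats::reshape(
      blups[, c("genotype", "trait", "value")],
      idvar = "genotype", timevar = "trait", direction = "wide"
    )
    rownames(m) <- m$genotype
    m <- as.matrix(m[, -1, drop = FALSE])
    colnames(m) <- sub("^value\\.", "", colnames(m))
  } else {
    m <- as.matrix(blups)
  }
  n <- nrow(m)
  if (n < 3) stop("need >= 3 genotypes for correlations", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  degenerate <- colnames(m)[sds == 0]
  r <- suppressWarnings(stats::cor(m))
  r[, degenerate] <- NA; r[degenerate, ] <- NA
  diag(r) <- ifelse(colnames(m) %in% degenerate, NA, 1)
  rc <- pmin(pmax(r, -1), 1)
  tstat <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[rc == 1 | rc == -1] <- 0
  diag(p) <- 0
  p[is.na(r)] <- NA
  list(r = r, p = p, n = n, degenerate = degenerate)
}

#' Build a signed correlation network
#'
#' Edges connect trait pairs whose correlation is significant at `alpha`
#' (two-sided, unadjusted by default; optional Holm adjustment). Edge width
#' is |r| (strictly increasing in correlation strength); sign records the
#' correlation direction. Degenerate (zero-variance) traits are excluded
#' from the edge set. Node order follows the correlation matrix columns.
#'
#' @param cm Result of [correlation_matrix()] (or a list with `r`, `p`).
#' @param alpha Significance level for inclusion (default 0.05).
#' @param categories Optional named character vector mapping trait ->
#'   category (e.g. architectural / physiological / biomass-related /
#'   manual).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return List with `nodes` and `edges` data frames.
#' @export
build_network <- function(cm, alpha = 0.05, categories = NULL,
                          adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  r <- cm$r; p <- cm$p
  traits <- colnames(r)
  nodes <- data.frame(
    trait = traits,
    category = if (is.null(categories)) NA_character_ else
      unname(categories[traits]),
    stringsAsFactors = FALSE
  )
  ut <- upper.tri(r)
  idx <- which(ut, arr.ind = TRUE)
  pv <- p[ut]
  if (adjust == "holm") pv <- stats::p.adjust(pv, method = "holm")
  keep <- !is.na(pv) & pv < alpha & !is.na(r[ut])
  edges <- data.frame(
    trait_i = traits[idx[keep, 1]],
    trait_j = traits[idx[keep, 2]],
    r = r[ut][keep],
    p = pv[keep],
    sign = ifelse(r[ut][keep] >= 0, "positive", "negative"),
    width = abs(r[ut][keep]),
    stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges, alpha = alpha, adjust = adjust)
}
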
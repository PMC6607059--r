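#' Stress tolerance indices from paired stress / non-stress yields
#'
#' Standard yield-based index family, computed per genotype from the
#' non-stress performance Yp and stress performance Ys (here: dry biomass):
#' \itemize{
#'   \item stress intensity \eqn{SI = 1 - \bar Y_s/\bar Y_p} (population level)
#'   \item stress susceptibility index \eqn{SSI = (1 - Y_s/Y_p)/SI}
#'   \item tolerance \eqn{TOL = Y_p - Y_s}
#'   \item mean productivity \eqn{MP = (Y_p + Y_s)/2}
#'   \item geometric mean productivity \eqn{GMP = \sqrt{Y_p Y_s}}
#'   \item stress tolerance index \eqn{STI = Y_p Y_s / \bar Y_p^2}
#' }
#'
#' @param Yp,Ys Equal-length positive vectors of non-stress / stress yields
#'   (named by genotype, or `genotypes` supplied).
#' @param genotypes Optional genotype labels.
#' @return `data.frame` with columns `genotype`, `Yp`, `Ys`, `SSI`, `TOL`,
#'   `MP`, `GMP`, `STI`; attributes `SI`, `Yp_bar`, `Ys_bar`.
#' @export
compute_stress_indices <- function(Yp, Ys, genotypes = NULL) {
  if (length(Yp) != length(Ys)) stop("Yp and Ys lengths differ", call. = FALSE)
  if (any(Yp <= 0) || any(Ys <= 0)) {
    stop("yields must be positive", call. = FALSE)
  }
  if (is.null(genotypes)) {
    genotypes <- names(Yp) %||% paste0("G", seq_along(Yp))
  }
  Yp_bar <- mean(Yp); Ys_bar <- mean(Ys)
  SI <- 1 - Ys_bar / Yp_bar
  if (SI <= 0) {
    stop("no population-level stress detected (mean Ys >= mean Yp)",
         call. = FALSE)
  }
  out <- data.frame(
    genotype = genotypes,
    Yp = unname(Yp), Ys = unname(Ys),
    SSI = unname((1 - Ys / Yp) / SI),
    TOL = unname(Yp - Ys),
    MP = unname((Yp + Ys) / 2),
    GMP = unname(sqrt(Yp * Ys)),
    STI = unname(Yp * Ys / Yp_bar^2),
    stringsAsFactors = FALSE
  )
  attr(out, "SI") <- SI
  attr(out, "Yp_bar") <- Yp_bar
  attr(out, "Ys_bar") <- Ys_bar
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' 10-grade scoring of a stress index
#'
#' Maps index values to integer scores 1..10. Two variants:
#' \describe{
#'   \item{`"minmax"`}{linear min-max binning with half-up rounding,
#'     \eqn{score = \lfloor 1 + 9 (x - min)/(max - min) + 0.5 \rfloor};}
#'   \item{`"decile"`}{decile ranks, \eqn{\lceil 10\,rank/n \rceil} with
#'     average ranks for ties.}
#' }
#' For `orientation = "lower_better"` (SSI, TOL: lower = more tolerant) the
#' values are reversed first, so the best genotype scores 10. A constant
#' input yields the neutral score 5 for every genotype (documented
#' convention).
#'
#' @param x Numeric index values (>= 2 values).
#' @param orientation `"higher_better"` or `"lower_better"`.
#' @param method `"minmax"` (default) or `"decile"`.
#' @return Integer scores in 1..10.
#' @export
score_indices <- function(x, orientation = c("higher_better", "lower_better"),
                          method = c("minmax", "decile")) {
  orientation <- match.arg(orientation)
  method <- match.arg(method)
  if (length(x) == 0) stop("empty input", call. = FALSE)
  if (orientation == "lower_better") x <- -x
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(5L, length(x)))
  s <- if (method == "minmax") {
    round_half_up(1 + 9 * (x - rng[1]) / (rng[2] - rng[1]))
  } else {
    ceiling(10 * rank(x, ties.method = "average") / length(x))
  }
  as.integer(pmin(pmax(s, 1L), 10L))
}

#' Score all five indices and aggregate into RCI and PCI
#'
#' SSI and TOL are scored `lower_better`; MP, GMP and STI `higher_better`.
#' The resilience capacity index RCI is the mean of the SSI and TOL scores;
#' the production capacity index PCI is the mean of the MP, GMP and STI
#' scores. Both lie between 1 and 10.
#'
#' @param indices Output of [compute_stress_indices()].
#' @param method Scoring variant, see [score_indices()].
#' @return `data.frame` with the five scores, `RCI` and `PCI`.
#' @export
compute_rci_pci <- function(indices, method = c("minmax", "decile")) {
  method <- match.arg(method)
  need <- c("SSI", "TOL", "MP", "GMP", "STI")
  stopifnot(all(need %in% names(indices)))
  sc <- data.frame(
    genotype = indices$genotype,
    score_SSI = score_indices(indices$SSI, "lower_better", method),
    score_TOL = score_indices(indices$TOL, "lower_better", method),
    score_MP = score_indices(indices$MP, "higher_better", method),
    score_GMP = score_indices(indices$GMP, "higher_better", method),
    score_STI = score_indices(indices$STI, "higher_better", method),
    stringsAsFactors = FALSE
  )
  sc$RCI <- (sc$score_SSI + sc$score_TOL) / 2
  sc$PCI <- (sc$score_MP + sc$score_GMP + sc$score_STI) / 3
  sc
}

#' Classify genotypes into Fernandez groups A-D
#'
#' Quadrants around the population means of RCI and PCI:
#' A = high resilience & high productivity (both at or above the mean),
#' B = productive but not resilient, C = resilient but not productive
#' (higher relative performance only under stress), D = low on both.
#' Values exactly at a mean count as "high" (deterministic tie rule).
#'
#' @param scores Output of [compute_rci_pci()] (needs `RCI`, `PCI`).
#' @param mixed_orientation If `"B_productive"` (default), B is the
#'   high-PCI/low-RCI quadrant; `"B_resilient"` swaps B and C.
#' @return The input with a `group` column (factor A/B/C/D).
#' @export
classify_groups <- function(scores,
                            mixed_orientation = c("B_productive",
                                                  "B_resilient")) {
  mixed_orientation <- match.arg(mixed_orientation)
  stopifnot(all(c("RCI", "PCI") %in% names(scores)))
  hiR <- scores$RCI >= mean(scores$RCI)
  hiP <- scores$PCI >= mean(scores$PCI)
  g <- ifelse(hiR & hiP, "A",
              ifelse(!hiR & !hiP, "D",
                     ifelse(hiP, "B", "C")))
  if (mixed_orientation == "B_resilient") {
    g[g == "B"] <- "tmp"; g[g == "C"] <- "B"; g[g == "tmp"] <- "C"
  }
  scores$group <- factor(g, levels = c("A", "B", "C", "D"))
  scores
}

#' Compare extreme groups A and D trait by trait
#'
#' Welch (unequal-variance) two-sample t-test per trait between the
#' genotypes of groups A and D, with means, standard errors and
#' significance stars (`*` p < 0.05, `**` p < 0.01).
#'
#' @param trait_values Long table (`genotype`, `trait`, `value`), typically
#'   genotype BLUPs within one treatment.
#' @param groups Named group vector/factor (names = genotypes) or a
#'   classified score table from [classify_groups()].
#' @param alpha Significance level for the single-star flag.
#' @return `data.frame`: per trait, group A/D n, mean, se, Welch `t`, `df`,
#'   `p_value`, `stars`.
#' @export
compare_extreme_groups <- function(trait_values, groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$genotype)
  }
  gA <- names(groups)[groups == "A"]
  gD <- names(groups)[groups == "D"]
  if (length(gA) < 2 || length(gD) < 2) {
    warning("group A or D has fewer than 2 members; comparison skipped",
            call. = FALSE)
    return(data.frame())
  }
  traits <- unique(trait_values$trait)
  rows <- lapply(traits, function(tr) {
    dv <- trait_values[trait_values$trait == tr, ]
    vA <- dv$value[dv$genotype %in% gA]
    vD <- dv$value[dv$genotype %in% gD]
    tt <- stats::t.test(vA, vD, var.equal = FALSE)
    data.frame(
      trait = tr,
      n_A = length(vA), mean_A = mean(vA), se_A = stats::sd(vA) / sqrt(length(vA)),
      n_D = length(vD), mean_D = mean(vD), se_D = stats::sd(vD) / sqrt(length(vD)),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value,
      stars = if (tt$p.value < 0.01) "**" else if (tt$p.value < alpha) "*" else "",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Add configurable derived indices (SPW, WUE, PNUE, ...)
#'
#' Augments a wide per-genotype (or per-plant) table with derived columns
#' computed from configurable formulas, e.g. water use efficiency
#' `WUE = BDw / water` or physiological nitrogen use efficiency
#' `PNUE = BDw / (BDw * NC / 100)`. Formulas are given as strings evaluated
#' against the table's columns; input columns are never modified, and the
#' applied formulas are recorded in the `formulas` attribute.
#'
#' @param data Wide `data.frame`.
#' @param config Named list of formula strings, e.g.
#'   `list(WUE = "BDw / water")`.
#' @return The augmented table.
#' @export
compute_derived_indices <- function(data,
                                    config = list(
                                      SPW = "1000 * BDw / PHg",
                                      WUE = "BDw / water",
                                      PNUE = "BDw / (BDw * NC / 100)")) {
  out <- data
  for (nm in names(config)) {
    expr <- parse(text = config[[nm]])[[1]]
    vars <- all.vars(expr)
    missing_vars <- setdiff(vars, names(data))
    if (length(missing_vars)) {
      stop("formula '", nm, "' needs missing column(s): ",
           paste(missing_vars, collapse = ", "), call. = FALSE)
    }
    val <- eval(expr, envir = data)
    if (any(!is.finite(val))) {
      stop("formula '", nm, "' produced non-finite values ",
           "(division by zero?)", call. = FALSE)
    }
    out[[nm]] <- val
  }
  attr(out, "formulas") <- config
  out
}
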
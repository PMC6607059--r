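#' Pipeline configuration
#'
#' Bundles everything needed for an end-to-end run: the input mode
#' (synthetic generation or a CSV trait table), design and panel
#' configurations, which traits are responses, the control label,
#' significance levels, the scoring variant and the output directory.
#' Validation is fail-fast: an invalid configuration never starts a run.
#'
#' @param mode `"synthetic"` or `"csv"`.
#' @param sim A [sim_config()] (synthetic mode).
#' @param panel A [panel_config()] (synthetic mode).
#' @param csv_path Input trait table (csv mode).
#' @param control Control treatment label.
#' @param responses Response trait names (fit targets for penalized
#'   selection; the second one is the classification / AMMI yield).
#' @param alpha Edge / test significance level.
#' @param scoring `"minmax"` or `"decile"` (see [score_indices()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; stage sub-seeds are derived from it.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "csv"),
                            sim = sim_config(),
                            panel = panel_config(),
                            csv_path = NULL,
                            control = "C",
                            responses = c("BFw", "BDw"),
                            alpha = 0.05,
                            scoring = c("minmax", "decile"),
                            out_dir = "phenotrial_out",
                            seed = 1L) {
  mode <- match.arg(mode)
  scoring <- match.arg(scoring)
  if (mode == "synthetic") {
    stopifnot(inherits(sim, "sim_config"), inherits(panel, "panel_config"))
    if (!control %in% sim$treatments) {
      stop("control label '", control, "' not among treatments", call. = FALSE)
    }
  } else if (is.null(csv_path)) {
    stop("csv mode needs csv_path", call. = FALSE)
  }
  structure(list(mode = mode, sim = sim, panel = panel, csv_path = csv_path,
                 control = control, responses = responses, alpha = alpha,
                 scoring = scoring, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sim <- do.call(sim_config, raw$sim %||% list())
  panel <- do.call(panel_config, raw$panel %||% list())
  args <- raw[setdiff(names(raw), c("sim", "panel"))]
  do.call(pipeline_config, c(list(sim = sim, panel = panel), args))
}

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

sub_seed <- function(seed, offset) (seed + offset * 1009L) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' Executes the analysis sequence end to end: simulate (or load) the trait
#' table; fit both residual-variance models per trait and select by AIC;
#' predict genotype BLUPs; write summaries, per-treatment correlation
#' matrices and networks; run fivefold-CV lasso and ridge per treatment x
#' response on the BLUPs; compute stress indices, 10-grade scores, RCI/PCI,
#' A-D groups and A-vs-D Welch comparisons per stress treatment; and the
#' AMMI decomposition of the dry-weight genotype x treatment table. All
#' outputs are CSV/JSON under `config$out_dir`; a manifest records the
#' config hash, seed and per-stage files. Identical config + seed gives
#' identical outputs. A stage failure aborts with a stage-named error and
#' leaves a `.partial` marker.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (invisibly), as written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out, ".partial")
  file.create(marker)
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## stage: data
  tbl <- stage("data", {
    if (config$mode == "synthetic") {
      sim <- config$sim
      sim$seed <- sub_seed(config$seed, 1L)
      simulate_trait_panel(sim, config$panel)
    } else {
      read_trait_table(config$csv_path)
    }
  })
  files["trait_table"] <- write_csv_plain(tbl, file.path(out, "trait_table.csv"))
  treatments <- unique(tbl$treatment)
  stress_trts <- setdiff(treatments, config$control)
  traits <- unique(tbl$trait)

  ## stage: variance components + BLUPs
  vc <- stage("variance_components", {
    lapply(stats::setNames(traits, traits), function(tr) {
      hom <- fit_reml(tbl, model_spec(tr, "homogeneous"))
      het <- fit_reml(tbl, model_spec(tr, "heterogeneous"))
      sel <- select_residual_model(hom, het)
      herit <- heritability_and_contributions(sel)
      list(fit = sel, hom = hom, het = het, h2 = herit$h2,
           contributions = herit$contributions)
    })
  })
  comps <- lapply(vc, function(x) list(
    residual_model = x$fit$residual_model,
    sigma2_G = x$fit$sigma2_G, sigma2_T = x$fit$sigma2_T,
    sigma2_GT = x$fit$sigma2_GT,
    sigma2_E = as.list(x$fit$sigma2_E),
    logREML = x$fit$logREML, AIC = x$fit$AIC,
    AIC_homogeneous = x$hom$AIC, AIC_heterogeneous = x$het$AIC,
    converged = x$fit$converged, h2 = x$h2,
    contributions = as.list(x$contributions)))
  jsonlite::write_json(comps, file.path(out, "components.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["components"] <- file.path(out, "components.json")
  blups <- do.call(rbind, lapply(vc, function(x) genotype_blups(x$fit)))
  rownames(blups) <- NULL
  files["blups"] <- write_csv_plain(blups, file.path(out, "blups.csv"))

  ## stage: summaries + networks
  stage("summaries_network", {
    files["summary"] <- write_csv_plain(
      summarize_traits(tbl, config$control), file.path(out, "summary.csv"))
    for (trt in treatments) {
      cm <- correlation_matrix(blups[blups$treatment == trt, ])
      safe <- gsub("[^A-Za-z0-9]", "_", trt)
      fp <- file.path(out, paste0("correlations_", safe, ".csv"))
      utils::write.csv(cm$r, fp, fileEncoding = "UTF-8")
      files[paste0("correlations_", safe)] <- fp
      net <- build_network(cm, alpha = config$alpha)
      fn <- file.path(out, paste0("network_", safe, ".json"))
      jsonlite::write_json(list(nodes = net$nodes, edges = net$edges),
                           fn, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files[paste0("network_", safe)] <- fn
    }
  })

  ## stage: penalized selection (on BLUPs, per treatment x response)
  sel_metrics <- list()
  stage("penalized_selection", {
    predictors <- setdiff(traits, config$responses)
    for (method in c("lasso", "ridge")) {
      fits <- list()
      for (resp in config$responses) {
        for (trt in treatments) {
          b <- blups[blups$treatment == trt, ]
          genos <- unique(b$genotype)
          X <- do.call(cbind, lapply(stats::setNames(predictors, predictors),
                                     function(tr) {
            bb <- b[b$trait == tr, ]
            stats::setNames(bb$value, bb$genotype)[genos]
          }))
          yv <- b[b$trait == resp, ]
          yy <- stats::setNames(yv$value, yv$genotype)[genos]
          std <- standardize(X, yy)
          fits[[paste(resp, trt, sep = ".")]] <-
            cross_validate_lambda(std, method,
                                  seed = sub_seed(config$seed, 2L))
        }
      }
      tab <- coefficient_table(fits)
      fp <- file.path(out, paste0(method, "_coefficients.csv"))
      files[paste0(method, "_coefficients")] <- write_csv_plain(tab, fp)
      sel_metrics[[method]] <- lapply(fits, function(f)
        list(lambda_opt = f$lambda_opt, nonzero = f$nonzero_count))
    }
  })

  ## stage: stress classification (per stress treatment, yield = 2nd response)
  recovery <- NULL
  stage("stress_classification", {
    yield <- config$responses[length(config$responses)]
    yb <- blups[blups$trait == yield, ]
    Yp <- stats::setNames(yb$value[yb$treatment == config$control],
                          yb$genotype[yb$treatment == config$control])
    planted <- attr(tbl, "planted_groups")
    for (trt in stress_trts) {
      Ys <- stats::setNames(yb$value[yb$treatment == trt],
                            yb$genotype[yb$treatment == trt])[names(Yp)]
      idx <- compute_stress_indices(Yp, Ys)
      scores <- classify_groups(compute_rci_pci(idx, config$scoring))
      safe <- gsub("[^A-Za-z0-9]", "_", trt)
      files[paste0("stress_indices_", safe)] <- write_csv_plain(
        idx, file.path(out, paste0("stress_indices_", safe, ".csv")))
      files[paste0("scores_", safe)] <- write_csv_plain(
        scores, file.path(out, paste0("scores_", safe, ".csv")))
      cmp <- compare_extreme_groups(
        blups[blups$treatment == trt, ], scores, alpha = config$alpha)
      files[paste0("group_comparison_", safe)] <- write_csv_plain(
        cmp, file.path(out, paste0("group_comparison_", safe, ".csv")))
      if (!is.null(planted)) {
        got <- stats::setNames(as.character(scores$group), scores$genotype)
        for (gl in c("A", "D")) {
          pl <- names(planted)[planted == gl]
          recovery[[paste(trt, gl, sep = ".")]] <-
            mean(got[pl] == gl)
        }
      }
    }
  })

  ## stage: AMMI on the yield trait
  stage("ammi", {
    yield <- config$responses[length(config$responses)]
    tw <- two_way_table(blups, yield)
    res <- ammi_decompose(double_center(tw), n_components = 2)
    stab <- stability_summary(res)
    sc <- rbind(
      data.frame(entity = "genotype", label = rownames(res$genotype_scores),
                 IPC1 = res$genotype_scores[, 1],
                 IPC2 = res$genotype_scores[, 2],
                 distance = stab$distance, row.names = NULL),
      data.frame(entity = "treatment", label = rownames(res$treatment_scores),
                 IPC1 = res$treatment_scores[, 1],
                 IPC2 = res$treatment_scores[, 2],
                 distance = sqrt(rowSums(res$treatment_scores^2)),
                 row.names = NULL))
    files["ammi_scores"] <- write_csv_plain(
      sc, file.path(out, "ammi_scores.csv"))
    jsonlite::write_json(
      list(singular_values = res$d,
           variance_explained = res$variance_explained,
           rank = res$rank),
      file.path(out, "ammi_summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    files["ammi_summary"] <- file.path(out, "ammi_summary.json")
  })

  ## manifest
  cfg_json <- file.path(out, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["config"] <- cfg_json
  manifest <- list(
    package_version = as.character(utils::packageVersion("phenotrial")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_json)),
    # paths relative to out_dir so identical runs give identical manifests
    files = as.list(vapply(files, basename, character(1))),
    group_recovery = recovery,
    selection = sel_metrics
  )
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.remove(marker)
  invisible(manifest)
}

serialize_config <- function(config) {
  list(
    mode = config$mode,
    sim = unclass(config$sim),
    panel = lapply(unclass(config$panel), function(x)
      if (is.matrix(x)) as.data.frame(x) else x),
    control = config$control, responses = config$responses,
    alpha = config$alpha, scoring = config$scoring, seed = config$seed
  )
}
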
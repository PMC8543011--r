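#' Run configuration for the end-to-end pipeline
#'
#' Collects the tunable parameters of every stage with defaults matching the
#' reporting conventions used throughout: gating quantile 0.999, clamp floor
#' 0.01% and cap 100%, DEG thresholds p < 0.01 with LFC > 2 (CD8) / > 1.4
#' (CD4), top-K validation window K = 300, single-cell positivity rule
#' "expression > 0".
#'
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "gate", "profile", "genesets", "insitu")`.
#' @param gating_quantile Control quantile for [set_thresholds()].
#' @param clamp_floor,clamp_cap Clamps for background-subtracted percents.
#' @param p_cut,lfc_cut_cd8,lfc_cut_cd4 DEG filtering thresholds.
#' @param top_k Validation rank window.
#' @param sc_threshold Single-cell positivity cutoff (expression strictly
#'   greater).
#' @param seed Master seed for simulation stages.
#' @param flow_config,bulk_config,sc_config Optional simulator configs; built
#'   from `seed` when omitted.
#' @param out_dir Output directory (created); `NULL` disables file output.
#' @return Object of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "gate", "profile"),
                       gating_quantile = 0.999,
                       clamp_floor = 0.01, clamp_cap = 100,
                       p_cut = 0.01, lfc_cut_cd8 = 2, lfc_cut_cd4 = 1.4,
                       top_k = 300, sc_threshold = 0, seed = 1L,
                       flow_config = NULL, bulk_config = NULL,
                       sc_config = NULL, out_dir = NULL) {
  known <- c("simulate", "gate", "profile", "genesets", "insitu")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_config("stages", paste("unknown:", paste(bad, collapse = ", ")))
  structure(list(stages = stages, gating_quantile = gating_quantile,
                 clamp_floor = clamp_floor, clamp_cap = clamp_cap,
                 p_cut = p_cut, lfc_cut_cd8 = lfc_cut_cd8,
                 lfc_cut_cd4 = lfc_cut_cd4, top_k = top_k,
                 sc_threshold = sc_threshold, seed = as.integer(seed),
                 flow_config = flow_config, bulk_config = bulk_config,
                 sc_config = sc_config, out_dir = out_dir),
            class = "run_config")
}

#' Execute the pipeline stages and emit a run manifest
#'
#' Runs the requested stages in order on simulated inputs (simulate ->
#' gate -> profile for flow; genesets for paired bulk; insitu for single
#' cells), writes TSV outputs when `out_dir` is set, and returns a manifest
#' recording the config echo, package version, per-stage timings and
#' warnings. Identical config and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return Object of class `run_manifest`; stage results in `$results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  warnings_log <- character()
  results <- list()
  timings <- numeric()
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  wrap <- function(stage, expr) {
    tic <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), tic, units = "secs"))
    res
  }
  sim <- NULL
  for (stage in config$stages) {
    results[[stage]] <- switch(stage,
      simulate = wrap("simulate", {
        fc <- config$flow_config %||% flow_sim_config(seed = config$seed)
        sim <- generate_flow_events(fc)
        if (!is.null(out))
          for (nm in names(sim$events))
            write_events_csv(sim$events[[nm]],
                             file.path(out, paste0("events_", nm, ".csv")))
        sim
      }),
      gate = wrap("gate", {
        if (is.null(sim)) stop("gate requires the simulate stage")
        thr <- set_thresholds(sim$events$alone, config$gating_quantile)
        pos <- lapply(sim$events, call_positivity, thresholds = thr)
        list(thresholds = thr, positivity = pos)
      }),
      profile = wrap("profile", {
        gate <- results$gate
        if (is.null(gate)) stop("profile requires the gate stage")
        pr <- lapply(c(CD8 = "CD8", CD4 = "CD4"), function(ss) list(
          metrics = reactivity_metrics(gate$positivity$autologous,
                                       gate$positivity$alone, ss),
          profile = combination_profile(gate$positivity$autologous,
                                        gate$positivity$alone, ss),
          contribution = contribution_order(gate$positivity$autologous, ss)))
        if (!is.null(out))
          for (ss in names(pr)) {
            utils::write.table(pr[[ss]]$metrics,
                               file.path(out, paste0("reactivity_", ss, ".tsv")),
                               sep = "\t", row.names = FALSE, quote = FALSE)
            utils::write.table(pr[[ss]]$profile$combos,
                               file.path(out, paste0("combinations_", ss, ".tsv")),
                               sep = "\t", row.names = FALSE, quote = FALSE)
          }
        pr
      }),
      genesets = wrap("genesets", {
        bc <- config$bulk_config %||% bulk_sim_config(seed = config$seed)
        bsim <- generate_bulk_pairs(bc)
        degs <- compute_paired_lfc(bsim$expr)
        gs <- derive_gene_set(degs, "CD8", config$p_cut, config$lfc_cut_cd8)
        rep <- validate_top_k(gs, degs, K = min(config$top_k, nrow(degs)))
        if (!is.null(out)) {
          utils::write.table(degs, file.path(out, "degs.tsv"), sep = "\t",
                             row.names = FALSE, quote = FALSE)
          writeLines(gs$genes, file.path(out, "geneset_CD8.txt"))
        }
        list(degs = degs, gene_set = gs, validation = rep, truth = bsim$truth)
      }),
      insitu = wrap("insitu", {
        scc <- config$sc_config %||% sc_sim_config(seed = config$seed)
        ssim <- generate_sc_counts(scc)
        calls <- binarize_markers(ssim$sc, threshold = config$sc_threshold)
        clusters <- assign_clusters(calls)
        hm <- cluster_geneset_heatmap(ssim$sc, clusters,
                                      ssim$truth$activation_genes)
        if (!is.null(out))
          utils::write.table(data.frame(gene = rownames(hm$z), hm$z,
                                        check.names = FALSE),
                             file.path(out, "heatmap_z.tsv"), sep = "\t",
                             row.names = FALSE, quote = FALSE)
        list(clusters = clusters, heatmap = hm, truth = ssim$truth)
      }),
      stop("unknown stage: ", stage))
  }
  manifest <- structure(list(
    config = config,
    version = as.character(utils::packageVersion("tilreact")),
    timings = timings,
    warnings = warnings_log,
    finished = format(Sys.time(), tz = "UTC"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    results = results), class = "run_manifest")
  if (!is.null(out)) {
    slim <- manifest[c("version", "timings", "warnings", "finished", "elapsed_s")]
    slim$seed <- config$seed
    slim$stages <- config$stages
    jsonlite::write_json(slim, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> tilreact %s; stages: %s; %.1fs; %d warning(s)\n",
              x$version, paste(names(x$timings), collapse = " -> "),
              x$elapsed_s, length(x$warnings)))
  invisible(x)
}
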
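#' Configuration for paired bulk-expression simulation
#'
#' Emulates paired TIL samples from the same patient measured after co-culture
#' with autologous versus allogeneic tumor cells: log2-scale expression with a
#' chosen set of genes truly upregulated in the autologous condition.
#'
#' @param n_genes Total genes in the universe (named `gene0001`, ...).
#' @param n_pairs Patients, each contributing one sample per condition
#'   (must be >= 2 for the paired test to be defined).
#' @param spiked_genes Named numeric vector: gene name -> true mean log2 fold
#'   change added to the autologous column. Names must fall inside the gene
#'   universe.
#' @param noise_sd Per-gene residual SD on the log2 scale (> 0).
#' @param baseline_mean,baseline_sd Location/scale of baseline log2 expression.
#' @param seed Integer seed.
#' @return Object of class `bulk_sim_config`.
#' @export
bulk_sim_config <- function(n_genes = 2000, n_pairs = 12,
                            spiked_genes = NULL, noise_sd = 0.5,
                            baseline_mean = 5, baseline_sd = 2, seed = 1L) {
  if (n_pairs < 2) stop_config("n_pairs", "must be >= 2 (paired test undefined)")
  if (noise_sd <= 0) stop_config("noise_sd", "must be > 0")
  universe <- sprintf("gene%04d", seq_len(n_genes))
  if (is.null(spiked_genes)) {
    spiked_genes <- setNames(rep(3, min(100, n_genes)),
                             universe[seq_len(min(100, n_genes))])
  }
  if (!all(names(spiked_genes) %in% universe))
    stop_config("spiked_genes", "names must fall inside the gene universe")
  structure(list(n_genes = as.integer(n_genes), n_pairs = as.integer(n_pairs),
                 genes = universe, spiked_genes = spiked_genes,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Generate paired autologous/allogeneic bulk expression
#'
#' Produces a genes x (2 * n_pairs) log2-scale matrix. Spiked genes receive
#' their true LFC in the autologous columns; every cell carries independent
#' Gaussian noise of SD `noise_sd` on top of a patient-specific baseline.
#'
#' @param config A [bulk_sim_config()].
#' @param subset Subset label attached to the samplesheet (`"CD8"`/`"CD4"`).
#' @return List with `expr` (a `bulk_expression_pair`: list of `matrix` and
#'   `samples` samplesheet) and `truth` (`synthetic_truth` with spiked gene
#'   LFCs).
#' @examples
#' sim <- generate_bulk_pairs(bulk_sim_config(n_genes = 50, n_pairs = 3, seed = 2))
#' dim(sim$expr$matrix)
#' @export
generate_bulk_pairs <- function(config, subset = "CD8") {
  stopifnot(inherits(config, "bulk_sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes; np <- config$n_pairs
    baseline <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
    patient_shift <- stats::rnorm(np, 0, 0.3)  # shared within a pair
    lfc <- setNames(numeric(ng), config$genes)
    lfc[names(config$spiked_genes)] <- config$spiked_genes
    auto <- allo <- matrix(0, ng, np, dimnames = list(config$genes, NULL))
    for (p in seq_len(np)) {
      mu <- baseline + patient_shift[p]
      allo[, p] <- mu + stats::rnorm(ng, 0, config$noise_sd)
      auto[, p] <- mu + lfc + stats::rnorm(ng, 0, config$noise_sd)
    }
    patients <- sprintf("P%02d", seq_len(np))
    mat <- cbind(auto, allo)
    colnames(mat) <- c(paste0(patients, "_auto"), paste0(patients, "_allo"))
    samples <- data.frame(sample = colnames(mat),
                          patient = rep(patients, 2),
                          condition = rep(c("autologous", "allogeneic"), each = np),
                          subset = subset, stringsAsFactors = FALSE)
    expr <- structure(list(matrix = mat, samples = samples),
                      class = "bulk_expression_pair")
    truth <- structure(list(labels = data.frame(gene = config$genes,
                                                true_lfc = unname(lfc),
                                                stringsAsFactors = FALSE),
                            config = config, kind = "bulk"),
                       class = "synthetic_truth")
    list(expr = expr, truth = truth)
  })
}
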
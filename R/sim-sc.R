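#' Configuration for sparse single-cell count simulation
#'
#' Emulates deep-coverage (Smart-seq2-like) single-cell counts for TILs whose
#' latent functional class is one of the eight Boolean combinations of
#' *TNFRSF9*, *TNF* and *IFNG* positivity. Marker genes are detected (count
#' > 0) exactly in the cells of classes declaring them positive, before
#' dropout; a bank of activation genes has negative-binomial expression whose
#' mean increases monotonically with the number of positive markers; the
#' tumor-specificity markers *ENTPD1* and *ITGAE* are expressed with
#' class-dependent probabilities (*ENTPD1* tracks *TNFRSF9*).
#'
#' @param n_cells Cells to generate (single subset per call).
#' @param subset `"CD8"` or `"CD4"`.
#' @param cluster_fractions Named fractions over the 8 combination classes of
#'   `TNFRSF9`/`TNF`/`IFNG` (labels from
#'   `combo_labels(c("TNFRSF9","TNF","IFNG"))`); must sum to 1.
#' @param marker_genes Named character vector giving the gene symbols used for
#'   the three reactivity markers plus `ENTPD1` and `ITGAE`.
#' @param n_activation_genes Number of gradient (activation-program) genes.
#' @param gradient_step Multiplicative increase of the activation-gene mean
#'   per additional positive marker (> 1).
#' @param n_noise_genes Unstructured background genes.
#' @param entpd1_prob,itgae_prob Detection probabilities
#'   `c(when TNFRSF9+, when TNFRSF9-)` for *ENTPD1* and (class-independent
#'   scalar) for *ITGAE*.
#' @param dropout_rate Probability that any truly expressed count is zeroed
#'   (zero-inflation); in `[0, 1)`.
#' @param seed Integer seed.
#' @return Object of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_cells = 5000, subset = "CD8",
                          cluster_fractions = NULL,
                          marker_genes = c(TNFRSF9 = "TNFRSF9", TNF = "TNF",
                                           IFNG = "IFNG", ENTPD1 = "ENTPD1",
                                           ITGAE = "ITGAE"),
                          n_activation_genes = 30,
                          gradient_step = 2,
                          n_noise_genes = 120,
                          entpd1_prob = c(0.75, 0.15),
                          itgae_prob = 0.45,
                          dropout_rate = 0,
                          seed = 1L) {
  if (anyDuplicated(marker_genes))
    stop_config("marker_genes", "gene name collision")
  labels <- combo_labels(c("TNFRSF9", "TNF", "IFNG"))
  if (is.null(cluster_fractions)) {
    cluster_fractions <- setNames(
      c(0.10, 0.08, 0.07, 0.05, 0.08, 0.07, 0.10, 0.45), labels)
  }
  if (!setequal(names(cluster_fractions), labels))
    stop_config("cluster_fractions", "must cover the 8 combination classes")
  if (abs(sum(cluster_fractions) - 1) > 1e-9 || any(cluster_fractions < 0))
    stop_config("cluster_fractions", "must be non-negative and sum to 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_config("dropout_rate", "must lie in [0, 1)")
  if (gradient_step <= 1) stop_config("gradient_step", "must be > 1")
  structure(list(n_cells = as.integer(n_cells), subset = subset,
                 cluster_fractions = cluster_fractions[labels],
                 marker_genes = marker_genes,
                 n_activation_genes = as.integer(n_activation_genes),
                 gradient_step = gradient_step,
                 n_noise_genes = as.integer(n_noise_genes),
                 entpd1_prob = entpd1_prob, itgae_prob = itgae_prob,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "sc_sim_config")
}

#' Generate sparse single-cell counts with known functional classes
#'
#' @param config An [sc_sim_config()].
#' @return List with `sc` (an `sc_expression`: sparse genes x cells count
#'   matrix plus cell metadata) and `truth` (`synthetic_truth` with the latent
#'   class per cell and the activation-gene names).
#' @examples
#' sim <- generate_sc_counts(sc_sim_config(n_cells = 200, seed = 3))
#' dim(sim$sc$counts)
#' @export
generate_sc_counts <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  with_seed(config$seed, {
    n <- config$n_cells
    markers3 <- c("TNFRSF9", "TNF", "IFNG")
    cls <- sample(names(config$cluster_fractions), n, TRUE,
                  config$cluster_fractions)
    posmat <- t(vapply(cls, parse_combo, logical(3), markers = markers3))
    k_pos <- rowSums(posmat)
    act_genes <- sprintf("ACT%03d", seq_len(config$n_activation_genes))
    noise_genes <- sprintf("NSE%03d", seq_len(config$n_noise_genes))
    genes <- c(unname(config$marker_genes), act_genes, noise_genes)
    counts <- matrix(0, length(genes), n, dimnames = list(genes, NULL))
    ## marker genes: truncated NB so positive classes always detect (count>=1)
    pos_count <- function(m) 1L + stats::rnbinom(m, size = 2, mu = 3)
    for (m in markers3) {
      idx <- which(posmat[, m])
      counts[config$marker_genes[[m]], idx] <- pos_count(length(idx))
    }
    p_ent <- ifelse(posmat[, "TNFRSF9"], config$entpd1_prob[1],
                    config$entpd1_prob[2])
    ent_on <- stats::runif(n) < p_ent
    counts[config$marker_genes[["ENTPD1"]], ent_on] <- pos_count(sum(ent_on))
    itg_on <- stats::runif(n) < config$itgae_prob
    counts[config$marker_genes[["ITGAE"]], itg_on] <- pos_count(sum(itg_on))
    ## activation program: NB mean rises geometrically with positive markers
    base_mu <- stats::runif(config$n_activation_genes, 0.8, 2)
    for (g in seq_along(act_genes)) {
      mu <- base_mu[g] * config$gradient_step^k_pos
      counts[act_genes[g], ] <- stats::rnbinom(n, size = 3, mu = mu)
    }
    for (g in noise_genes)
      counts[g, ] <- stats::rnbinom(n, size = 2, mu = 0.5)
    if (config$dropout_rate > 0) {
      nz <- which(counts > 0)
      drop <- nz[stats::runif(length(nz)) < config$dropout_rate]
      counts[drop] <- 0
    }
    cell_ids <- sprintf("cell%05d", seq_len(n))
    colnames(counts) <- cell_ids
    sc <- structure(list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                              "CsparseMatrix"),
                         cells = data.frame(cell = cell_ids,
                                            subset = config$subset,
                                            dataset = "synthetic",
                                            stringsAsFactors = FALSE)),
                    class = "sc_expression")
    truth <- structure(list(labels = data.frame(cell = cell_ids, class = cls,
                                                n_pos = k_pos,
                                                stringsAsFactors = FALSE),
                            activation_genes = act_genes,
                            config = config, kind = "sc"),
                       class = "synthetic_truth")
    list(sc = sc, truth = truth)
  })
}
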
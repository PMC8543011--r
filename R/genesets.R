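#' Normalize a bulk count/expression matrix to log2 scale
#'
#' Per-sample total scaling to a common library size followed by
#' `log2(x + 1)`. Matrices already on a log scale should skip this step.
#'
#' @param mat Genes x samples non-negative matrix.
#' @param target_total Common library size after scaling (default: median of
#'   the observed column totals).
#' @return Log2-scale matrix of the same dimensions.
#' @export
normalize_log2 <- function(mat, target_total = NULL) {
  totals <- colSums(mat)
  if (any(totals <= 0)) stop("sample with zero total", call. = FALSE)
  if (is.null(target_total)) target_total <- stats::median(totals)
  log2(sweep(mat, 2, target_total / totals, "*") + 1)
}

#' Per-gene paired log2 fold changes between autologous and allogeneic
#' co-culture
#'
#' For every gene, the per-patient LFC is the log2 expression in the
#' autologous sample minus the log2 expression in the matched allogeneic
#' sample; the gene's summary is the arithmetic mean LFC and a two-sided
#' paired t-test p-value (a t-test on the per-patient LFC vector). Genes with
#' identical values in both conditions get p = 1 by convention.
#'
#' @param pairs A `bulk_expression_pair` (list with log2 `matrix` and a
#'   `samples` sheet giving `sample`, `patient`, `condition`), or a matrix
#'   plus a `samples` data frame.
#' @param samples Samplesheet when `pairs` is a bare matrix.
#' @return Object of class `deg_records`: data frame with `gene`, `mean_lfc`,
#'   `p_value`, plus the per-patient LFC matrix in attribute `lfc`.
#' @export
compute_paired_lfc <- function(pairs, samples = NULL) {
  if (inherits(pairs, "bulk_expression_pair")) {
    mat <- pairs$matrix; samples <- pairs$samples
  } else mat <- pairs
  stopifnot(is.matrix(mat), !is.null(samples))
  auto <- samples[samples$condition == "autologous", ]
  allo <- samples[samples$condition == "allogeneic", ]
  unmatched <- c(setdiff(auto$patient, allo$patient),
                 setdiff(allo$patient, auto$patient))
  if (length(unmatched) || anyDuplicated(auto$patient) || anyDuplicated(allo$patient))
    stop("patients without exactly one sample per condition: ",
         paste(unique(c(unmatched, auto$patient[duplicated(auto$patient)],
                        allo$patient[duplicated(allo$patient)])), collapse = ", "),
         call. = FALSE)
  patients <- sort(auto$patient)
  a_cols <- auto$sample[match(patients, auto$patient)]
  b_cols <- allo$sample[match(patients, allo$patient)]
  lfc <- mat[, a_cols, drop = FALSE] - mat[, b_cols, drop = FALSE]
  colnames(lfc) <- patients
  mean_lfc <- rowMeans(lfc)
  n <- length(patients)
  sds <- apply(lfc, 1, stats::sd)
  tstat <- mean_lfc / (sds / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  p[sds == 0] <- 1   # degenerate: no variation across patients
  out <- data.frame(gene = rownames(mat), mean_lfc = unname(mean_lfc),
                    p_value = unname(p), stringsAsFactors = FALSE)
  structure(out, class = c("deg_records", "data.frame"),
            lfc = lfc, n_pairs = n)
}

#' Derive a tumor-specific activation gene set
#'
#' Filters the paired differential-expression records to genes with
#' `p < p_cut` and `mean LFC > lfc_cut`, then removes the reactivity marker
#' genes themselves (*TNFRSF9*, *TNF*, *IFNG*), which are tracked separately.
#' Default LFC cutoffs are 2 for CD8 and 1.4 for CD4 gene sets, with
#' `p < 0.01`; no multiple-testing correction is applied by default, but a
#' Benjamini-Hochberg option is available.
#'
#' @param degs A [compute_paired_lfc()] result.
#' @param subset `"CD8"` or `"CD4"` (sets the default `lfc_cut`).
#' @param p_cut P-value cutoff (strict `<`), default 0.01.
#' @param lfc_cut Mean-LFC cutoff (strict `>`); default 2 (CD8) or 1.4 (CD4).
#' @param exclude Marker genes removed by name.
#' @param adjust Apply Benjamini-Hochberg adjustment before filtering.
#' @return Object of class `activation_gene_set`: list with `genes` (sorted),
#'   `subset`, `p_cut`, `lfc_cut`, `excluded`.
#' @export
derive_gene_set <- function(degs, subset = c("CD8", "CD4"), p_cut = 0.01,
                            lfc_cut = NULL,
                            exclude = c("TNFRSF9", "TNF", "IFNG"),
                            adjust = FALSE) {
  subset <- match.arg(subset)
  stopifnot(inherits(degs, "deg_records"))
  if (is.null(lfc_cut)) lfc_cut <- if (subset == "CD8") 2.0 else 1.4
  p <- if (adjust) stats::p.adjust(degs$p_value, "BH") else degs$p_value
  keep <- p < p_cut & degs$mean_lfc > lfc_cut & !(degs$gene %in% exclude)
  structure(list(subset = subset, genes = sort(degs$gene[keep]),
                 p_cut = p_cut, lfc_cut = lfc_cut, excluded = exclude,
                 adjusted = adjust),
            class = "activation_gene_set")
}

#' @export
print.activation_gene_set <- function(x, ...) {
  cat(sprintf("<activation_gene_set> %s: %d genes (p < %g, LFC > %g)\n",
              x$subset, length(x$genes), x$p_cut, x$lfc_cut))
  invisible(x)
}

#' Genes shared between two activation gene sets
#'
#' @param cd8,cd4 [derive_gene_set()] results.
#' @return Sorted character vector of shared genes.
#' @export
intersect_sets <- function(cd8, cd4) {
  stopifnot(inherits(cd8, "activation_gene_set"),
            inherits(cd4, "activation_gene_set"))
  sort(intersect(cd8$genes, cd4$genes))
}

#' Validate a gene set against an antigen-specific reference by top-K rank
#'
#' Ranks the reference genes by decreasing mean LFC (ties broken by gene
#' name, stable) and reports the fraction of gene-set members found within
#' the top K most-upregulated genes, together with the fraction whose
#' reference mean LFC exceeds 1.
#'
#' @param gene_set An [derive_gene_set()] result.
#' @param reference A [compute_paired_lfc()] result (or any data frame with
#'   `gene` and `mean_lfc`) covering the gene universe.
#' @param K Top-rank window, default 300.
#' @param lfc_floor LFC threshold for the second fraction, default 1.
#' @return Object of class `validation_report`: list with `K`,
#'   `frac_in_top_k`, `frac_lfc_above`, `n_set`, `missing` (set members absent
#'   from the reference).
#' @export
validate_top_k <- function(gene_set, reference, K = 300, lfc_floor = 1) {
  stopifnot(inherits(gene_set, "activation_gene_set"))
  if (K > nrow(reference))
    stop("K exceeds the reference gene universe", call. = FALSE)
  ord <- order(-reference$mean_lfc, reference$gene)
  ranks <- seq_len(nrow(reference))
  rank_of <- setNames(ranks, reference$gene[ord])
  present <- gene_set$genes[gene_set$genes %in% reference$gene]
  missing <- setdiff(gene_set$genes, present)
  lfc_of <- setNames(reference$mean_lfc, reference$gene)
  structure(list(K = K,
                 frac_in_top_k = mean(rank_of[present] <= K),
                 frac_lfc_above = mean(lfc_of[present] > lfc_floor),
                 n_set = length(gene_set$genes), missing = missing),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %.0f%% of %d genes in top %d; %.0f%% with LFC > 1\n",
              100 * x$frac_in_top_k, x$n_set, x$K, 100 * x$frac_lfc_above))
  invisible(x)
}
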
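#' Binarize marker-gene expression in single cells
#'
#' Calls a cell positive for a marker gene when its expression strictly
#' exceeds the threshold (default 0: detection equals positivity, the natural
#' rule for deep-coverage single-cell data).
#'
#' @param sc An `sc_expression` (list with genes x cells `counts` and `cells`
#'   metadata) or a bare genes x cells matrix.
#' @param markers Marker gene names (must be present as rows).
#' @param threshold Positivity cutoff; expression must be `> threshold`.
#' @return Object of class `marker_call_matrix`: cells x markers logical
#'   matrix with cell ids as rownames.
#' @export
binarize_markers <- function(sc, markers = c("TNFRSF9", "TNF", "IFNG"),
                             threshold = 0) {
  mat <- if (inherits(sc, "sc_expression")) sc$counts else sc
  missing <- setdiff(markers, rownames(mat))
  if (length(missing))
    stop("marker gene(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  calls <- t(as.matrix(mat[markers, , drop = FALSE]) > threshold)
  structure(calls, class = c("marker_call_matrix", class(calls)))
}

GROUP_LEVELS <- c("Triple Negative", "Single Positive",
                  "Double Positive", "Triple Positive")

#' Partition cells into functional clusters by marker positivity
#'
#' Each cell is assigned to exactly one of the `2^k` Boolean combination
#' clusters of its k marker calls (8 clusters for the
#' *TNFRSF9*/*TNF*/*IFNG* panel, 4 for *ENTPD1*/*ITGAE*). For three markers
#' the grouped label counts positive markers: zero = Triple Negative, one =
#' Single Positive, two = Double Positive, three = Triple Positive.
#'
#' @param calls A [binarize_markers()] result with 2 or 3 marker columns.
#' @return Object of class `functional_clusters`: data frame with `cell`,
#'   `combo` (factor over all `2^k` labels) and, for 3 markers, `group`
#'   (factor over the four grouped labels).
#' @export
assign_clusters <- function(calls) {
  k <- ncol(calls)
  if (!k %in% c(2L, 3L)) stop("need 2 or 3 marker columns", call. = FALSE)
  markers <- colnames(calls)
  labels <- combo_labels(markers)
  combo <- apply(calls, 1, function(r)
    paste0(markers, ifelse(r, "+", "-"), collapse = ""))
  out <- data.frame(cell = rownames(calls) %||% as.character(seq_len(nrow(calls))),
                    combo = factor(combo, levels = labels),
                    stringsAsFactors = FALSE)
  if (k == 3L)
    out$group <- factor(GROUP_LEVELS[rowSums(calls) + 1], levels = GROUP_LEVELS)
  structure(out, class = c("functional_clusters", "data.frame"),
            markers = markers)
}

## per-row Z-score with population (n) denominator; constant rows -> 0
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  z <- (m - mu) / sd_pop
  z[sd_pop == 0, ] <- 0
  z
}

cluster_means <- function(mat, cluster) {
  cl <- droplevels(cluster)
  out <- vapply(levels(cl), function(l)
    Matrix::rowMeans(mat[, cl == l, drop = FALSE]),
    numeric(nrow(mat)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1,
                  dimnames = list(rownames(mat), levels(cl)))
  out
}

#' Cross-cluster Z-score heatmap of a gene set
#'
#' Computes each gene's mean expression per functional cluster and
#' standardizes every gene row to mean 0, SD 1 across clusters (population
#' denominator) — the summary underlying gene-set heatmaps over the
#' TN/SP/DP/TP or combination clusters. Empty clusters are dropped with a
#' warning.
#'
#' @param sc An `sc_expression` or genes x cells matrix (counts or
#'   normalized).
#' @param clusters An [assign_clusters()] result; which grouping is used is
#'   set by `by` (`"group"` when available, else `"combo"`).
#' @param gene_set Character vector of genes (absent genes dropped with a
#'   warning) or an `activation_gene_set`.
#' @param by Cluster column to summarize over.
#' @param normalize Apply per-cell total scaling + `log1p` before averaging.
#' @return Object of class `cluster_heatmap`: list with `z` (genes x clusters
#'   Z-scores), `means` (underlying cluster means) and `cluster_sizes`.
#' @export
cluster_geneset_heatmap <- function(sc, clusters, gene_set,
                                    by = c("group", "combo"),
                                    normalize = TRUE) {
  mat <- if (inherits(sc, "sc_expression")) sc$counts else sc
  if (inherits(gene_set, "activation_gene_set")) gene_set <- gene_set$genes
  by <- match.arg(by)
  if (by == "group" && is.null(clusters$group)) by <- "combo"
  cl <- clusters[[by]]
  present <- intersect(gene_set, rownames(mat))
  if (length(present) < length(gene_set))
    warning("dropping gene(s) absent from the matrix: ",
            paste(setdiff(gene_set, present), collapse = ", "))
  if (!length(present)) stop("no gene-set genes present", call. = FALSE)
  empty <- setdiff(levels(cl), levels(droplevels(cl)))
  if (length(empty))
    warning("dropping empty cluster(s): ", paste(empty, collapse = ", "))
  if (nlevels(droplevels(cl)) < 2)
    stop("need at least 2 non-empty clusters", call. = FALSE)
  if (normalize) mat <- normalize_cells(mat)
  means <- cluster_means(mat[present, , drop = FALSE], cl)
  structure(list(z = zscore_rows(means), means = means,
                 cluster_sizes = table(droplevels(cl)), by = by),
            class = "cluster_heatmap")
}

## per-cell total-count scaling to the median total, then log1p
normalize_cells <- function(mat) {
  totals <- Matrix::colSums(mat)
  totals[totals == 0] <- 1
  target <- stats::median(totals)
  log1p(mat %*% Matrix::Diagonal(x = target / totals))
}

#' @export
print.cluster_heatmap <- function(x, ...) {
  cat(sprintf("<cluster_heatmap> %d genes x %d clusters (by %s)\n",
              nrow(x$z), ncol(x$z), x$by))
  invisible(x)
}

#' Score signature panels per cell and summarize per cluster
#'
#' A panel score is the per-cell mean normalized expression of the panel's
#' genes (e.g. exhaustion/dysfunction, co-stimulation, effector, naive
#' programs). Scores are averaged per functional cluster and Z-scored across
#' clusters, yielding one row per panel.
#'
#' @param sc An `sc_expression` or genes x cells matrix.
#' @param clusters An [assign_clusters()] result.
#' @param panels Named list of gene vectors. Genes absent from the matrix are
#'   dropped with a warning; a panel empty after dropping is an error.
#' @param by Cluster column to summarize over.
#' @param normalize Per-cell total scaling + `log1p` before scoring.
#' @return A `cluster_heatmap` whose rows are panels; `cell_scores` attribute
#'   carries the per-cell panel scores.
#' @export
score_signature_panels <- function(sc, clusters, panels,
                                   by = c("group", "combo"),
                                   normalize = TRUE) {
  mat <- if (inherits(sc, "sc_expression")) sc$counts else sc
  by <- match.arg(by)
  if (by == "group" && is.null(clusters$group)) by <- "combo"
  cl <- clusters[[by]]
  stopifnot(length(panels) >= 1, !is.null(names(panels)))
  if (normalize) mat <- normalize_cells(mat)
  scores <- vapply(names(panels), function(pn) {
    genes <- intersect(panels[[pn]], rownames(mat))
    dropped <- setdiff(panels[[pn]], genes)
    if (length(dropped))
      warning("panel '", pn, "': dropping absent gene(s): ",
              paste(dropped, collapse = ", "))
    if (!length(genes))
      stop("panel '", pn, "' empty after dropping absent genes", call. = FALSE)
    Matrix::colMeans(mat[genes, , drop = FALSE])
  }, numeric(ncol(mat)))
  means <- t(vapply(colnames(scores), function(pn)
    tapply(scores[, pn], droplevels(cl), mean), numeric(nlevels(droplevels(cl)))))
  structure(list(z = zscore_rows(means), means = means,
                 cluster_sizes = table(droplevels(cl)), by = by,
                 cell_scores = scores),
            class = "cluster_heatmap")
}

#' Cross-tabulate reactivity combinations against specificity-marker clusters
#'
#' Builds the 8 x 4 contingency table of the *TNFRSF9*/*TNF*/*IFNG*
#' combination cluster against the *ENTPD1*/*ITGAE* cluster for the same
#' cells, with row and column fractions — the summary behind asking whether
#' CD39/CD103 positivity captures the reactive combinations.
#'
#' @param calls_3 A 3-marker [binarize_markers()] result.
#' @param calls_2 A 2-marker [binarize_markers()] result on the same cells.
#' @return Object of class `specificity_crosstab`: list with `counts`
#'   (8 x 4), `row_frac`, `col_frac`.
#' @export
crosstab_specificity_markers <- function(calls_3, calls_2) {
  if (nrow(calls_3) != nrow(calls_2) ||
      !identical(rownames(calls_3), rownames(calls_2)))
    stop("cell ids differ between the two call matrices", call. = FALSE)
  cl3 <- assign_clusters(calls_3)
  cl2 <- assign_clusters(calls_2)
  counts <- table(cl3$combo, cl2$combo)
  rs <- rowSums(counts); cs <- colSums(counts)
  row_frac <- sweep(counts, 1, pmax(rs, 1), "/")
  col_frac <- sweep(counts, 2, pmax(cs, 1), "/")
  structure(list(counts = counts, row_frac = row_frac, col_frac = col_frac),
            class = "specificity_crosstab")
}
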
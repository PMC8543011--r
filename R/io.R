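#' Read a flow-cytometry event table from CSV or FCS
#'
#' Accepts a delimited event x channel table (header row) or an FCS 3.0
#' file. Channel names are mapped to the canonical panel via `channel_map`,
#' and an intensity transform is applied to the activation/subset channels
#' (`arcsinh` with a configurable cofactor, or `none` for data already on a
#' transformed scale, e.g. the output of the bundled simulator).
#'
#' @param path CSV or FCS file.
#' @param channel_map Named character vector `canonical = file_column`;
#'   identity by default.
#' @param transform `"none"` (default) or `"arcsinh"`.
#' @param cofactor Arcsinh cofactor (default 150, a common choice for
#'   conventional cytometer scales).
#' @param sample_id,condition,inhibitor Metadata overrides when the file
#'   carries none.
#' @return An `event_table` data frame.
#' @export
read_events <- function(path, channel_map = NULL,
                        transform = c("none", "arcsinh"), cofactor = 150,
                        sample_id = NULL, condition = NULL,
                        inhibitor = "none") {
  transform <- match.arg(transform)
  is_fcs <- grepl("\\.fcs$", path, ignore.case = TRUE)
  tab <- if (is_fcs) read_fcs(path)
         else utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(channel_map)) {
    missing <- setdiff(unname(channel_map), names(tab))
    if (length(missing))
      stop("channel(s) in map absent from file: ",
           paste(missing, collapse = ", "), call. = FALSE)
    for (canon in names(channel_map))
      names(tab)[names(tab) == channel_map[[canon]]] <- canon
  }
  need <- c(ACTIVATION_CHANNELS, "CD4", "CD8", "viability")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("event table lacks channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (transform == "arcsinh")
    for (ch in need) tab[[ch]] <- asinh(tab[[ch]] / cofactor)
  if (!all(vapply(tab[need], function(x) all(is.finite(x)), logical(1))))
    stop("non-finite intensities in ", path, call. = FALSE)
  if (is.null(tab$event_id)) tab$event_id <- seq_len(nrow(tab))
  if (!is.null(sample_id)) tab$sample_id <- sample_id
  if (!is.null(condition)) tab$condition <- condition
  if (is.null(tab$sample_id)) tab$sample_id <- basename(path)
  if (is.null(tab$condition)) tab$condition <- NA_character_
  if (is.null(tab$inhibitor)) tab$inhibitor <- inhibitor
  class(tab) <- c("event_table", "data.frame")
  tab
}

#' Write an event table to CSV
#' @param events An `event_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Read/write a bulk expression matrix as TSV (genes x samples)
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path TSV file.
#' @return `read_bulk_tsv`: the matrix; `write_bulk_tsv`: `path`, invisibly.
#' @export
write_bulk_tsv <- function(mat, path) {
  utils::write.table(data.frame(gene = rownames(mat), mat,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bulk_tsv
#' @export
read_bulk_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  mat
}

#' Read/write single-cell counts as MatrixMarket with sidecars
#'
#' Writes `matrix.mtx`, `features.tsv` (gene names) and `barcodes.tsv`
#' (cell ids) into a directory; the reader reassembles an `sc_expression`.
#'
#' @param sc An `sc_expression`.
#' @param dir Directory (created if needed).
#' @return `read_sc_mtx`: an `sc_expression`; `write_sc_mtx`: `dir`,
#'   invisibly.
#' @export
write_sc_mtx <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(sc$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sc$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(sc$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(sc$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_sc_mtx
#' @export
read_sc_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  cells_path <- file.path(dir, "cells.tsv")
  cells <- if (file.exists(cells_path))
    utils::read.delim(cells_path, stringsAsFactors = FALSE)
  else data.frame(cell = colnames(counts), subset = NA, dataset = NA)
  structure(list(counts = counts, cells = cells), class = "sc_expression")
}

#' Write a synthetic-truth object as JSON
#' @param truth A `synthetic_truth`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(kind = truth$kind, seed = truth$config$seed,
                  labels = truth$labels)
  jsonlite::write_json(payload, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
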
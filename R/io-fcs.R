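## Minimal FCS 3.0 I/O: LIST mode, single-precision float, little-endian.
## Covers the subset of the standard needed to exchange event tables with
## cytometry software; keywords beyond the required set are not interpreted.

#' Write an event table's channels to an FCS 3.0 file
#'
#' Stores the numeric channel columns as float32 LIST-mode data with `$PnN`
#' channel names. Metadata columns (sample/condition) go into custom
#' keywords.
#'
#' @param events An `event_table`.
#' @param path Output file.
#' @param channels Channel columns to store (default: all numeric channels).
#' @return `path`, invisibly.
#' @export
write_events_fcs <- function(events, path,
                             channels = c(ACTIVATION_CHANNELS,
                                          "CD4", "CD8", "viability")) {
  mat <- as.matrix(events[, channels, drop = FALSE])
  n_par <- ncol(mat); n_tot <- nrow(mat)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot),
          "$NEXTDATA", "0")
  for (i in seq_len(n_par)) {
    rng <- max(1024, ceiling(max(abs(mat[, i])) + 1))
    kw <- c(kw, sprintf("$P%dN", i), channels[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), as.character(rng))
  }
  kw <- c(kw, "#SAMPLE", as.character(events$sample_id[1] %||% "NA"),
          "#CONDITION", as.character(events$condition[1] %||% "NA"))
  delim <- "|"
  ## iterate: text length depends on the data offsets it encodes
  data_len <- 4L * n_par * n_tot
  text_start <- 58L
  build_text <- function(begin_data, end_data) {
    paste0(delim, paste(c(kw, "$BEGINDATA", as.character(begin_data),
                          "$ENDDATA", as.character(end_data)),
                        collapse = delim), delim)
  }
  text <- build_text(0, 0)
  for (i in 1:3) {
    text_end <- text_start + nchar(text, "bytes") - 1L
    begin_data <- text_end + 1L
    text <- build_text(begin_data, begin_data + data_len - 1L)
  }
  text_end <- text_start + nchar(text, "bytes") - 1L
  begin_data <- text_end + 1L
  end_data <- begin_data + data_len - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, begin_data, end_data, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0 file written by [write_events_fcs()]
#'
#' Parses the header offsets, the TEXT segment and float32 LIST-mode data.
#'
#' @param path FCS file.
#' @return Data frame of channels (float32 precision) with `sample_id` and
#'   `condition` restored from the custom keywords when present.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (substr(header, 1, 6) != "FCS3.0")
    stop("not an FCS 3.0 file: ", path, call. = FALSE)
  off <- as.integer(trimws(substring(header, 10 + 8 * (0:3) + 1, 10 + 8 * (1:4))))
  text_start <- off[1]; text_end <- off[2]
  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 != 0) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), 2)],
                 parts[seq(1, length(parts), 2)])
  n_par <- as.integer(kw[["$PAR"]]); n_tot <- as.integer(kw[["$TOT"]])
  if (!identical(kw[["$DATATYPE"]], "F"))
    stop("unsupported $DATATYPE (only F/float32)", call. = FALSE)
  seek(con, as.integer(kw[["$BEGINDATA"]]))
  vals <- readBin(con, numeric(), n = n_par * n_tot, size = 4,
                  endian = "little")
  mat <- matrix(vals, ncol = n_par, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(n_par),
                          function(i) kw[[sprintf("$P%dN", i)]], character(1))
  out <- as.data.frame(mat)
  if (!is.null(kw[["#SAMPLE"]]) && kw[["#SAMPLE"]] != "NA")
    out$sample_id <- kw[["#SAMPLE"]]
  if (!is.null(kw[["#CONDITION"]]) && kw[["#CONDITION"]] != "NA")
    out$condition <- kw[["#CONDITION"]]
  out
}
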
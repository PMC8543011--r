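# Shared fixture builders; everything generated in code at test time.

## positivity matrix straight from logical columns (bypasses gating)
make_pos <- function(CD137s, CD137i, TNF, IFNg, CD107a, subset = "CD8") {
  n <- length(TNF)
  out <- data.frame(event_id = seq_len(n), subset = subset,
                    CD137s = CD137s, CD137i = CD137i, TNF = TNF,
                    IFNg = IFNg, CD107a = CD107a,
                    stringsAsFactors = FALSE)
  out$CD137 <- out$CD137s | out$CD137i
  structure(out, class = c("positivity_matrix", "data.frame"),
            sample_id = "fixture", n_total = n)
}

## random positivity matrix with given per-marker rates
random_pos <- function(n, rates = c(CD137s = .12, CD137i = .10, TNF = .10,
                                    IFNg = .08, CD107a = .04),
                       subset = "CD8") {
  draw <- function(p) runif(n) < p
  make_pos(draw(rates["CD137s"]), draw(rates["CD137i"]), draw(rates["TNF"]),
           draw(rates["IFNg"]), draw(rates["CD107a"]), subset)
}

## an all-negative control of the same shape
null_pos <- function(n, subset = "CD8") {
  f <- rep(FALSE, n)
  make_pos(f, f, f, f, f, subset)
}

## small bulk pair with explicit per-pair values for one gene
tiny_bulk <- function(auto_vals, allo_vals, gene = "geneX") {
  np <- length(auto_vals)
  mat <- rbind(c(auto_vals, allo_vals))
  rownames(mat) <- gene
  patients <- sprintf("P%02d", seq_len(np))
  colnames(mat) <- c(paste0(patients, "_auto"), paste0(patients, "_allo"))
  samples <- data.frame(sample = colnames(mat), patient = rep(patients, 2),
                        condition = rep(c("autologous", "allogeneic"), each = np),
                        subset = "CD8", stringsAsFactors = FALSE)
  structure(list(matrix = mat, samples = samples),
            class = "bulk_expression_pair")
}

## brute-force per-event combination count (independent oracle)
oracle_combo_counts <- function(pos) {
  labels <- combo_labels(c("CD137", "TNF", "IFNg"))
  counts <- setNames(integer(length(labels)), labels)
  for (i in seq_len(nrow(pos))) {
    lab <- paste0("CD137", if (pos$CD137s[i] || pos$CD137i[i]) "+" else "-",
                  "TNF", if (pos$TNF[i]) "+" else "-",
                  "IFNg", if (pos$IFNg[i]) "+" else "-")
    counts[lab] <- counts[lab] + 1L
  }
  counts
}

## brute-force union sizes over every marker subset (inclusion-exclusion base)
oracle_union_size <- function(flags, markers) {
  if (!length(markers)) return(0L)
  sum(Reduce(`|`, lapply(markers, function(m) flags[, m])))
}
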
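#' Background subtraction with the reporting clamps
#'
#' Subtracts the unstimulated-control positivity from the stimulated
#' positivity. Negative differences are reported as 0.01% and values that
#' exceed 100% after any normalization are reported as 100%, the conventions
#' used for all statistics and figures downstream.
#'
#' @param stimulated_pct,control_pct Percent positive (0--100) in the
#'   stimulated and control samples. Vectorized.
#' @param floor Lower clamp, default 0.01 (percent).
#' @param cap Upper clamp, default 100 (percent).
#' @return Background-subtracted percent, clamped to `[floor, cap]`.
#' @examples
#' subtract_background(3, 1)    # 2
#' subtract_background(1, 3)    # 0.01
#' clamp_percent(104)           # 100
#' @export
subtract_background <- function(stimulated_pct, control_pct,
                                floor = 0.01, cap = 100) {
  if (any(stimulated_pct < 0 | stimulated_pct > 100) ||
      any(control_pct < 0 | control_pct > 100))
    stop("percent inputs must lie in [0, 100]", call. = FALSE)
  clamp_percent(stimulated_pct - control_pct, floor = floor, cap = cap)
}

#' @rdname subtract_background
#' @param x Percent value(s) to clamp.
#' @export
clamp_percent <- function(x, floor = 0.01, cap = 100) {
  pmin(pmax(x, floor), cap)
}

pct_positive <- function(flags) 100 * mean(flags)

#' Reactivity metrics for one sample and subset
#'
#' Computes the three union definitions of TIL activation among live subset
#' events: CD137+ (total CD137), Antitumor Function+ (at least one of TNF,
#' IFN-gamma, CD107a) and Total Reactive (at least one of all four markers),
#' plus each single marker. Each percentage is reported raw and
#' background-subtracted against the matched control (TILs alone), clamped to
#' `[0.01, 100]`.
#'
#' @param pos,control_pos [call_positivity()] results for the stimulated and
#'   control samples.
#' @param subset `"CD8"` or `"CD4"`.
#' @return Object of class `reactivity_result`: a data frame with one row per
#'   metric and columns `metric`, `raw_pct`, `control_pct`, `adjusted_pct`.
#' @export
reactivity_metrics <- function(pos, control_pos, subset = c("CD8", "CD4")) {
  subset <- match.arg(subset)
  p <- pos[pos$subset == subset, , drop = FALSE]
  q <- control_pos[control_pos$subset == subset, , drop = FALSE]
  if (nrow(p) == 0) stop("no live events in subset ", subset, call. = FALSE)
  if (nrow(q) == 0) stop("no live control events in subset ", subset, call. = FALSE)
  unions <- function(m) list(
    CD137s = m$CD137s, CD137i = m$CD137i, CD137 = m$CD137,
    TNF = m$TNF, IFNg = m$IFNg, CD107a = m$CD107a,
    AntitumorFunction = m$TNF | m$IFNg | m$CD107a,
    TotalReactive = m$CD137 | m$TNF | m$IFNg | m$CD107a)
  raw <- vapply(unions(p), pct_positive, numeric(1))
  ctl <- vapply(unions(q), pct_positive, numeric(1))
  out <- data.frame(sample_id = attr(pos, "sample_id") %||% NA_character_,
                    subset = subset, metric = names(raw),
                    raw_pct = unname(raw), control_pct = unname(ctl),
                    adjusted_pct = subtract_background(unname(raw), unname(ctl)),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("reactivity_result", "data.frame"),
            n_events = nrow(p), n_control = nrow(q))
}

#' Boolean-combination profile of reactive cells
#'
#' Assigns each live subset event to one of the eight Boolean combinations of
#' total CD137, TNF and IFN-gamma; the seven combinations that exclude the
#' all-negative population form the reactive profile. Each combination's
#' percent of the parent population is background-subtracted against the
#' matched control combination (negative differences truncated at zero), then
#' renormalized over the seven reactive combinations. The three-way
#' sub-grouping splits total reactive cells (any of the four markers) into
#' CD137+AF-, CD137-AF+ and CD137+AF+, where AF (antitumor function) means at
#' least one of TNF, IFN-gamma, CD107a.
#'
#' @param pos,control_pos [call_positivity()] results.
#' @param subset `"CD8"` or `"CD4"`.
#' @return Object of class `combination_profile` with elements `combos`
#'   (7-row data frame: label, stimulated/control percent of parent, adjusted
#'   percent, fraction of reactive), `grouping` (3-row data frame) and the
#'   denominators used.
#' @export
combination_profile <- function(pos, control_pos, subset = c("CD8", "CD4")) {
  subset <- match.arg(subset)
  p <- pos[pos$subset == subset, , drop = FALSE]
  q <- control_pos[control_pos$subset == subset, , drop = FALSE]
  if (nrow(p) == 0) stop("no live events in subset ", subset, call. = FALSE)
  labels <- combo_labels(REACTIVITY_MARKERS)
  reactive_labels <- setdiff(labels, "CD137-TNF-IFNg-")
  combo_of <- function(m)
    paste0("CD137", ifelse(m$CD137, "+", "-"),
           "TNF", ifelse(m$TNF, "+", "-"),
           "IFNg", ifelse(m$IFNg, "+", "-"))
  stim_pct <- 100 * as.vector(table(factor(combo_of(p), labels))) / nrow(p)
  ctl_pct <- 100 * as.vector(table(factor(combo_of(q), labels))) / nrow(q)
  names(stim_pct) <- names(ctl_pct) <- labels
  adj <- pmax(stim_pct[reactive_labels] - ctl_pct[reactive_labels], 0)
  frac <- if (sum(adj) > 0) adj / sum(adj) else adj
  combos <- data.frame(combo = reactive_labels,
                       stim_pct = unname(stim_pct[reactive_labels]),
                       control_pct = unname(ctl_pct[reactive_labels]),
                       adjusted_pct = unname(adj),
                       fraction = unname(frac),
                       stringsAsFactors = FALSE)
  ## 3-way grouping over total reactive cells (CD107a included in AF)
  af <- p$TNF | p$IFNg | p$CD107a
  reactive <- p$CD137 | af
  g_stim <- c(`CD137+AF-` = 100 * mean(p$CD137 & !af),
              `CD137-AF+` = 100 * mean(!p$CD137 & af),
              `CD137+AF+` = 100 * mean(p$CD137 & af))
  af_q <- q$TNF | q$IFNg | q$CD107a
  g_ctl <- c(`CD137+AF-` = 100 * mean(q$CD137 & !af_q),
             `CD137-AF+` = 100 * mean(!q$CD137 & af_q),
             `CD137+AF+` = 100 * mean(q$CD137 & af_q))
  g_adj <- pmax(g_stim - g_ctl, 0)
  g_frac <- if (sum(g_adj) > 0) g_adj / sum(g_adj) else g_adj
  grouping <- data.frame(group = names(g_stim),
                         stim_pct = unname(g_stim),
                         control_pct = unname(g_ctl),
                         adjusted_pct = unname(g_adj),
                         fraction = unname(g_frac),
                         stringsAsFactors = FALSE)
  structure(list(subset = subset, combos = combos, grouping = grouping,
                 n_events = nrow(p), n_control = nrow(q),
                 n_reactive = sum(reactive)),
            class = "combination_profile")
}

#' @export
print.combination_profile <- function(x, ...) {
  cat(sprintf("<combination_profile> %s: %d live events, %d reactive\n",
              x$subset, x$n_events, x$n_reactive))
  print(x$combos[, c("combo", "fraction")], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Incremental marker contribution to the reactive union
#'
#' Orders markers by decreasing single-marker positive fraction (the panel
#' order CD137, TNF, IFN-gamma, CD107a breaks ties) and reports the
#' incremental union gain of adding each marker, as a percentage of the total
#' reactive population. Gains are non-negative and sum to 100%.
#'
#' @param pos A [call_positivity()] result.
#' @param subset `"CD8"` or `"CD4"`.
#' @param markers Markers considered, default all four.
#' @return Object of class `contribution_decomposition`: data frame with
#'   `marker` (in contribution order), `single_pct` (single-marker percent of
#'   live events) and `gain_pct` (incremental share of the union, summing to
#'   100).
#' @export
contribution_order <- function(pos, subset = c("CD8", "CD4"),
                               markers = FLOW_MARKERS) {
  subset <- match.arg(subset)
  p <- pos[pos$subset == subset, , drop = FALSE]
  flags <- as.matrix(p[, markers, drop = FALSE])
  total <- rowSums(flags) > 0
  if (!any(total)) stop("no reactive events in subset ", subset, call. = FALSE)
  single <- colMeans(flags)
  ## stable order: decreasing single-marker fraction, panel order breaks ties
  ord <- order(-single, match(markers, FLOW_MARKERS))
  gains <- numeric(length(markers))
  covered <- rep(FALSE, nrow(flags))
  for (k in seq_along(ord)) {
    new_cover <- covered | flags[, ord[k]]
    gains[k] <- sum(new_cover) - sum(covered)
    covered <- new_cover
  }
  out <- data.frame(marker = markers[ord],
                    single_pct = 100 * unname(single[ord]),
                    gain_pct = 100 * gains / sum(total),
                    stringsAsFactors = FALSE)
  structure(out, class = c("contribution_decomposition", "data.frame"),
            subset = subset, n_reactive = sum(total))
}

#' Inhibitor modulation relative to the no-inhibitor reference
#'
#' Expresses a CD137 positivity percentage under a protein-transport
#' inhibitor condition relative to the matched no-inhibitor reference:
#' `normalized = condition / reference`, and
#' `percent modulation = (normalized - 1) * 100` (e.g. -18 means an 18%
#' reduction).
#'
#' @param condition_pct Percent positive under the inhibitor condition.
#' @param reference_pct Percent positive without inhibitors (> 0).
#' @param form Which CD137 form the value refers to
#'   (`"total"`, `"surface"`, `"intracellular"`); metadata only.
#' @param inhibitor Condition label; metadata only.
#' @return Object of class `modulation_result`: data frame with `normalized`
#'   and `percent_modulation`.
#' @examples
#' inhibitor_modulation(8.2, 10)    # -18% modulation
#' @export
inhibitor_modulation <- function(condition_pct, reference_pct,
                                 form = "total", inhibitor = NA_character_) {
  if (any(reference_pct <= 0))
    stop("modulation undefined: reference percentage is zero", call. = FALSE)
  normalized <- condition_pct / reference_pct
  out <- data.frame(inhibitor = inhibitor, form = form,
                    condition_pct = condition_pct,
                    reference_pct = reference_pct,
                    normalized = normalized,
                    percent_modulation = (normalized - 1) * 100,
                    stringsAsFactors = FALSE)
  structure(out, class = c("modulation_result", "data.frame"))
}

#' Paired Wilcoxon signed-rank test across samples
#'
#' Two-sided paired Wilcoxon signed-rank test. For small samples (up to 16
#' non-zero differences) the p-value is exact, computed by enumerating the
#' null distribution of the signed-rank sum over all sign assignments, with
#' average ranks for tied magnitudes (so constant shifts are handled
#' exactly); larger samples use [stats::wilcox.test()]. Zero differences are
#' dropped; identical vectors return p = 1 by convention.
#'
#' @param values_a,values_b Matched per-sample percentages (length >= 5).
#' @return Two-sided p-value.
#' @examples
#' paired_marker_test(1:8, 1:8 + 2)   # exact 2/2^8 = 0.0078125
#' @export
paired_marker_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(values_a) < 5)
    stop("need at least 5 matched samples", call. = FALSE)
  d <- values_b - values_a
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  if (length(d) <= 16) return(exact_signed_rank_p(d))
  stats::wilcox.test(values_b, values_a, paired = TRUE, exact = FALSE)$p.value
}

## exact two-sided signed-rank p: null distribution of the rank sum over all
## 2^m sign assignments (ranks doubled so average ties stay integer),
## two-sided by symmetric deviation from the null mean
exact_signed_rank_p <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))
  total <- sum(r2)
  f <- numeric(total + 1)   # f[s + 1] = #assignments with doubled rank sum s
  f[1] <- 1
  for (r in r2) {
    g <- numeric(total + 1)
    g[(r + 1):(total + 1)] <- f[1:(total + 1 - r)]
    f <- f + g
  }
  t_obs <- sum(r2[d > 0])
  dev <- abs(t_obs - total / 2)
  s <- 0:total
  sum(f[abs(s - total / 2) >= dev - 1e-9]) / 2^length(d)
}
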
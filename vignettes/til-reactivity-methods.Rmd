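---
title: "Detecting tumor-specific reactive TILs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tumor-specific reactive TILs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilreact)
```

## The problem

Solid tumors are infiltrated by T cells of mixed provenance: some recognize
tumor antigens presented by the autologous tumor ("tumor-specific reactive"
TILs), others are bystanders. Detecting the reactive fraction matters for
immune monitoring and for selecting cells for adoptive therapy. `tilreact`
implements three coordinated read-outs of reactivity:

* protein-level, by flow cytometry after a short co-culture with autologous
  tumor cells, using CD137 (4-1BB, the protein of *TNFRSF9*), TNF, IFNγ and
  the degranulation marker CD107a;
* transcriptome-level, by paired bulk expression of the same TILs exposed to
  autologous versus allogeneic tumor cells;
* in situ, by marker-gene positivity in single-cell expression data.

## Flow model and gating

An event table carries transformed intensities for eight channels (surface
CD137, intracellular CD137, TNF, IFNγ, CD107a, CD4, CD8, viability) plus
condition labels (autologous / allogeneic / alone, crossed with the
protein-transport-inhibitor variant). Since manual gates are not
reproducible, `set_thresholds()` replaces them with a rule: the cutoff for
each activation channel is a high quantile (default **0.999**) of the
channel in the TILs-alone control, and an event is positive when its
intensity is **strictly greater** than the cutoff (an intensity exactly at
the threshold is negative). The viability and CD4/CD8 channels separate two
well-split populations, so their cutoffs are placed midway between the two
component centers (a two-center k-means on the control); CD4/CD8 gates are
mutually exclusive — double-positive and double-negative events are
excluded, and dead events are removed before any metric.

Total CD137 is the Boolean OR of the surface and intracellular calls. The
three activation definitions are unions over live subset events: CD137⁺;
Antitumor Function⁺ (≥ 1 of TNF, IFNγ, CD107a); Total Reactive (≥ 1 of all
four). Every reported percentage is background-subtracted against the
matched control and clamped: negative differences become **0.01 %**, values
above the scale become **100 %**. The floor applies after subtraction only;
raw percentages may be 0.

For polyfunctionality, events are cross-classified by (CD137, TNF, IFNγ)
into 8 combinations; the 7 non-all-negative ones are the reactive profile.
Each combination's percent of the parent is subtracted against the matched
control combination (truncated at zero) and the seven are renormalized to
fractions summing to one. Subtracting per combination (rather than only at
the union level) mirrors exporting the per-group table and subtracting its
background; a union-level alternative can be had by passing an all-negative
control. The three-way sub-grouping (CD137⁺AF⁻ / CD137⁻AF⁺ / CD137⁺AF⁺)
includes CD107a in AF.

"Order of relevance" in the marker-contribution decomposition is the
decreasing single-marker positive fraction, with the fixed panel order
(CD137, TNF, IFNγ, CD107a) breaking ties; the k-th gain is the increment in
union coverage from adding the k-th marker, expressed as a percentage of
the total reactive population, so gains are non-negative and sum to 100.

Inhibitor effects are reported as `(condition/reference − 1) × 100` percent
modulation of surface, intracellular or total CD137 relative to the
no-inhibitor condition.

Paired comparisons across samples use a two-sided Wilcoxon signed-rank
test. For up to 16 non-zero differences the p-value is exact, by
enumerating the signed-rank null over all sign assignments with average
ranks for tied magnitudes — this handles the common case of a constant shift,
where every |difference| ties, which closed-form tables refuse; larger
samples fall back to `stats::wilcox.test()`. All-zero differences return
p = 1.

## Paired bulk expression and activation gene sets

Expression is assumed log2-normalized; `normalize_log2()` offers the
default pre-step (per-sample total scaling to a common library size, then
`log2(x+1)`), which cancels in paired differences under proportional
scaling. Per gene, the per-patient LFC is `log2(autologous) −
log2(allogeneic)`; the summary is the arithmetic mean LFC and a two-sided
paired t-test on the per-patient LFC vector (equivalent to the paired test
on the log values). No multiple-testing correction is applied by default —
the selection rule is a raw p < 0.01 filter combined with an effect-size
cutoff — but a Benjamini–Hochberg flag exists.

Activation gene sets keep genes with p < 0.01 **and** mean LFC > 2 (CD8) or
> 1.4 (CD4), then drop *TNFRSF9*, *TNF* and *IFNG* by name, since those are
tracked separately as markers. Validation against an antigen-specific
reference ranks the reference by decreasing mean LFC (stable sort,
gene-name tie-break) and reports the fraction of set members within the top
K = 300 and the fraction with reference LFC > 1.

## In situ classification

Single cells are called positive for a marker gene when expression is
strictly greater than 0 (configurable); for deep-coverage Smart-seq2-like
data detection is a reasonable proxy for expression, which is why the
default cutoff is 0. Three markers give 8 combination clusters; counting
positive markers gives the Triple Negative / Single / Double / Triple
Positive grouping; *ENTPD1*/*ITGAE* give 4 clusters. Heatmap summaries are
per-gene per-cluster means, Z-scored **across clusters** (population, i.e.
n, denominator), so each row has mean 0 and SD 1 and a constant gene is an
all-zero row; empty clusters are dropped with a warning rather than
imputed. Panel scores are per-cell means of normalized expression
(per-cell total scaling + `log1p` by default) over the panel's genes,
averaged per cluster and Z-scored the same way. Panel gene lists are
user-supplied inputs.

## What the generators emulate

* **Flow** (`flow_sim_config()`): a mixture over the 16 functional classes
  (the CD137/TNF/IFNγ/CD107a combinations) per subset, with two-component
  Gaussian intensities per channel on an arcsinh-like scale (negative
  location 1.0, SD 0.35; positive location 4.0, SD 0.40 — well-separated
  components, as gated ICS markers are). Default reactive mass: 30 % (CD8)
  and 25 % (CD4), in the neighborhood of the reactive fractions seen in
  highly selected co-cultures, with CD137-only the largest single reactive
  class and CD107a contributing little marginal coverage. Controls draw all
  non-background events from the all-negative class; a spurious positive
  rate of 5·10⁻⁴ per marker models residual background. CD137⁺ events
  occupy surface/intracellular states with baseline probabilities
  0.85/0.70; inhibitors multiply these occupancies (BFA ×0.24 on surface,
  ×1.35 intracellular, etc.), so transport inhibition relocates CD137
  between compartments while total CD137 is conserved by construction —
  the qualitative behavior observed for brefeldin A and monensin. No
  per-event intensity distributions are published for this assay, so the
  two-component model is a stand-in; no acceptance check depends on its
  specific shape, only on threshold-gating behaving sensibly on it.
  Not emulated: spectral spillover/compensation, doublets, acquisition
  batch effects — passing tests say nothing about those.
* **Bulk** (`bulk_sim_config()`): patient-paired log2 matrices with a
  patient-level baseline shift, i.i.d. Gaussian noise (SD 0.5) and a spiked
  gene set with true mean LFC 3 at 12 pairs — matching the study scale of
  ~12 patients per subset. Real RNA-seq has gene-length and
  mean–variance structure this ignores; the paired design makes the
  derivation insensitive to anything that cancels within a patient.
* **Single cell** (`sc_sim_config()`): latent class per cell over the 8
  marker combinations (45 % Triple Negative by default, reflecting that
  most in situ TILs express none of the three markers), truncated-NB
  marker counts so positivity is exact before dropout, an activation-gene
  bank whose NB mean doubles per additional positive marker, *ENTPD1*
  detection tracking *TNFRSF9* (0.75 vs 0.15) and class-independent
  *ITGAE*, plus optional uniform dropout (zero-inflation). With dropout d,
  a cell with k positive markers is recovered iff none of its k marker
  counts dropped, so classifier accuracy has the closed form
  E[(1−d)^k] — a property the tests exploit. Library-size variation and
  gene–gene correlation beyond the gradient are not modeled.

Every generator consumes a single integer seed and restores the caller's
RNG state, so identical configs are bit-reproducible.

## Numerical choices and problem sizes

Fractions must sum to 1 within 1e-9; Z-score rows are checked to the same
tolerance. Ties in marker ordering and in LFC ranking break
deterministically (panel order; gene name). The test-suite problem sizes —
50,000 events × 10 seeds for combination-fraction recovery, 20 replicates
of 1,000 genes × 12 pairs for spike recovery, 2,000 null genes for t-test
calibration, 10,000 cells for the gradient — are chosen so that each check
has narrow sampling error while the whole suite runs in well under a
minute per file.

## Limitations

* Gating thresholds are a quantile rule, not learned mixtures; data whose
  control and stimulated conditions differ in background level will bias
  the subtraction.
* The FCS support is a minimal FCS 3.0 float-LIST reader/writer intended
  for interchange of the package's own tables; it does not parse vendor
  keywords, compensation matrices or integer data types.
* Combination-level background subtraction truncates at zero before
  renormalizing; when stimulation is weak relative to background the
  renormalized fractions are noisy.
* In situ positivity at "> 0" is calibrated for deep-coverage data; for
  shallow droplet data a higher cutoff (or the dropout-aware accuracy
  formula) should inform interpretation.
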
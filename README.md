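# tilreact

Quantifying **tumor-specific reactive TILs** (tumor-infiltrating
lymphocytes). Only a fraction of the T cells inside a tumor actually
recognize tumor antigens; the rest are bystanders. `tilreact` implements a
complete, reproducible version of the analysis used to detect the reactive
fraction on three levels:

1. **Flow cytometry** — after an 8-hour co-culture of TILs with autologous
   tumor cells, events are gated on viability and CD8/CD4 subset, and each
   activation channel (surface CD137, intracellular CD137, TNF, IFNγ,
   CD107a) is thresholded against the TILs-alone control. Reactivity is
   defined three ways:
   - CD137⁺ TILs: positive for total CD137 (Boolean `S-CD137 OR IC-CD137`),
   - Antitumor Function⁺ TILs: positive for ≥ 1 of TNF, IFNγ, CD107a,
   - Total Reactive TILs: positive for ≥ 1 of all four markers,

   each minus the unstimulated control, with negative differences reported
   as **0.01 %** and over-normalized values as **100 %**. Boolean gating of
   (CD137, TNF, IFNγ) yields the **7** reactive combinations (the
   all-negative group is excluded), whose background-subtracted fractions
   profile the polyfunctionality of the reactive repertoire. Inhibitor
   conditions (brefeldin A, monensin) are summarized as
   `(condition/reference − 1) × 100` percent modulation of surface,
   intracellular and total CD137.

2. **Paired bulk transcriptomics** — per patient, the log2 fold change
   (LFC) of each gene between TILs co-cultured with *autologous* vs
   *allogeneic* tumor cells; a paired t-test on the per-patient LFCs; and
   activation gene sets filtered at p < 0.01 and mean LFC > 2 (CD8) or
   > 1.4 (CD4), excluding the marker genes *TNFRSF9*, *TNF*, *IFNG*
   themselves. Gene sets are validated by the fraction of members falling
   in the top-K (default 300) most-upregulated genes of an
   antigen-specific reference.

3. **Single-cell in situ** — cells are called positive for *TNFRSF9*,
   *TNF*, *IFNG* (expression > 0) and partitioned into the 8 combination
   clusters, grouped as Triple Negative / Single / Double / Triple
   Positive by the number of positive markers; gene sets and signature
   panels are summarized as per-cluster means Z-scored across clusters.
   The same machinery handles the *ENTPD1*/*ITGAE* (CD39/CD103)
   specificity markers (4 clusters) and their 8 × 4 cross-tabulation
   against the reactivity combinations.

Synthetic-data generators with known ground truth (`flow_sim_config()`,
`bulk_sim_config()`, `sc_sim_config()`) emulate all three data types, so
every step is testable against truth labels.

## Worked example

```r
library(tilreact)

sim <- generate_flow_events(flow_sim_config(n_events = 20000, seed = 42))
thr <- set_thresholds(sim$events$alone)           # 0.999 control quantile
pos <- call_positivity(sim$events$autologous, thr)
ctl <- call_positivity(sim$events$alone, thr)

reactivity_metrics(pos, ctl, "CD8")[, c("metric", "raw_pct", "adjusted_pct")]
#>              metric raw_pct adjusted_pct
#> 1            CD137s   20.48         20.4
#> 2            CD137i   16.67         16.6
#> 3             CD137   23.03         22.9
#> 4               TNF   18.68         18.6
#> 5              IFNg   16.34         16.2
#> 6            CD107a    6.12          6.0
#> 7 AntitumorFunction   23.55         23.2
#> 8     TotalReactive   30.72         30.3

combination_profile(pos, ctl, "CD8")
#> <combination_profile> CD8: 11609 live events, 3566 reactive
#>            combo fraction
#>  CD137+TNF+IFNg+   0.3139
#>  CD137+TNF+IFNg-   0.1332
#>  CD137+TNF-IFNg+   0.0805
#>  CD137-TNF+IFNg+   0.0776
#>  CD137+TNF-IFNg-   0.2342
#>  CD137-TNF+IFNg-   0.0928
#>  CD137-TNF-IFNg+   0.0679

contribution_order(pos, "CD8")
#>   marker single_pct gain_pct
#> 1  CD137      23.03    74.99
#> 2    TNF      18.68    17.02
#> 3   IFNg      16.34     6.98
#> 4 CD107a       6.12     1.01
```

Reading: of the live CD8⁺ events, 30.3 % are reactive after background
subtraction (the generator's truth is 30 %); the seven Boolean combinations
partition those reactive cells (here 31 % are triple-positive and 23 % are
CD137-only); and CD137 alone accounts for 75 % of the reactive union, with
TNF adding 17 more points, IFNγ 7 and CD107a 1 — the marker-contribution
decomposition "summed in order of relevance".

The bulk and single-cell stages follow the same pattern; see
`?compute_paired_lfc`, `?derive_gene_set`, `?assign_clusters`,
`?cluster_geneset_heatmap`, and `run_pipeline()` for an end-to-end driver
that writes TSV outputs plus a run manifest.

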
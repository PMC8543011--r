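test_that("paired LFC is the per-patient log2 difference with a paired t-test", {
  ## log2 values (8, 6) in every one of 3 pairs -> mean LFC = 2
  bp <- tiny_bulk(auto_vals = c(8, 8, 8), allo_vals = c(6, 6, 6))
  degs <- compute_paired_lfc(bp)
  expect_equal(degs$mean_lfc, 2)
  expect_equal(degs$p_value, 1)   # zero variance across patients -> convention
  ## identical conditions -> LFC 0 and p = 1
  bp0 <- tiny_bulk(c(5, 6, 7), c(5, 6, 7))
  degs0 <- compute_paired_lfc(bp0)
  expect_equal(degs0$mean_lfc, 0)
  expect_equal(degs0$p_value, 1)
})

test_that("per-gene t statistics agree with stats::t.test on random fixtures", {
  set.seed(4)
  sim <- generate_bulk_pairs(bulk_sim_config(n_genes = 60, n_pairs = 7, seed = 4))
  degs <- compute_paired_lfc(sim$expr)
  lfc <- attr(degs, "lfc")
  for (g in sample(degs$gene, 20)) {
    ref <- t.test(lfc[g, ])
    i <- match(g, degs$gene)
    expect_equal(degs$p_value[i], ref$p.value, tolerance = 1e-12)
    expect_equal(degs$mean_lfc[i], unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("unmatched patients are reported by id", {
  bp <- tiny_bulk(c(8, 8, 8), c(6, 6, 6))
  bp$samples <- bp$samples[-4, ]   # drop P01 allogeneic
  expect_error(compute_paired_lfc(bp), "P01")
})

test_that("gene-set derivation applies both thresholds and the name exclusion", {
  degs <- structure(data.frame(
    gene = c("geneA", "geneB", "geneC", "TNF", "TNFRSF9", "IFNG", "geneD"),
    mean_lfc = c(5, 2.5, 1.5, 6, 6, 6, 3),
    p_value = c(0.02, 0.001, 0.001, 1e-6, 1e-6, 1e-6, 0.009),
    stringsAsFactors = FALSE), class = c("deg_records", "data.frame"))
  gs <- derive_gene_set(degs, "CD8")
  expect_equal(gs$genes, c("geneB", "geneD"))   # geneA fails p, geneC fails LFC
  expect_false(any(c("TNF", "TNFRSF9", "IFNG") %in% gs$genes))
  ## CD4 cutoff admits the 1.5-LFC gene
  gs4 <- derive_gene_set(degs, "CD4")
  expect_true("geneC" %in% gs4$genes)
  ## threshold monotonicity: tightening either cutoff never grows the set
  gs_tight_lfc <- derive_gene_set(degs, "CD8", lfc_cut = 2.8)
  gs_tight_p <- derive_gene_set(degs, "CD8", p_cut = 0.005)
  expect_true(all(gs_tight_lfc$genes %in% gs$genes))
  expect_true(all(gs_tight_p$genes %in% gs$genes))
})

test_that("spiked genes are recovered with controlled false positives", {
  set.seed(20)
  recov <- fpr <- numeric(5)
  for (i in 1:5) {
    spiked <- setNames(rep(3, 60), sprintf("gene%04d", 1:60))
    cfg <- bulk_sim_config(n_genes = 1200, n_pairs = 12, spiked_genes = spiked,
                           noise_sd = 0.5, seed = 100 + i)
    sim <- generate_bulk_pairs(cfg)
    gs <- derive_gene_set(compute_paired_lfc(sim$expr), "CD8")
    recov[i] <- mean(names(spiked) %in% gs$genes)
    fpr[i] <- mean(setdiff(cfg$genes, names(spiked)) %in% gs$genes)
  }
  expect_gte(mean(recov), 0.95)
  expect_lte(mean(fpr), 0.02)
})

test_that("set intersection equals a naive membership scan", {
  mk <- function(genes, subset) structure(
    list(subset = subset, genes = sort(genes), p_cut = 0.01,
         lfc_cut = 2, excluded = character(), adjusted = FALSE),
    class = "activation_gene_set")
  expect_equal(intersect_sets(mk(c("a", "b"), "CD8"), mk(c("c", "d"), "CD4")),
               character(0))
  expect_equal(intersect_sets(mk(c("a", "b"), "CD8"), mk(c("b", "a"), "CD4")),
               c("a", "b"))
  set.seed(6)
  g1 <- sample(letters, 15); g2 <- sample(letters, 15)
  naive <- sort(unique(g1[vapply(g1, function(g) any(g2 == g), logical(1))]))
  expect_equal(intersect_sets(mk(g1, "CD8"), mk(g2, "CD4")), naive)
})

test_that("top-K validation ranks by LFC with stable gene-name ties", {
  ref <- structure(data.frame(
    gene = sprintf("g%03d", 1:500),
    mean_lfc = c(10, 0, seq(5, 0.5, length.out = 399), rep(0, 99)),
    stringsAsFactors = FALSE), class = c("deg_records", "data.frame"))
  gs <- structure(list(subset = "CD8", genes = c("g001", "g002"), p_cut = .01,
                       lfc_cut = 2, excluded = character(), adjusted = FALSE),
                  class = "activation_gene_set")
  ## g001 has rank 1; g002 (LFC 0, first zero by name) lands at rank 401
  rep_ <- validate_top_k(gs, ref, K = 300)
  expect_equal(rep_$frac_in_top_k, 0.5)
  expect_equal(rep_$frac_lfc_above, 0.5)
  ## entirely inside the window
  gs_top <- structure(list(subset = "CD8", genes = "g001", p_cut = .01,
                           lfc_cut = 2, excluded = character(), adjusted = FALSE),
                      class = "activation_gene_set")
  expect_equal(validate_top_k(gs_top, ref, K = 300)$frac_in_top_k, 1)
  expect_error(validate_top_k(gs, ref, K = 501), "universe")
  ## independent sort oracle with tie-break on gene name
  set.seed(13)
  ref2 <- structure(data.frame(gene = sprintf("g%03d", 1:200),
                               mean_lfc = sample(rep(1:40, 5)),
                               stringsAsFactors = FALSE),
                    class = c("deg_records", "data.frame"))
  pick <- sort(sample(ref2$gene, 30))
  gs2 <- structure(list(subset = "CD8", genes = pick, p_cut = .01,
                        lfc_cut = 2, excluded = character(), adjusted = FALSE),
                   class = "activation_gene_set")
  ord <- ref2[order(-ref2$mean_lfc, ref2$gene), "gene"]
  oracle <- mean(match(pick, ord) <= 50)
  expect_equal(validate_top_k(gs2, ref2, K = 50)$frac_in_top_k, oracle)
})

test_that("null data yield the expected small gene sets", {
  ## pure null: expected set size ~ n_genes * P(p < .01 & LFC > 2), which is
  ## tiny for LFC > 2 under SD-0.5 noise; check the observed set is tiny
  set.seed(44)
  sizes <- vapply(1:5, function(i) {
    cfg <- bulk_sim_config(n_genes = 1500, n_pairs = 11,
                           spiked_genes = setNames(numeric(0), character(0)),
                           noise_sd = 0.5, seed = 200 + i)
    length(derive_gene_set(compute_paired_lfc(generate_bulk_pairs(cfg)$expr),
                           "CD8")$genes)
  }, numeric(1))
  expect_lte(mean(sizes), 1)
})
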
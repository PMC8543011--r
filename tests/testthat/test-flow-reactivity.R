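test_that("control-quantile thresholds bound control positivity", {
  sim <- generate_flow_events(flow_sim_config(n_events = 5000, seed = 2,
                                              background_rate = 0))
  ctl <- sim$events$alone
  thr <- set_thresholds(ctl, quantile = 0.999)
  for (ch in c("CD137s", "CD137i", "TNF", "IFNg", "CD107a"))
    expect_lte(mean(ctl[[ch]] > thr[[ch]]), 0.001)
  expect_error(set_thresholds(ctl[0, ]), "empty")
  expect_error(set_thresholds(ctl, quantile = 0.4), "quantile")
})

test_that("positivity calls use strict inequality and the CD137 OR rule", {
  thr <- structure(setNames(rep(1, 8),
                            c("CD137s","CD137i","TNF","IFNg","CD107a",
                              "CD4","CD8","viability")),
                   class = "gate_thresholds")
  ev <- data.frame(event_id = 1:4, sample_id = "s", condition = "autologous",
                   inhibitor = "none",
                   CD137s = c(1.0, 2, 0, 0),   # exactly at threshold -> negative
                   CD137i = c(0, 0, 2, 0),
                   TNF = c(0, 0, 0, 0), IFNg = 0, CD107a = 0,
                   CD4 = 0, CD8 = 2, viability = 2)
  pos <- call_positivity(ev, thr)
  expect_equal(pos$CD137s, c(FALSE, TRUE, FALSE, FALSE))
  ## T-CD137 is the element-wise OR of surface and intracellular calls
  expect_equal(pos$CD137, pos$CD137s | pos$CD137i)
  expect_equal(pos$CD137, c(FALSE, TRUE, TRUE, FALSE))
  ## all-zero intensities give an all-negative row
  expect_false(any(unlist(pos[4, c("CD137s","CD137i","TNF","IFNg","CD107a")])))
  ## missing channel is named
  expect_error(call_positivity(ev[, -5], thr), "CD137s")
})

test_that("background subtraction applies the 0.01/100 clamps", {
  expect_equal(subtract_background(3.0, 1.0), 2.0)
  expect_equal(subtract_background(1.0, 3.0), 0.01)
  expect_equal(clamp_percent(104.0), 100.0)
  expect_equal(subtract_background(c(3, 1), c(1, 3)), c(2, 0.01))
  expect_error(subtract_background(101, 0), "0, 100")
  expect_error(subtract_background(50, -1), "0, 100")
})

test_that("reactivity metrics follow the three union definitions", {
  f <- rep(FALSE, 100)
  only107 <- f; only107[1:10] <- TRUE
  pos <- make_pos(f, f, f, f, only107)
  res <- reactivity_metrics(pos, null_pos(50))
  get <- function(m) res$adjusted_pct[res$metric == m]
  expect_equal(get("AntitumorFunction"), 10)
  expect_equal(get("TotalReactive"), 10)
  expect_equal(get("CD137"), 0.01)     # floor: nothing above control
  ## all markers positive with a clean control -> every metric 100
  t_ <- rep(TRUE, 40)
  res2 <- reactivity_metrics(make_pos(t_, t_, t_, t_, t_), null_pos(40))
  expect_true(all(res2$adjusted_pct == 100))
  expect_error(reactivity_metrics(pos, null_pos(50), "CD4"), "CD4")
})

test_that("union metrics are monotone and clamped", {
  set.seed(31)
  for (i in 1:10) {
    pos <- random_pos(400)
    res <- reactivity_metrics(pos, null_pos(200))
    raw <- setNames(res$raw_pct, res$metric)
    expect_gte(raw[["TotalReactive"]], raw[["AntitumorFunction"]])
    for (m in c("TNF", "IFNg", "CD107a"))
      expect_gte(raw[["AntitumorFunction"]], raw[[m]])
    expect_gte(raw[["TotalReactive"]], raw[["CD137"]])
    expect_true(all(res$adjusted_pct >= 0.01 & res$adjusted_pct <= 100))
  }
})

test_that("combination profile matches the per-event oracle and partitions", {
  set.seed(17)
  pos <- random_pos(10000)
  ctl <- null_pos(5000)
  prof <- combination_profile(pos, ctl)
  counts <- oracle_combo_counts(pos)
  labels7 <- prof$combos$combo
  expect_equal(prof$combos$stim_pct, 100 * as.vector(counts[labels7]) / nrow(pos))
  ## 8 combination counts partition the live events exactly
  expect_equal(sum(counts), nrow(pos))
  expect_equal(sum(prof$combos$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(prof$grouping$fraction), 1, tolerance = 1e-9)
})

test_that("combination profile handles degenerate and uniform mixtures", {
  f <- rep(FALSE, 60); t_ <- !f
  ## every reactive event CD137+TNF-IFNg-
  prof <- combination_profile(make_pos(t_, f, f, f, f), null_pos(30))
  expect_equal(prof$combos$fraction[prof$combos$combo == "CD137+TNF-IFNg-"], 1)
  expect_equal(sum(prof$combos$fraction), 1)
  ## uniform over the 7 reactive combinations
  labels7 <- setdiff(combo_labels(c("CD137","TNF","IFNg")), "CD137-TNF-IFNg-")
  per <- 70
  flags <- do.call(rbind, lapply(labels7, function(l)
    matrix(parse_combo(l, c("CD137","TNF","IFNg")), per, 3, byrow = TRUE)))
  pos <- make_pos(flags[, 1], rep(FALSE, nrow(flags)), flags[, 2], flags[, 3],
                  rep(FALSE, nrow(flags)))
  prof2 <- combination_profile(pos, null_pos(100))
  expect_equal(prof2$combos$fraction, rep(1 / 7, 7), tolerance = 1e-9)
})

test_that("marker contribution equals exhaustive inclusion-exclusion", {
  ## disjoint sets of sizes 40/30/20/10 -> gains are the set sizes
  n <- 100
  mk <- function(from, len) { x <- rep(FALSE, n); x[from:(from + len - 1)] <- TRUE; x }
  pos <- make_pos(mk(1, 40), rep(FALSE, n), mk(41, 30), mk(71, 20), mk(91, 10))
  con <- contribution_order(pos)
  expect_equal(con$marker, c("CD137", "TNF", "IFNg", "CD107a"))
  expect_equal(con$gain_pct, c(40, 30, 20, 10))
  ## nested sets: first marker covers everything
  pos2 <- make_pos(mk(1, 40), rep(FALSE, n), mk(1, 30), mk(1, 20), mk(1, 10))
  expect_equal(contribution_order(pos2)$gain_pct, c(100, 0, 0, 0))
  ## random events: greedy gains reproduce brute-force union sizes
  set.seed(23)
  for (rep_i in 1:5) {
    pos3 <- random_pos(500)
    con3 <- contribution_order(pos3)
    flags <- as.matrix(pos3[, c("CD137", "TNF", "IFNg", "CD107a")])
    total <- oracle_union_size(flags, colnames(flags))
    for (k in seq_len(4)) {
      gain_oracle <- oracle_union_size(flags, con3$marker[1:k]) -
        oracle_union_size(flags, con3$marker[seq_len(k - 1)])
      expect_equal(con3$gain_pct[k], 100 * gain_oracle / total)
    }
    expect_true(all(con3$gain_pct >= 0))
    expect_equal(sum(con3$gain_pct), 100)
  }
})

test_that("inhibitor modulation is the normalized ratio minus one", {
  expect_equal(inhibitor_modulation(10, 10)$percent_modulation, 0)
  expect_equal(inhibitor_modulation(8.2, 10)$percent_modulation, -18)
  expect_equal(inhibitor_modulation(20.9, 10)$percent_modulation, 109)
  expect_error(inhibitor_modulation(5, 0), "reference")
})

test_that("occupancy shifts relocate CD137 without losing total signal", {
  cfg <- flow_sim_config(n_events = 30000, seed = 12)
  sim <- generate_flow_events(cfg, conditions = c("autologous", "alone"),
                              inhibitors = c("none", "BFA"))
  thr <- set_thresholds(sim$events$alone)
  metr <- function(key) {
    pos <- call_positivity(sim$events[[key]], thr)
    ctl_key <- if (grepl("BFA", key)) "alone.BFA" else "alone"
    ctl <- call_positivity(sim$events[[ctl_key]], thr)
    r <- reactivity_metrics(pos, ctl, "CD8")
    setNames(r$adjusted_pct, r$metric)
  }
  ref <- metr("autologous"); bfa <- metr("autologous.BFA")
  mod_total <- inhibitor_modulation(bfa[["CD137"]], ref[["CD137"]])$percent_modulation
  mod_surface <- inhibitor_modulation(bfa[["CD137s"]], ref[["CD137s"]])$percent_modulation
  mod_ic <- inhibitor_modulation(bfa[["CD137i"]], ref[["CD137i"]])$percent_modulation
  expect_lt(abs(mod_total), 10)    # total conserved
  expect_lt(mod_surface, -50)      # surface depleted
  expect_gt(mod_ic, 10)            # intracellular enriched
})

test_that("paired Wilcoxon is exact for small samples and matches stats", {
  expect_equal(paired_marker_test(1:8, 1:8 + 5), 2 / 2^8)
  expect_equal(paired_marker_test(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 1)
  expect_error(paired_marker_test(1:3, 1:3), "at least 5")
  set.seed(99)
  for (i in 1:100) {
    a <- rnorm(12); b <- a + rnorm(12, 0.3)
    expect_equal(paired_marker_test(a, b),
                 wilcox.test(b, a, paired = TRUE, exact = TRUE)$p.value)
  }
})
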
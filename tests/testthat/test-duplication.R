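# Ks spectra, age calibration, event assignment, duplicate-class
# enrichment, syntelog motif conservation and Ka:Ks flags.

test_that("wilcoxon_greater matches exact enumeration on tied tiny groups", {
  out <- wilcoxon_greater(c(3, 4, 5), c(1, 1, 2))
  expect_equal(out$method, "exact enumeration")
  expect_equal(out$p_value, oracle_wilcoxon_greater(c(3, 4, 5), c(1, 1, 2)),
               tolerance = 1e-12)
  # identical groups: no shift, p >= 0.5
  same <- wilcoxon_greater(c(2, 2, 3), c(2, 2, 3))
  expect_gte(same$p_value, 0.5)
})

test_that("wilcoxon_greater equals the enumeration oracle for sizes <= 8", {
  withr::with_seed(61, {
    for (i in 1:50) {
      nx <- sample(2:8, 1); ny <- sample(2:8, 1)
      x <- sample(0:6, nx, replace = TRUE)
      y <- sample(0:6, ny, replace = TRUE)
      expect_equal(wilcoxon_greater(x, y)$p_value,
                   oracle_wilcoxon_greater(x, y), tolerance = 1e-12)
    }
  })
})

test_that("the tie-free exact path agrees with wilcox.test", {
  withr::with_seed(62, {
    for (i in 1:20) {
      x <- rnorm(15); y <- rnorm(12)
      ours <- wilcoxon_greater(x, y)
      expect_equal(ours$method, "exact distribution")
      ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(unname(ours$statistic), unname(ref$statistic))
    }
  })
})

test_that("the large-sample path applies tie and continuity corrections", {
  withr::with_seed(63, {
    x <- round(rnorm(40, 5.4, 1)); y <- round(rnorm(40, 5, 1))
  })
  ours <- wilcoxon_greater(x, y)
  expect_equal(ours$method, "normal approximation")
  ref <- wilcox.test(x, y, alternative = "greater", exact = FALSE,
                     correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("ks_peaks finds mixture components within tolerance", {
  cfg1 <- simulation_config(
    n_pairs = 500, seed = 64,
    ks_mixture = tibble(mean = 0.3, sd = 0.05, weight = 1, event = "e"))
  sp1 <- ks_peaks(simulate_syntelogs(cfg1))
  expect_equal(nrow(sp1$peaks), 1)
  expect_equal(sp1$peaks$position, 0.3, tolerance = 0.03)
  cfg2 <- simulation_config(
    n_pairs = 1000, seed = 65,
    ks_mixture = tibble(mean = c(0, 0.45), sd = 0.05, weight = c(0.5, 0.5),
                        event = c("young", "old")))
  sp2 <- ks_peaks(simulate_syntelogs(cfg2))
  expect_equal(nrow(sp2$peaks), 2)
  expect_equal(sp2$peaks$position, c(0, 0.45), tolerance = 0.05)
  # prominence filter monotonicity
  all_peaks <- ks_peaks(simulate_syntelogs(cfg2), min_prominence = 0)
  expect_gte(nrow(all_peaks$peaks), nrow(sp2$peaks))
  # degenerate: identical Ks
  deg <- ks_peaks(tibble(Ks = rep(2, 60)))
  expect_true(deg$degenerate)
  expect_equal(deg$peaks$position, log10(2))
})

test_that("age calibration is linear in Ks with the gamma anchor", {
  sp <- structure(list(peaks = tibble(position = log10(c(1, 0.5, 2)),
                                      height = c(3, 2, 1),
                                      prominence = c(3, 2, 1)) %>%
                         arrange(position)),
                  class = "woodnet_ks_spectrum")
  ages <- calibrate_ages(sp, anchor_peak = log10(1), anchor_age_ma = 125)
  expect_equal(ages$age_ma[ages$position == log10(1)], 125)
  expect_equal(ages$age_ma[ages$position == log10(0.5)], 62.5)
  expect_equal(ages$age_ma[ages$position == log10(2)], 250)
  # anchoring at the printed gamma position scales the same way
  sp2 <- structure(list(peaks = tibble(position = c(0.01283722,
                                                    0.01283722 + log10(2)),
                                       height = c(2, 1),
                                       prominence = c(2, 1))),
                   class = "woodnet_ks_spectrum")
  ages2 <- calibrate_ages(sp2, anchor_peak = 1)
  expect_equal(ages2$age_ma, c(125, 250))
})

test_that("event assignment uses the window and the older-peak tie rule", {
  sp <- structure(list(peaks = tibble(position = c(0, 0.4),
                                      height = c(2, 2),
                                      prominence = c(2, 2))),
                  class = "woodnet_ks_spectrum")
  pairs <- tibble(Ks = 10^c(0, 0.2, 0.39, 0.8))
  out <- assign_events(pairs, sp, window_log10 = 0.25,
                       event_names = c("young", "old"))
  # 0.2 is equidistant between the peaks: the older one wins the tie
  expect_equal(out$event, c("young", "old", "old", NA))
  # two-component recovery: >= 90% of pairs land on their own component
  cfg <- simulation_config(
    n_pairs = 1000, seed = 66,
    ks_mixture = tibble(mean = c(0, 0.45), sd = c(0.05, 0.05),
                        weight = c(0.5, 0.5), event = c("young", "old")))
  pairs2 <- simulate_syntelogs(cfg)
  sp2 <- ks_peaks(pairs2)
  lab <- assign_events(pairs2, sp2, event_names = c("young", "old"))
  ok <- !is.na(lab$event)
  expect_gte(mean(lab$event[ok] == pairs2$event[ok]), 0.9)
})

test_that("duplicate-class enrichment matches the hypergeometric tail", {
  genes <- paste0("g", 1:500)
  clusters <- tibble(gene = genes,
                     cluster = rep(1:10, each = 50))
  # cluster 1 holds all and only the WGM genes
  pairs <- tibble(gene_a = genes[1:25], gene_b = genes[26:50],
                  duplicate_class = "WGM")
  out <- duplicate_class_enrichment(clusters, pairs)
  expect_lt(out$p_value[out$cluster == 1], 1e-6)
  expect_equal(out$p_value[out$cluster == 1],
               oracle_fisher_greater(50, 0, 0, 450), tolerance = 1e-12)
  expect_true(all(out$p_value[out$cluster != 1] == 1))
  # an empty class never fires
  none <- duplicate_class_enrichment(clusters, pairs,
                                     class_of_interest = "tandem")
  expect_true(all(none$p_value == 1))
})

test_that("null duplicate labels keep the type-I rate near nominal", {
  withr::with_seed(67, {
    hits <- 0; total <- 0
    for (i in 1:50) {
      genes <- paste0("g", 1:300)
      clusters <- tibble(gene = genes, cluster = rep(1:6, each = 50))
      dup <- sample(genes, 60)
      pairs <- tibble(gene_a = dup[1:30], gene_b = dup[31:60],
                      duplicate_class = "WGM")
      out <- duplicate_class_enrichment(clusters, pairs)
      hits <- hits + sum(out$significant)
      total <- total + nrow(out)
    }
  })
  expect_lte(hits / total, 0.07)
})

test_that("syntelog motif conservation counts shared motifs and tests groups", {
  genes <- paste0("g", 1:8)
  presence <- tibble(gene = genes,
                     M1 = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
                     M2 = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
  clusters <- tibble(gene = genes,
                     cluster = c(1L, 1L, 1L, 2L, 2L, 2L, NA, NA))
  pairs <- tibble(gene_a = c("g1", "g3", "g5", "g7"),
                  gene_b = c("g2", "g5", "g6", "g8"))
  out <- syntelog_motif_conservation(pairs, presence, clusters)
  expect_equal(out$per_pair$conserved_motifs, c(2, 1, 1, 0))
  expect_equal(out$per_pair$group,
               c("same_cluster", "different_cluster", "same_cluster",
                 "unclustered"))
  expect_equal(nrow(out$tests), 2)
  expect_equal(out$tests$comparison,
               c("same_vs_different_cluster", "same_vs_unclustered"))
  # empty comparison groups: skipped with warnings
  warns <- capture_warnings(
    out2 <- syntelog_motif_conservation(pairs[c(1, 3), ], presence, clusters))
  expect_true(any(grepl("n = 0", warns)))
  expect_true(all(is.na(out2$tests$p_value)))
})

test_that("a planted same-cluster shift is detected by the one-sided test", {
  cfg <- simulation_config(n_pairs = 200, syntelog_shift = 2, seed = 68)
  pairs <- simulate_syntelogs(cfg, motif_counts = TRUE)
  same <- pairs$conserved_motifs[pairs$group == "same_cluster"]
  diff_ <- pairs$conserved_motifs[pairs$group == "different_cluster"]
  expect_lt(wilcoxon_greater(same, diff_)$p_value, 0.01)
})

test_that("ka_ks flags ratios above one and summarizes Ka by group", {
  pairs <- tibble(gene_a = c("a", "b", "c"), gene_b = c("d", "e", "f"),
                  Ks = c(0.4, 0.5, 0), Ka = c(0.5, 0, 0.3))
  clusters <- tibble(gene = c("a", "d", "b", "e", "c", "f"),
                     cluster = c(1L, 1L, 1L, 2L, NA, NA))
  out <- ka_ks_flags(pairs, clusters)
  expect_equal(out$n_zero_ks, 1)
  expect_equal(out$pairs$flagged, c(TRUE, FALSE))
  expect_equal(out$pairs$ka_ks[1], 1.25)
  same_mean <- out$summary$mean_ka[out$summary$group == "same_cluster"]
  expect_equal(same_mean, 0.5)
})
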
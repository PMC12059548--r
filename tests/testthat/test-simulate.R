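# Synthetic-data generator: determinism, zero-noise limits, and the
# generative contracts every downstream recovery test relies on.

test_that("config validation names the offending field", {
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(replicates_per_fraction = 0),
               "replicates_per_fraction")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(conservation_fraction = 1.5),
               "conservation_fraction")
  expect_error(simulation_config(
    ks_mixture = tibble(mean = 0, sd = -1, weight = 1, event = "x")), "sd")
  expect_error(simulation_config(
    ks_mixture = tibble(mean = 0, sd = 1, weight = 0.5, event = "x")),
    "sum to 1")
})

test_that("same seed gives bit-identical outputs across all generators", {
  cfg <- simulation_config(n_genes = 80, n_interactions = 6, seed = 3)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr, b$expr)
  pa <- simulate_promoters(cfg, a$truth)
  pb <- simulate_promoters(cfg, b$truth)
  expect_identical(pa$promoters, pb$promoters)
  sa <- simulate_second_species(cfg, pa$truth, pa$pwms)
  sb <- simulate_second_species(cfg, pb$truth, pb$pwms)
  expect_identical(sa$expr2, sb$expr2)
  expect_identical(sa$promoters2, sb$promoters2)
  expect_identical(simulate_syntelogs(cfg), simulate_syntelogs(cfg))
  expect_identical(simulate_trait(cfg, a$truth), simulate_trait(cfg, a$truth))
})

test_that("zero noise makes assigned genes exact multiples of the profile", {
  cfg <- simulation_config(n_genes = 120, n_modules = 3, noise_sd = 0,
                           noise_gene_fraction = 0, n_interactions = 4,
                           seed = 5)
  sim <- simulate_expression(cfg)
  avg <- average_replicates(sim$expr, sim$samples)
  m <- log2(as.matrix(avg[-1]) + 1)
  rownames(m) <- avg$gene
  mod <- sim$truth$module_of_gene
  for (g in sample(mod$gene, 20)) {
    k <- mod$module[mod$gene == g]
    expect_gt(cor(m[g, ], sim$truth$profiles[k, ]), 1 - 1e-10)
  }
})

test_that("planted regulator-target pairs stay tightly correlated", {
  # 50 replicates per fraction tighten the fraction means; the generative
  # contract asks mean r >= 0.9 at noise_sd 0.25
  cfg <- simulation_config(n_genes = 150, replicates_per_fraction = 50,
                           n_interactions = 10, seed = 11)
  sim <- simulate_expression(cfg)
  avg <- average_replicates(sim$expr, sim$samples)
  m <- log2(as.matrix(avg[-1]) + 1)
  rownames(m) <- avg$gene
  ints <- sim$truth$planted_interactions
  rs <- mapply(function(a, b) cor(m[a, ], m[b, ]), ints$tf, ints$target)
  expect_gte(mean(rs), 0.9)
})

test_that("promoter planting is recorded and exclusive when the null rate is 0", {
  cfg <- simulation_config(n_genes = 40, n_tfs = 1, n_interactions = 1,
                           planted_hit_rate_null = 0, seed = 13)
  sim <- simulate_expression(cfg)
  pro <- simulate_promoters(cfg, sim$truth, instance_mode = "consensus")
  pos <- pro$truth$planted_motif_positions
  expect_equal(nrow(pos), 1)
  target <- sim$truth$planted_interactions$target[1]
  expect_equal(pos$gene, target)
  # the planted consensus string sits at the recorded coordinate
  pwm <- pro$pwms[[pos$motif]]
  cons <- woodnet:::sample_pwm_instance(pwm, "consensus")
  ins <- if (pos$strand == "-") woodnet:::reverse_complement_chr(cons) else cons
  seq <- pro$promoters$sequence[pro$promoters$gene == target]
  expect_equal(substr(seq, pos$offset + 1, pos$offset + nchar(cons)), ins)
  # and scanning recovers exactly that site
  hits <- scan_pwm(pro$promoters, pwm, p_threshold = 1e-4)
  planted_hit <- hits %>% filter(gene == target, offset == pos$offset,
                                 strand == pos$strand)
  expect_equal(nrow(planted_hit), 1)
})

test_that("background composition follows the GC parameter", {
  cfg <- simulation_config(n_genes = 200, n_interactions = 0, n_tfs = 1,
                           planted_hit_rate_null = 0, gc = 0.5, seed = 17)
  sim <- simulate_expression(cfg)
  pro <- simulate_promoters(cfg, sim$truth)
  chars <- strsplit(paste(pro$promoters$sequence, collapse = ""), "")[[1]]
  gc <- mean(chars %in% c("G", "C"))
  expect_gt(gc, 0.47)
  expect_lt(gc, 0.53)
})

test_that("motif longer than promoter is rejected", {
  cfg <- simulation_config(n_genes = 20, promoter_length = 30,
                           motif_length = 12, n_interactions = 2, seed = 1)
  sim <- simulate_expression(cfg)
  long_pwm <- random_pwm("MX", 40, seed = 1)
  pwms <- simulate_pwms(cfg)
  pwms[[1]] <- long_pwm
  pwms[[1]]$id <- cfg$motif_ids[1]
  expect_error(simulate_promoters(cfg, sim$truth, pwms = pwms), "longer")
})

test_that("second species honors the planted conservation fraction limits", {
  base <- list(n_genes = 120, n_tfs = 2, n_interactions = 10, seed = 19,
               noise_sd = 0)
  # all conserved: every interaction's ortholog pair keeps r and motif
  cfg1 <- do.call(simulation_config, c(base, conservation_fraction = 1))
  sim <- simulate_expression(cfg1)
  pro <- simulate_promoters(cfg1, sim$truth)
  sp2 <- simulate_second_species(cfg1, pro$truth, pro$pwms)
  avg2 <- average_replicates(sp2$expr2, sp2$samples2)
  hits2 <- scan_pwms(sp2$promoters2, pro$pwms, p_threshold = 1e-5)
  pres2 <- presence_matrix(hits2, sp2$promoters2$gene, names(pro$pwms))
  rep1 <- conservation_fraction(sim$truth$planted_interactions,
                                sp2$orthogroups, avg2, pres2)
  expect_equal(glance(rep1)$fraction_conserved, 1.0)
  # none conserved, motif-removal mode: motif-required conservation is 0
  cfg0 <- do.call(simulation_config, c(base, conservation_fraction = 0))
  sim0 <- simulate_expression(cfg0)
  pro0 <- simulate_promoters(cfg0, sim0$truth)
  sp0 <- simulate_second_species(cfg0, pro0$truth, pro0$pwms)
  avg0 <- average_replicates(sp0$expr2, sp0$samples2)
  hits0 <- scan_pwms(sp0$promoters2, pro0$pwms, p_threshold = 1e-5)
  pres0 <- presence_matrix(hits0, sp0$promoters2$gene, names(pro0$pwms))
  rep0 <- conservation_fraction(sim0$truth$planted_interactions,
                                sp0$orthogroups, avg0, pres0)
  expect_equal(glance(rep0)$fraction_conserved, 0.0)
})

test_that("syntelog Ks follows the mixture and omega scales Ka", {
  cfg <- simulation_config(
    n_pairs = 500, seed = 23,
    ks_mixture = tibble(mean = 0.3, sd = 0.05, weight = 1, event = "e"))
  pairs <- simulate_syntelogs(cfg)
  expect_equal(mean(log10(pairs$Ks)), 0.3, tolerance = 0.01)
  # omega fixed at 1.5 flags every pair downstream
  cfg2 <- simulation_config(n_pairs = 100, seed = 29,
                            omega_meanlog = log(1.5), omega_sdlog = 0)
  flags <- ka_ks_flags(simulate_syntelogs(cfg2))
  expect_true(all(flags$pairs$flagged))
})

test_that("trait with zero noise matches the driver module eigengene", {
  cfg <- simulation_config(n_genes = 120, trait_noise = 0, noise_sd = 0,
                           n_interactions = 6, seed = 31)
  sim <- simulate_expression(cfg)
  trait <- simulate_trait(cfg, sim$truth)
  avg <- average_replicates(sim$expr, sim$samples)
  norm <- zscore_norm(avg)
  members <- sim$truth$module_of_gene %>%
    filter(module == sim$truth$trait_driver_module)
  eg <- module_eigengene(norm, members$gene)
  expect_equal(abs(cor(trait$value, eg$eigengene)), 1, tolerance = 1e-6)
  expect_error(simulate_trait(cfg, sim$truth, driver_module = 99),
               "unknown module")
})

test_that("every planted interaction is recoverable in principle", {
  cfg <- simulation_config(n_genes = 100, n_interactions = 8, seed = 37,
                           noise_sd = 0)
  sim <- simulate_expression(cfg)
  pro <- simulate_promoters(cfg, sim$truth)
  pos <- pro$truth$planted_motif_positions %>% filter(kind == "planted")
  ints <- sim$truth$planted_interactions
  # target promoter carries the motif...
  expect_true(all(paste(ints$target, ints$motif) %in%
                    paste(pos$gene, pos$motif)))
  # ... and the noiseless correlation is 1
  avg <- average_replicates(sim$expr, sim$samples)
  m <- log2(as.matrix(avg[-1]) + 1); rownames(m) <- avg$gene
  rs <- mapply(function(a, b) cor(m[a, ], m[b, ]), ints$tf, ints$target)
  expect_true(all(rs > 1 - 1e-10))
})
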
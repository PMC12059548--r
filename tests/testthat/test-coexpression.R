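# Tight consensus clustering, soft power, TOM, modules and eigengenes.

test_that("zero-noise planted modules are recovered exactly", {
  cfg <- simulation_config(n_genes = 90, n_modules = 3, noise_sd = 0,
                           noise_gene_fraction = 0, n_interactions = 3,
                           seed = 2)
  sim <- simulate_expression(cfg)
  norm <- zscore_norm(average_replicates(sim$expr, sim$samples))
  tc <- tight_clusters(norm)
  truth <- sim$truth$module_of_gene
  j <- truth %>% left_join(tc, by = "gene")
  expect_equal(length(unique(na.omit(j$cluster))), 3)
  expect_equal(adjusted_rand_index(j$module, j$cluster), 1)
})

test_that("tightness loosens clustering monotonically and rejects noise", {
  sc <- small_scenario(seed = 1)
  tc_tight <- tight_clusters(sc$norm, t = 0.5)
  tc_loose <- tight_clusters(sc$norm, t = 1.0)
  expect_gte(sum(is.na(tc_tight$cluster)), sum(is.na(tc_loose$cluster)))
  truth <- sc$sim$truth$module_of_gene
  j <- truth %>% filter(gene %in% sc$norm$gene) %>%
    left_join(tc_loose, by = "gene")
  noise <- j %>% filter(is.na(module))
  expect_gte(mean(is.na(noise$cluster)), 0.8)
  expect_error(tight_clusters(sc$norm, t = -1), "t")
})

test_that("tight clustering is invariant to gene order", {
  sc <- small_scenario(seed = 1)
  tc <- tight_clusters(sc$norm)
  perm <- withr::with_seed(9, sample(nrow(sc$norm)))
  tc_perm <- tight_clusters(sc$norm[perm, ])
  j <- tc %>% inner_join(tc_perm, by = "gene", suffix = c("", "_perm"))
  expect_equal(adjusted_rand_index(j$cluster, j$cluster_perm), 1)
})

test_that("signed adjacency endpoints and the TOM triple-loop oracle", {
  # perfectly correlated pair: a = 1; anti-correlated: a = 0
  x <- tibble(gene = c("a", "b", "c"),
              F1 = c(1, 2, -1), F2 = c(2, 4, -2), F3 = c(3, 6, -3))
  net <- signed_tom(x, beta = 6)
  expect_equal(net$adjacency["a", "b"], 1)
  expect_equal(net$adjacency["a", "c"], 0)
  # random 12-gene instance against an independent triple loop
  withr::with_seed(4, m <- matrix(rnorm(12 * 8), 12, 8,
                                  dimnames = list(paste0("g", 1:12),
                                                  paste0("F", 1:8))))
  xt <- as_tibble(m) %>% mutate(gene = rownames(m)) %>%
    select(gene, dplyr::everything())
  net2 <- signed_tom(xt, beta = 10)
  a <- ((1 + cor(t(m))) / 2)^10
  diag(a) <- 1
  k <- rowSums(a) - 1
  tom_oracle <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    if (i == j) { tom_oracle[i, j] <- 1; next }
    s <- 0
    for (u in 1:12) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tom_oracle[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  expect_lt(max(abs(unname(net2$tom) - tom_oracle)), 1e-12)
  expect_lt(max(abs(net2$tom - t(net2$tom))), 1e-12)
  expect_true(all(net2$tom >= 0 & net2$tom <= 1 + 1e-12))
  expect_error(signed_tom(xt, beta = 0), "beta")
})

test_that("TOM reaches 1 exactly for identical binary neighborhoods", {
  # a and b identical (a_ab = 1); c and d exactly anti-correlated with them
  # (signed adjacency 0), so the shared neighborhood is binary
  x <- tibble(gene = c("a", "b", "c", "d"),
              F1 = c(1, 1, 4, 4), F2 = c(2, 2, 3, 3), F3 = c(3, 3, 2, 2),
              F4 = c(4, 4, 1, 1))
  net <- signed_tom(x, beta = 4)
  expect_equal(net$tom["a", "b"], 1)
  expect_lt(net$tom["a", "c"], 1)
})

test_that("wgcna_modules splits block structure and merges monotonically", {
  # two blocks of perfect within-block TOM: emulate with two module profiles
  cfg <- simulation_config(n_genes = 80, n_modules = 2, noise_sd = 0,
                           noise_gene_fraction = 0, n_interactions = 2,
                           seed = 6)
  sim <- simulate_expression(cfg)
  norm <- zscore_norm(average_replicates(sim$expr, sim$samples))
  net <- signed_tom(norm, 10)
  wm <- wgcna_modules(net, min_module_size = 10)
  expect_equal(length(unique(na.omit(wm$cluster))), 2)
  truth <- sim$truth$module_of_gene
  j <- truth %>% left_join(wm, by = "gene")
  expect_equal(adjusted_rand_index(j$module, j$cluster), 1)
  # raising the cut height can only merge
  sc <- small_scenario(seed = 1)
  net2 <- signed_tom(sc$norm, 10)
  n_low <- length(unique(na.omit(wgcna_modules(net2, 0.5)$cluster)))
  n_high <- length(unique(na.omit(wgcna_modules(net2, 0.9)$cluster)))
  expect_lte(n_high, n_low)
})

test_that("planted modules are recovered by the signed network path", {
  cfg <- simulation_config(n_genes = 300, n_modules = 4, seed = 8,
                           n_interactions = 4)
  sim <- simulate_expression(cfg)
  norm <- clust_normalize(filter_flat_genes(
    average_replicates(sim$expr, sim$samples))$kept)
  wm <- wgcna_modules(signed_tom(norm, 10))
  truth <- sim$truth$module_of_gene %>% filter(gene %in% norm$gene)
  j <- truth %>% left_join(wm, by = "gene")
  keep <- !is.na(j$module)
  expect_gte(adjusted_rand_index(j$module[keep], j$cluster[keep]), 0.8)
})

test_that("pick_soft_power degenerates and is order-invariant", {
  sc <- small_scenario(seed = 1)
  norm_small <- sc$norm[1:80, ]
  expect_equal(as.numeric(pick_soft_power(norm_small, powers = 1)), 1)
  b1 <- pick_soft_power(norm_small, powers = c(2, 6, 10))
  perm <- withr::with_seed(3, sample(nrow(norm_small)))
  b2 <- pick_soft_power(norm_small[perm, ], powers = c(2, 6, 10))
  expect_equal(as.numeric(b1), as.numeric(b2))
  expect_error(pick_soft_power(sc$norm[1:3, ]), ">= 4")
})

test_that("a hub-dominated expression design yields a scale-free fit", {
  # heavy-tailed hub attachment: gene i follows the hub profile with weight
  # w_i from a long-tailed law, the rest is noise
  withr::with_seed(10, {
    nf <- 10; n <- 400
    hub <- rnorm(nf)
    w <- runif(n)^2
    m <- t(vapply(seq_len(n), function(i) {
      w[i] * hub + sqrt(1 - w[i]^2) * rnorm(nf)
    }, numeric(nf)))
  })
  rownames(m) <- paste0("g", seq_len(n)); colnames(m) <- paste0("F", 1:nf)
  x <- as_tibble(m) %>% mutate(gene = rownames(m)) %>%
    select(gene, dplyr::everything())
  beta <- pick_soft_power(x, powers = c(2, 4, 6, 8, 10, 12))
  fit <- attr(beta, "fit_table")
  expect_gte(fit$r_squared[fit$power == as.numeric(beta)], 0.8)
})

test_that("eigengenes track the module profile with the right sign", {
  # two identical genes: eigengene proportional to their shared profile
  x <- tibble(gene = c("a", "b"), F1 = c(1, 1), F2 = c(3, 3), F3 = c(2, 2))
  eg <- module_eigengene(x, c("a", "b"))
  expect_equal(abs(cor(eg$eigengene, c(1, 3, 2))), 1, tolerance = 1e-12)
  # sign convention: positive correlation with the member mean, always
  withr::with_seed(12, {
    for (i in 1:100) {
      mm <- matrix(rnorm(6 * 5), 6, 5,
                   dimnames = list(paste0("g", 1:6), paste0("F", 1:5)))
      xt <- as_tibble(mm) %>% mutate(gene = rownames(mm)) %>%
        select(gene, dplyr::everything())
      eg_i <- module_eigengene(xt, rownames(mm))
      mean_profile <- colMeans(mm - rowMeans(mm))
      expect_gt(cor(eg_i$eigengene, mean_profile), 0)
    }
  })
  expect_error(module_eigengene(x, "a"), ">= 2")
  flat <- tibble(gene = c("a", "b"), F1 = c(1, 2), F2 = c(1, 2), F3 = c(1, 2))
  expect_error(module_eigengene(flat, c("a", "b")), "flat")
})

test_that("planted-module eigengene is faithful at study noise", {
  sc <- small_scenario(seed = 1)
  truth <- sc$sim$truth$module_of_gene
  members <- truth$gene[!is.na(truth$module) & truth$module == 2]
  eg <- module_eigengene(sc$norm, members)
  expect_gte(abs(cor(eg$eigengene, sc$sim$truth$profiles[2, ])), 0.95)
})

test_that("tight clusters and signed-network modules agree on planted data", {
  sc <- small_scenario(seed = 1)
  tc <- tight_clusters(sc$norm)
  wm <- wgcna_modules(signed_tom(sc$norm, 10))
  # every tight cluster overlaps some module far beyond chance
  both <- tc %>% rename(tight = cluster) %>%
    inner_join(wm %>% rename(wg = cluster), by = "gene")
  for (k in sort(unique(na.omit(both$tight)))) {
    in_k <- both$tight == k & !is.na(both$tight)
    best <- names(sort(table(both$wg[in_k]), decreasing = TRUE))[1]
    a <- sum(in_k & both$wg == best, na.rm = TRUE)
    b <- sum(in_k) - a
    c_ <- sum(both$wg == best & !in_k, na.rm = TRUE)
    d <- nrow(both) - a - b - c_
    p <- woodnet:::fisher_one_sided(a, b, c_, d)
    expect_lt(p, 1e-6)
  }
})
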
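# Full pipeline run on the default study-condition scenario (600 genes,
# 6 modules, 3 regulator layers, 25 planted interactions, noise_sd 0.25,
# null motif-planting rate 0.02), shared by the recovery checks.

default_pipeline <- function(seed = 101) {
  key <- paste0("pipe", seed)
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  cfg <- simulation_config(seed = seed)
  sim <- simulate_expression(cfg)
  avg <- average_replicates(sim$expr, sim$samples)
  filt <- filter_flat_genes(avg)
  norm <- clust_normalize(filt$kept)
  pro <- simulate_promoters(cfg, sim$truth)
  hits <- scan_pwms(pro$promoters, pro$pwms, p_threshold = 1e-5)
  pres <- presence_matrix(hits, pro$promoters$gene, names(pro$pwms))
  clusters <- tight_clusters(norm)
  enr <- motif_enrichment(pres, clusters)
  motif2tf <- sim$truth$tfs[c("motif", "tf", "family")]
  net <- infer_interactions(pres, avg, clusters, motif2tf,
                            enriched = enr[enr$significant, ])
  truth_edges <- with(sim$truth$planted_interactions,
                      paste(tf, target, motif))
  called_edges <- with(net, paste(tf, target, motif))
  out <- list(
    cfg = cfg, sim = sim, avg = avg, norm = norm, pres = pres,
    clusters = clusters, enr = enr, net = net,
    precision = mean(called_edges %in% truth_edges),
    recall = mean(truth_edges %in% called_edges)
  )
  .scenario_cache[[key]] <- out
  out
}
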
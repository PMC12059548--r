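# Readers and writers for the pipeline's tabular and sequence formats.

#' Read / write a genes-by-samples expression TSV
#'
#' First column `gene`, remaining columns numeric (TPM).
#' @param path file path.
#' @return tibble.
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_expression_tsv
#' @param expr expression tibble.
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read / write the sample map (sample, fraction, replicate)
#' @param path file path.
#' @export
read_sample_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_sample_map
#' @param samples sample map tibble.
#' @export
write_sample_map <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' Write promoter sequences as FASTA
#'
#' @param promoters tibble with `gene`, `sequence`.
#' @param path output path.
#' @export
write_promoter_fasta <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(setNames(promoters$sequence, promoters$gene))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA path.
#' @return tibble: gene, sequence, length.
#' @export
read_promoter_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(gene = sub("\\s.*", "", names(ss)),
         sequence = unname(as.character(ss)),
         length = Biostrings::width(ss))
}

#' Read a gene-to-GO annotation TSV (columns gene, go_id)
#' @param path file path.
#' @export
read_gene2go <- function(path) {
  readr::read_tsv(path, col_names = c("gene", "go_id"),
                  show_col_types = FALSE, comment = "#")
}

#' Write a cluster assignment TSV (gene, cluster)
#' @param assignment tibble (`gene`, `cluster`).
#' @param path file path.
#' @export
write_clusters_tsv <- function(assignment, path) {
  readr::write_tsv(assignment, path)
  invisible(path)
}

#' Export a network as GraphML or DOT
#'
#' @param net interaction tibble from [infer_interactions()].
#' @param path output path.
#' @param format "graphml" or "dot".
#' @export
write_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- igraph::graph_from_data_frame(
    net %>%
      select("tf", "target", "motif", "r", "cross_cluster") %>%
      mutate(cross_cluster = as.integer(.data$cross_cluster)),
    directed = TRUE
  )
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Export a module dendrogram as Newick
#'
#' @param assignment result of [wgcna_modules()] (carries the tree).
#' @param path output path.
#' @export
write_dendrogram_newick <- function(assignment, path) {
  tree <- attr(assignment, "tree")
  if (is.null(tree)) abort("assignment carries no dendrogram")
  ape::write.tree(ape::as.phylo(tree), path)
  invisible(path)
}

#' Write all simulated inputs of a scenario to a directory
#'
#' Materializes the generator output in the pipeline's exchange formats:
#' expression and sample-map TSVs for both species, promoter FASTAs, the
#' MEME motif file, Orthogroups.tsv, the syntelog TSV and a ground-truth
#' JSON.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return the output directory, invisibly.
#' @export
write_simulation <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_expression(config)
  pro <- simulate_promoters(config, sim$truth)
  sp2 <- simulate_second_species(config, pro$truth, pro$pwms)
  pairs <- simulate_syntelogs(config)
  trait <- simulate_trait(config, sim$truth)
  p <- function(f) file.path(outdir, f)
  write_expression_tsv(sim$expr, p("expression.tsv"))
  write_sample_map(sim$samples, p("samples.tsv"))
  write_promoter_fasta(pro$promoters, p("promoters.fa"))
  write_meme(pro$pwms, p("motifs.meme"))
  write_expression_tsv(sp2$expr2, p("expression_species2.tsv"))
  write_sample_map(sp2$samples2, p("samples_species2.tsv"))
  write_promoter_fasta(sp2$promoters2, p("promoters_species2.fa"))
  readr::write_tsv(sp2$orthogroups, p("Orthogroups.tsv"))
  readr::write_tsv(pairs, p("syntelogs.tsv"))
  readr::write_tsv(trait, p("trait.tsv"))
  truth <- sp2$truth
  jsonlite::write_json(list(
    module_of_gene = truth$module_of_gene,
    tfs = truth$tfs,
    planted_interactions = truth$planted_interactions,
    planted_motif_positions = truth$planted_motif_positions,
    conserved_flags = truth$conserved_flags,
    trait_driver_module = truth$trait_driver_module
  ), p("truth.json"), dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
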
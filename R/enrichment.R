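# Enrichment testing: per-cluster motif enrichment (one-sided Fisher with
# joint BH adjustment) and GO term enrichment (hypergeometric with
# Bonferroni) after DAG propagation.

# One-sided (greater) Fisher exact p for the table [a b; c d] equals the
# hypergeometric upper tail. Vectorized over tables.
fisher_one_sided <- function(a, b, c, d) {
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Per-cluster motif enrichment (Fisher + FDR)
#'
#' For every (cluster, motif) pair, a one-sided (greater) Fisher exact test
#' on \[in-cluster & motif, in-cluster & no motif; out & motif, out & no
#' motif\], where "out" covers all other genes in the presence matrix
#' (unclustered genes count only in the population). Benjamini-Hochberg
#' adjustment is applied jointly across all cluster x motif tests.
#'
#' @param presence tibble from [presence_matrix()] (`gene` + logical motif
#'   columns).
#' @param clusters tibble (`gene`, `cluster`), `NA` = unclustered.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return tibble: cluster, motif, a, b, c, d, odds_ratio, or_infinite,
#'   p_value, adjusted_p, method = "BH", significant.
#' @export
motif_enrichment <- function(presence, clusters, alpha = 0.05) {
  stopifnot(is.data.frame(presence), "gene" %in% names(presence))
  motifs <- setdiff(names(presence), "gene")
  cl <- clusters %>% filter(!is.na(.data$cluster))
  missing <- setdiff(cl$gene, presence$gene)
  if (length(missing)) {
    abort(paste("clustered genes missing from the presence matrix:",
                paste(head(missing, 5), collapse = ", ")))
  }
  n_pop <- nrow(presence)
  rows <- list()
  for (k in sort(unique(cl$cluster))) {
    members <- cl$gene[cl$cluster == k]
    if (!length(members)) {
      warn(sprintf("cluster %s is empty; skipped", k))
      next
    }
    in_cl <- presence$gene %in% members
    for (m in motifs) {
      hit <- presence[[m]]
      a <- sum(in_cl & hit); b <- sum(in_cl & !hit)
      c_ <- sum(!in_cl & hit); d <- sum(!in_cl & !hit)
      rows[[length(rows) + 1L]] <-
        tibble(cluster = k, motif = m, a = a, b = b, c = c_, d = d)
    }
  }
  out <- bind_rows(rows)
  out <- out %>%
    mutate(
      odds_ratio = ifelse(.data$b * .data$c == 0, Inf,
                          (.data$a * .data$d) / (.data$b * .data$c)),
      or_infinite = .data$b * .data$c == 0 & .data$a * .data$d > 0,
      p_value = fisher_one_sided(.data$a, .data$b, .data$c, .data$d),
      adjusted_p = p.adjust(.data$p_value, method = "BH"),
      method = "BH",
      significant = .data$adjusted_p < alpha
    )
  stopifnot(all(out$a + out$b + out$c + out$d == n_pop))
  out
}

#' Parse an OBO 1.2 ontology file
#'
#' Keeps `[Term]` stanzas: id, name, namespace, obsolete flag, and parents
#' via `is_a` and `relationship: part_of`.
#'
#' @param path OBO file path.
#' @return list with `terms` (tibble: id, name, namespace, obsolete) and
#'   `parents` (named list of parent term ids).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\[", lines)
  term_starts <- starts[lines[starts] == "[Term]"]
  ends <- c(starts[-1] - 1, length(lines))
  terms <- list(); parents <- list()
  for (i in seq_along(term_starts)) {
    s <- term_starts[i]
    e <- ends[match(s, starts)]
    block <- lines[(s + 1):e]
    getv <- function(key) sub(paste0("^", key, ": *"), "",
                              grep(paste0("^", key, ":"), block, value = TRUE))
    id <- getv("id")[1]
    if (is.na(id)) next
    isa <- sub(" *!.*", "", getv("is_a"))
    rel <- getv("relationship")
    po <- sub(" *!.*", "", sub("^part_of +", "", rel[grepl("^part_of ", rel)]))
    terms[[length(terms) + 1L]] <- tibble(
      id = id,
      name = if (length(getv("name"))) getv("name")[1] else NA_character_,
      namespace = if (length(getv("namespace"))) getv("namespace")[1]
                  else NA_character_,
      obsolete = any(getv("is_obsolete") == "true")
    )
    parents[[id]] <- c(isa, po)
  }
  list(terms = bind_rows(terms), parents = parents)
}

# All ancestors (inclusive of the term itself) via is_a/part_of, memoized.
ancestors_table <- function(dag) {
  memo <- new.env(parent = emptyenv())
  get_anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    memo[[id]] <- id   # cycle guard; DAG assumed acyclic
    ps <- dag$parents[[id]]
    ps <- ps[ps %in% names(dag$parents)]
    res <- unique(c(id, unlist(lapply(ps, get_anc))))
    memo[[id]] <- res
    res
  }
  sapply(names(dag$parents), get_anc, simplify = FALSE)
}

#' GO term enrichment (hypergeometric + Bonferroni) with DAG propagation
#'
#' Annotations are propagated to all ancestors through `is_a` and `part_of`
#' before counting. Terms with at least one study gene are tested with the
#' hypergeometric upper tail; Bonferroni adjustment over the tested terms.
#' Only terms of `namespace` are considered (biological_process by
#' default).
#'
#' @param study character vector of study genes (must be within
#'   `population`).
#' @param population character vector of background genes; defaults to all
#'   genes with >= 1 propagated annotation.
#' @param gene2go tibble with columns `gene`, `go_id`.
#' @param dag ontology from [read_obo()].
#' @param namespace GO namespace filter.
#' @param alpha significance threshold on the adjusted p.
#' @return tibble: term, name, a, b, c, d, odds_ratio, p_value, adjusted_p,
#'   method = "Bonferroni", significant.
#' @export
go_enrichment <- function(study, population = NULL, gene2go, dag,
                          namespace = "biological_process", alpha = 0.05) {
  anc <- ancestors_table(dag)
  keep_terms <- dag$terms$id[!dag$terms$obsolete &
                               (is.na(dag$terms$namespace) |
                                  dag$terms$namespace == namespace)]
  g2g <- gene2go %>%
    filter(.data$go_id %in% names(anc)) %>%
    group_by(.data$gene) %>%
    summarise(terms = list(unique(unlist(anc[.data$go_id]))),
              .groups = "drop") %>%
    mutate(terms = lapply(.data$terms, intersect, keep_terms))
  ann <- setNames(g2g$terms, g2g$gene)
  if (is.null(population)) population <- names(ann)
  bad <- setdiff(study, population)
  if (length(bad)) {
    abort(paste("study genes absent from the population:",
                paste(head(bad, 5), collapse = ", ")))
  }
  pop_ann <- ann[intersect(population, names(ann))]
  study_ann <- ann[intersect(study, names(ann))]
  pop_counts <- table(unlist(pop_ann))
  study_counts <- table(unlist(study_ann))
  tested <- names(study_counts)
  if (!length(tested)) {
    return(tibble(term = character(), name = character(), a = integer(),
                  b = integer(), c = integer(), d = integer(),
                  odds_ratio = numeric(), p_value = numeric(),
                  adjusted_p = numeric(), method = character(),
                  significant = logical()))
  }
  N <- length(population); S <- length(study)
  a <- as.integer(study_counts[tested])
  m <- as.integer(pop_counts[tested])
  b <- S - a
  c_ <- m - a
  d <- N - S - c_
  p <- phyper(a - 1, m, N - m, S, lower.tail = FALSE)
  name_map <- setNames(dag$terms$name, dag$terms$id)
  tibble(term = tested, name = unname(name_map[tested]),
         a = a, b = b, c = c_, d = d,
         odds_ratio = ifelse(b * c_ == 0, Inf, (a * d) / (b * c_)),
         p_value = p,
         adjusted_p = pmin(1, length(tested) * p),
         method = "Bonferroni",
         significant = pmin(1, length(tested) * p) < alpha) %>%
    arrange(.data$p_value)
}
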
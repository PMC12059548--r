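# Cross-species conservation of inferred interactions through orthogroups,
# threshold sensitivity, and conserved co-expression orthogroup detection.

#' Parse an Orthogroups.tsv-style table into long form
#'
#' @param orthogroups tibble: `orthogroup` + one column per species holding
#'   comma-separated gene ids (empty or NA allowed).
#' @return tibble: orthogroup, species, gene.
#' @export
orthogroups_long <- function(orthogroups) {
  stopifnot("orthogroup" %in% names(orthogroups))
  orthogroups %>%
    tidyr::pivot_longer(-"orthogroup", names_to = "species",
                        values_to = "genes") %>%
    filter(!is.na(.data$genes), .data$genes != "") %>%
    mutate(gene = strsplit(.data$genes, ", *")) %>%
    select(-"genes") %>%
    tidyr::unnest("gene")
}

#' Cross-species conservation of network interactions
#'
#' An interaction is conserved iff some ortholog pair (tf', target') of its
#' TF and target has `|Pearson r| > r_threshold` in the second species'
#' expression and -- when `motif_required` -- the same motif present
#' upstream of target' (existential over orthogroup members). Interactions
#' whose TF or target has no expressed ortholog are non-evaluable and
#' reported separately.
#'
#' @param net interaction tibble from [infer_interactions()] (or any tibble
#'   with tf, target, motif columns).
#' @param orthogroups wide orthogroup table (see [orthogroups_long()]).
#' @param expr2 species-2 expression tibble (`gene` + fraction columns).
#' @param presence2 species-2 presence matrix at the chosen window.
#' @param r_threshold correlation threshold (default 0.7).
#' @param motif_required require the same motif upstream of the target
#'   ortholog (default TRUE).
#' @param window promoter window (bp) the presence matrix was computed at;
#'   recorded in the report.
#' @param species1,species2 column names in `orthogroups`.
#' @return a `woodnet_conservation`: list with `summary` (one-row tibble),
#'   `per_interaction`, and `per_regulator` tibbles.
#' @export
conservation_fraction <- function(net, orthogroups, expr2, presence2,
                                  r_threshold = 0.7, motif_required = TRUE,
                                  window = 1000,
                                  species1 = "species1",
                                  species2 = "species2") {
  og <- orthogroups_long(orthogroups)
  if (!all(c(species1, species2) %in% unique(og$species))) {
    abort(paste("species columns absent from the orthogroup table:",
                species1, "/", species2))
  }
  g2og <- og %>% filter(.data$species == species1)
  og2g <- og %>% filter(.data$species == species2)
  m2 <- expr_matrix(expr2)
  orth_of <- function(g) {
    ogs <- g2og$orthogroup[g2og$gene == g]
    intersect(og2g$gene[og2g$orthogroup %in% ogs], rownames(m2))
  }
  per <- purrr::pmap_dfr(
    list(net$tf, net$target, net$motif),
    function(tf, target, motif) {
      tf2 <- orth_of(tf); tg2 <- orth_of(target)
      if (!length(tf2) || !length(tg2)) {
        return(tibble(tf = tf, target = target, motif = motif,
                      evaluable = FALSE, conserved = NA, best_r = NA_real_))
      }
      best <- 0; cons <- FALSE
      for (a in tf2) for (b in tg2) {
        if (a == b) next
        r <- suppressWarnings(cor(m2[a, ], m2[b, ]))
        if (is.na(r)) next
        motif_ok <- !motif_required ||
          (motif %in% names(presence2) && b %in%
             presence2$gene[presence2[[motif]]])
        if (abs(r) > abs(best)) best <- r
        if (abs(r) > r_threshold && motif_ok) cons <- TRUE
      }
      tibble(tf = tf, target = target, motif = motif,
             evaluable = TRUE, conserved = cons, best_r = best)
    })
  ev <- per %>% filter(.data$evaluable)
  summary <- tibble(
    r_threshold = r_threshold, window = window,
    motif_required = motif_required,
    n_interactions = nrow(per),
    n_evaluable = nrow(ev),
    n_non_evaluable = nrow(per) - nrow(ev),
    n_conserved = sum(ev$conserved),
    fraction_conserved = if (nrow(ev)) mean(ev$conserved) else NA_real_
  )
  per_regulator <- ev %>%
    group_by(.data$tf) %>%
    summarise(n = n(), n_conserved = sum(.data$conserved),
              fraction_conserved = mean(.data$conserved), .groups = "drop")
  structure(list(summary = summary, per_interaction = per,
                 per_regulator = per_regulator),
            class = "woodnet_conservation")
}

#' @export
print.woodnet_conservation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "conservation: %d/%d evaluable interactions conserved (%.1f%%) at |r| > %s%s\n",
    s$n_conserved, s$n_evaluable, 100 * s$fraction_conserved, s$r_threshold,
    if (s$motif_required) " with motif" else " (correlation only)"))
  invisible(x)
}

#' @method tidy woodnet_conservation
#' @export
tidy.woodnet_conservation <- function(x, ...) x$per_interaction

#' @method glance woodnet_conservation
#' @export
glance.woodnet_conservation <- function(x, ...) x$summary

#' Conservation across a grid of correlation thresholds
#'
#' One [conservation_fraction()] report per threshold; the conserved
#' fraction is checked to be non-increasing in the threshold (it must be,
#' since the criteria are nested).
#'
#' @inheritParams conservation_fraction
#' @param thresholds ascending correlation thresholds.
#' @return tibble with one summary row per threshold.
#' @export
threshold_sensitivity <- function(net, orthogroups, expr2, presence2,
                                  thresholds = c(0.7, 0.8, 0.9),
                                  motif_required = TRUE, window = 1000,
                                  species1 = "species1",
                                  species2 = "species2") {
  if (is.unsorted(thresholds)) abort("`thresholds` must be ascending")
  out <- purrr::map_dfr(thresholds, function(th) {
    glance(conservation_fraction(net, orthogroups, expr2, presence2,
                                 r_threshold = th,
                                 motif_required = motif_required,
                                 window = window, species1 = species1,
                                 species2 = species2))
  })
  fr <- out$fraction_conserved[!is.na(out$fraction_conserved)]
  stopifnot(all(diff(fr) <= 1e-12))
  out
}

#' Orthogroups with conserved co-expression across species
#'
#' Each species is clustered independently; an orthogroup is conserved iff
#' every species has at least one clustered member and some combination of
#' the members' clusters has pairwise centroid correlation above
#' `centroid_r_min` on aligned fractions. Fractions are aligned by shared
#' labels when any are shared, else positionally by rank order when the
#' label sets differ but have equal length.
#'
#' @param assignments named list (per species) of (`gene`, `cluster`)
#'   tibbles.
#' @param centroids named list (per species) of tibbles `cluster` +
#'   fraction columns (cluster mean profiles).
#' @param orthogroups wide orthogroup table; its species columns must match
#'   the names of `assignments`.
#' @param centroid_r_min pairwise centroid correlation threshold.
#' @return tibble: orthogroup, conserved, conserved_in (comma-joined
#'   species with a clustered member), plus one `cluster_<species>` column
#'   per species.
#' @export
conserved_modules <- function(assignments, centroids, orthogroups,
                              centroid_r_min = 0.7) {
  species <- names(assignments)
  stopifnot(length(species) >= 2, !is.null(names(centroids)),
            setequal(species, names(centroids)))
  og <- orthogroups_long(orthogroups) %>% filter(.data$species %in% species)

  # align centroid fraction columns across species
  frac_cols <- lapply(centroids, function(x) setdiff(names(x), "cluster"))
  shared <- Reduce(intersect, frac_cols)
  cent_mats <- if (length(shared) >= 3) {
    lapply(centroids, function(x) {
      m <- as.matrix(x[shared]); rownames(m) <- x$cluster; m
    })
  } else if (length(unique(lengths(frac_cols))) == 1 &&
             lengths(frac_cols)[1] >= 3) {
    lapply(centroids, function(x) {   # positional alignment by rank order
      m <- as.matrix(x[setdiff(names(x), "cluster")])
      rownames(m) <- x$cluster; m
    })
  } else {
    abort("no shared or alignable fractions across species")
  }

  cl_maps <- lapply(assignments, function(a) setNames(a$cluster, a$gene))
  rows <- lapply(unique(og$orthogroup), function(o) {
    sub <- og[og$orthogroup == o, ]
    per_sp <- lapply(species, function(sp) {
      g <- sub$gene[sub$species == sp]
      cl <- unique(na.omit(unname(cl_maps[[sp]][g])))
      cl
    })
    names(per_sp) <- species
    clustered_in <- species[lengths(per_sp) > 0]
    conserved <- FALSE
    if (length(clustered_in) == length(species)) {
      combos <- expand.grid(per_sp, stringsAsFactors = FALSE)
      for (j in seq_len(nrow(combos))) {
        ok <- TRUE
        for (a in 1:(length(species) - 1)) for (b in (a + 1):length(species)) {
          ca <- as.character(combos[j, a]); cb <- as.character(combos[j, b])
          r <- suppressWarnings(cor(cent_mats[[a]][ca, ], cent_mats[[b]][cb, ]))
          if (is.na(r) || r <= centroid_r_min) { ok <- FALSE; break }
        }
        if (ok) { conserved <- TRUE; break }
      }
    }
    row <- tibble(orthogroup = o, conserved = conserved,
                  conserved_in = paste(clustered_in, collapse = ","))
    for (sp in species) {
      row[[paste0("cluster_", sp)]] <-
        if (length(per_sp[[sp]])) paste(per_sp[[sp]], collapse = ",")
        else NA_character_
    }
    row
  })
  bind_rows(rows)
}
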
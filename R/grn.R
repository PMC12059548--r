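# Regulatory network construction from motif presence + expression
# correlation, the nested-regression screen for regulators without known
# binding motifs, and trait-profile correlation.

#' Infer regulatory interactions from motif presence and correlation
#'
#' An edge `tf -> target` for motif `m` is called iff the target promoter
#' carries `m` and the absolute Pearson correlation between TF and target
#' expression (raw TPM over fractions) exceeds `r_min`. Candidate TFs are
#' restricted to those whose motif is enriched in at least one cluster;
#' targets are screened across all clusters, and edges whose TF and target
#' sit in different clusters are flagged `cross_cluster`. When several TFs
#' of the same family share a motif and pass for a target, only the TF with
#' the highest `|r|` is kept (ties broken by gene id). Self-edges are
#' excluded.
#'
#' @param presence tibble from [presence_matrix()].
#' @param expr tibble (`gene` + fraction columns, raw TPM).
#' @param clusters tibble (`gene`, `cluster`), `NA` = unclustered.
#' @param motif2tf tibble with columns `motif`, `tf`, `family`.
#' @param enriched optional tibble with a `motif` column (for example the
#'   significant rows of [motif_enrichment()]); `NULL` admits all motifs.
#' @param r_min correlation threshold (default 0.7, in (0, 1)).
#' @param include_unclustered also screen genes outside every cluster
#'   (default FALSE: the screen runs across all clusters, i.e. over
#'   clustered genes).
#' @return tibble of interactions: tf, target, motif, family, r,
#'   tf_cluster, target_cluster, cross_cluster; attribute `r_min`.
#' @export
infer_interactions <- function(presence, expr, clusters, motif2tf,
                               enriched = NULL, r_min = 0.7,
                               include_unclustered = FALSE) {
  if (r_min <= 0 || r_min >= 1) abort("`r_min` must be in (0, 1)")
  stopifnot(all(c("motif", "tf", "family") %in% names(motif2tf)))
  m <- expr_matrix(expr)
  cand <- motif2tf
  if (!is.null(enriched)) cand <- cand %>% filter(.data$motif %in% enriched$motif)
  missing_tf <- setdiff(cand$tf, rownames(m))
  if (length(missing_tf)) {
    warn(paste("TFs absent from expression; skipped:",
               paste(missing_tf, collapse = ", ")))
    cand <- cand %>% filter(!.data$tf %in% missing_tf)
  }
  cl_map <- setNames(clusters$cluster, clusters$gene)
  edges <- list()
  for (i in seq_len(nrow(cand))) {
    tf <- cand$tf[i]; motif <- cand$motif[i]
    if (!motif %in% names(presence)) next
    tgts <- presence$gene[presence[[motif]]]
    tgts <- intersect(setdiff(tgts, tf), rownames(m))
    if (!include_unclustered) {
      tgts <- intersect(tgts, clusters$gene[!is.na(clusters$cluster)])
    }
    if (!length(tgts)) next
    r <- suppressWarnings(
      as.numeric(cor(m[tf, ], t(m[tgts, , drop = FALSE])))
    )
    pass <- !is.na(r) & abs(r) > r_min
    if (!any(pass)) next
    edges[[length(edges) + 1L]] <- tibble(
      tf = tf, target = tgts[pass], motif = motif,
      family = cand$family[i], r = r[pass]
    )
  }
  out <- if (length(edges)) bind_rows(edges) else
    tibble(tf = character(), target = character(), motif = character(),
           family = character(), r = numeric())
  # one regulator per (target, motif, family): keep max |r|, ties by tf id
  out <- out %>%
    arrange(.data$target, .data$motif, .data$family,
            desc(abs(.data$r)), .data$tf) %>%
    group_by(.data$target, .data$motif, .data$family) %>%
    slice(1) %>%
    ungroup() %>%
    mutate(
      tf_cluster = unname(cl_map[.data$tf]),
      target_cluster = unname(cl_map[.data$target]),
      cross_cluster = !is.na(.data$tf_cluster) &
        (is.na(.data$target_cluster) |
           .data$tf_cluster != .data$target_cluster)
    ) %>%
    select("tf", "target", "motif", "family", "r", "tf_cluster",
           "target_cluster", "cross_cluster") %>%
    arrange(.data$tf, .data$target, .data$motif)
  attr(out, "r_min") <- r_min
  class(out) <- c("woodnet_network", class(out))
  out
}

#' @export
print.woodnet_network <- function(x, ...) {
  cat("regulatory network:", nrow(x), "interactions,",
      length(unique(x$tf)), "regulators, |r| >",
      attr(x, "r_min"), "\n")
  NextMethod()
}

# Gaussian-likelihood LRT from residual sums of squares:
# stat = n * log(RSS_reduced / RSS_full) = -2 (l_reduced - l_full).
# The p-value uses the exact finite-sample calibration of this statistic
# under Gaussian OLS: stat is a monotone function of the partial F,
# F = (exp(stat/n) - 1) * (n - p_full) / df, so P(F_{df, n-p_full} >= F)
# is exact where the chi-square reference (its large-n limit) is
# anticonservative at the small n this screen runs on.
lrt_rss <- function(fit_reduced, fit_full) {
  rss_r <- sum(stats::residuals(fit_reduced)^2)
  rss_f <- sum(stats::residuals(fit_full)^2)
  n <- length(stats::residuals(fit_full))
  p_full <- length(stats::coef(fit_full))
  df <- p_full - length(stats::coef(fit_reduced))
  if (rss_f <= 1e-300 && rss_r <= 1e-300) {
    # both models interpolate the data: no evidence against the reduction
    return(tibble(statistic = 0, df = df, p_value = 1))
  }
  stat <- n * log(rss_r / max(rss_f, .Machine$double.xmin))
  f_stat <- (exp(stat / n) - 1) * (n - p_full) / df
  tibble(statistic = stat, df = df,
         p_value = stats::pf(f_stat, df, n - p_full, lower.tail = FALSE))
}

#' Nested-regression screen for dual-regulator targets
#'
#' Fits four OLS models of a target's expression on two regulators
#' (named after the KNAT7/KNAT3 screen): `K7: y ~ k7`, `K3: y ~ k3`,
#' `ADD: y ~ k7 + k3`, `FULL: y ~ k7 * k3`, all with intercept. The target
#' passes the screen iff the best R-squared exceeds `r2_min`. Model
#' selection is by closed testing against the full model: each reduced
#' model is compared with FULL by the Gaussian RSS-identity
#' likelihood-ratio statistic (exact finite-sample F calibration), and the
#' most parsimonious model not rejected at `alpha` is chosen (ties between
#' the two single-regulator models go to the higher R-squared); if every
#' reduction is rejected, FULL is kept. Collinear regulators
#' (`|r| > 0.999`) exclude the interaction model, and ADD takes the role
#' of the full model.
#'
#' @param data data frame with one row per observation.
#' @param response,k7,k3 column names (character) of the target and the two
#'   regulator expression vectors.
#' @param r2_min variance-explained gate (default 0.7).
#' @param alpha LRT significance level (default 0.05).
#' @return a `woodnet_knat_fit`: list with `r2` (named), `lrt` (tibble),
#'   `chosen`, `passed`, `collinear`, `n`, and the four `fits`. Use
#'   [tidy()] / [glance()] for tabular views.
#' @export
knat_screen <- function(data, response = "y", k7 = "k7", k3 = "k3",
                        r2_min = 0.7, alpha = 0.05) {
  stopifnot(all(c(response, k7, k3) %in% names(data)))
  d <- tibble(y = data[[response]], k7 = data[[k7]], k3 = data[[k3]])
  d <- d[complete.cases(d), ]
  n <- nrow(d)
  if (n < 6) abort("need >= 6 observations")
  collinear <- abs(cor(d$k7, d$k3)) > 0.999
  fits <- list(
    K7 = lm(y ~ k7, data = d),
    K3 = lm(y ~ k3, data = d),
    ADD = lm(y ~ k7 + k3, data = d)
  )
  if (!collinear) fits$FULL <- lm(y ~ k7 * k3, data = d)
  r2 <- vapply(fits, function(f) {
    suppressWarnings(summary(f)$r.squared)  # perfect fits are legitimate
  }, numeric(1))
  if (!collinear) {
    stopifnot(r2["FULL"] >= r2["ADD"] - 1e-10,
              r2["ADD"] >= max(r2["K7"], r2["K3"]) - 1e-10)
  }
  top <- if (collinear) "ADD" else "FULL"
  reduced <- setdiff(names(fits), top)
  lrt <- bind_rows(lapply(reduced, function(mname) {
    lrt_rss(fits[[mname]], fits[[top]]) %>%
      mutate(comparison = paste0(mname, "_vs_", top))
  })) %>% select("comparison", "statistic", "df", "p_value")
  passed <- max(r2) > r2_min

  # most parsimonious model not rejected against the top model; the two
  # single-regulator models are tied in size and resolved by R-squared
  not_rejected <- reduced[vapply(reduced, function(mname) {
    lrt$p_value[lrt$comparison == paste0(mname, "_vs_", top)] >= alpha
  }, logical(1))]
  singles <- intersect(c("K7", "K3"), not_rejected)
  chosen <- if (length(singles)) {
    singles[which.max(r2[singles])]
  } else if ("ADD" %in% not_rejected) {
    "ADD"
  } else {
    top
  }
  structure(list(r2 = r2, lrt = lrt, chosen = chosen, passed = passed,
                 collinear = collinear, n = n, alpha = alpha,
                 r2_min = r2_min, fits = fits),
            class = "woodnet_knat_fit")
}

#' @export
print.woodnet_knat_fit <- function(x, ...) {
  cat("nested-regression screen (n =", x$n, "): chosen", x$chosen,
      sprintf("(R2 = %.3f, gate %s)", x$r2[x$chosen],
              if (x$passed) "passed" else "failed"), "\n")
  invisible(x)
}

#' @method tidy woodnet_knat_fit
#' @export
tidy.woodnet_knat_fit <- function(x, ...) {
  tibble(term = names(x$r2), r_squared = unname(x$r2),
         chosen = names(x$r2) == x$chosen) %>%
    left_join(
      x$lrt %>%
        mutate(term = sub("_vs_.*", "", .data$comparison)) %>%
        select("term", lrt_statistic = "statistic", lrt_p = "p_value"),
      by = "term"
    )
}

#' @method glance woodnet_knat_fit
#' @export
glance.woodnet_knat_fit <- function(x, ...) {
  getp <- function(cmp) {
    if (cmp %in% x$lrt$comparison) x$lrt$p_value[x$lrt$comparison == cmp]
    else NA_real_
  }
  tibble(chosen = x$chosen, r_squared = unname(x$r2[x$chosen]),
         passed = x$passed, collinear = x$collinear, n = x$n,
         k7_vs_full_p = getp("K7_vs_FULL"),
         k3_vs_full_p = getp("K3_vs_FULL"),
         add_vs_full_p = getp("ADD_vs_FULL"))
}

#' Run the nested-regression screen over many targets
#'
#' @param expr tibble (`gene` + sample/fraction columns).
#' @param targets character vector of target gene ids.
#' @param k7_gene,k3_gene regulator gene ids.
#' @inheritParams knat_screen
#' @return tibble: one [glance()] row per target, with a `target` column.
#' @export
knat_screen_all <- function(expr, targets, k7_gene, k3_gene,
                            r2_min = 0.7, alpha = 0.05) {
  m <- expr_matrix(expr)
  stopifnot(all(c(k7_gene, k3_gene) %in% rownames(m)))
  purrr::map_dfr(targets, function(g) {
    d <- tibble(y = m[g, ], k7 = m[k7_gene, ], k3 = m[k3_gene, ])
    fit <- knat_screen(d, r2_min = r2_min, alpha = alpha)
    glance(fit) %>% mutate(target = g, .before = 1)
  })
}

#' Percent-normalize MS peak intensities against an internal standard
#'
#' Each peak intensity is divided by the sample's internal-standard
#' intensity; the ratios are then scaled to sum to 100 within each sample.
#'
#' @param intensities long tibble with columns `sample`, `peak`,
#'   `intensity`.
#' @param standard tibble with columns `sample`, `intensity` (internal
#'   standard per sample), or a named numeric vector.
#' @return tibble: sample, peak, ratio, percent (percent sums to 100 per
#'   sample).
#' @export
peak_ratio_normalize <- function(intensities, standard) {
  stopifnot(all(c("sample", "peak", "intensity") %in% names(intensities)))
  if (!is.data.frame(standard)) {
    standard <- tibble(sample = names(standard),
                       intensity = as.numeric(standard))
  }
  bad <- standard$sample[standard$intensity <= 0]
  if (length(bad)) {
    abort(paste("internal standard <= 0 in sample(s):",
                paste(bad, collapse = ", ")))
  }
  is_map <- setNames(standard$intensity, standard$sample)
  missing <- setdiff(unique(intensities$sample), names(is_map))
  if (length(missing)) {
    abort(paste("no internal standard for sample(s):",
                paste(missing, collapse = ", ")))
  }
  intensities %>%
    mutate(ratio = .data$intensity / unname(is_map[.data$sample])) %>%
    group_by(.data$sample) %>%
    mutate(percent = 100 * .data$ratio / sum(.data$ratio)) %>%
    ungroup() %>%
    select("sample", "peak", "ratio", "percent")
}

#' Genes correlating with a trait profile
#'
#' Pearson correlation between each gene's fraction-level expression and a
#' trait profile; genes with `|r| > r_min` are returned, sorted by
#' decreasing `|r|`.
#'
#' @param expr tibble (`gene` + fraction columns).
#' @param trait tibble with columns `fraction`, `value`.
#' @param r_min correlation threshold (default 0.7); 0 returns all genes.
#' @return tibble: gene, r.
#' @export
trait_correlation <- function(expr, trait, r_min = 0.7) {
  stopifnot(all(c("fraction", "value") %in% names(trait)))
  m <- expr_matrix(expr)
  shared <- intersect(colnames(m), trait$fraction)
  if (length(shared) < 3) abort("need >= 3 shared fractions")
  tv <- trait$value[match(shared, trait$fraction)]
  r <- suppressWarnings(as.numeric(cor(tv, t(m[, shared, drop = FALSE]))))
  out <- tibble(gene = rownames(m), r = r) %>%
    filter(!is.na(.data$r), abs(.data$r) > r_min) %>%
    arrange(desc(abs(.data$r)))
  attr(out, "r_min") <- r_min
  attr(out, "n_fractions") <- length(shared)
  out
}
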
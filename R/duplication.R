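# Whole-genome-multiplication analysis: Ks spectra and peak detection, age
# calibration against the gamma event, event assignment, duplicate-class
# enrichment in clusters, syntelog promoter-motif conservation (one-sided
# Wilcoxon), and Ka:Ks divergence flags.

#' One-sided Wilcoxon rank-sum test (greater)
#'
#' Exact by full enumeration of group assignments when both groups have at
#' most `enum_max` observations (ties handled exactly); exact via the
#' Wilcoxon distribution when there are no ties and both groups have at
#' most 25; otherwise a normal approximation with tie correction and
#' continuity correction. Alternative: `x` stochastically greater than
#' `y`.
#'
#' @param x,y numeric vectors.
#' @param enum_max largest group size for the enumeration path.
#' @return tibble: statistic (Mann-Whitney U of `x`), p_value, method.
#' @export
wilcoxon_greater <- function(x, y, enum_max = 10) {
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) abort("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))
  if (nx <= enum_max && ny <= enum_max) {
    idx <- combn(nx + ny, nx)
    us <- apply(idx, 2, function(s) sum(r[s])) - nx * (nx + 1) / 2
    p <- mean(us >= u_obs - 1e-9)
    method <- "exact enumeration"
  } else if (!ties && nx <= 25 && ny <= 25) {
    # P(U >= u_obs) under the null
    p <- stats::pwilcox(u_obs - 1, nx, ny, lower.tail = FALSE)
    method <- "exact distribution"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    n <- nx + ny
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u_obs - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal approximation"
  }
  tibble(statistic = u_obs, p_value = p, method = method,
         n_x = nx, n_y = ny)
}

#' Ks spectrum: KDE over log10 Ks with prominence-filtered peaks
#'
#' Gaussian kernel density over log10(Ks) for pairs with Ks in (0,
#' `ks_max`]; peaks are local maxima of the density whose topographic
#' prominence is at least `min_prominence` times the maximum density.
#' Bandwidth defaults to Silverman's rule of thumb.
#'
#' @param pairs tibble with a `Ks` column.
#' @param bandwidth KDE bandwidth on the log10 scale (default Silverman).
#' @param min_prominence prominence threshold as a fraction of the maximum
#'   density (default 0.05).
#' @param ks_max pairs with Ks above this are dropped as saturated
#'   (default 5).
#' @param n_grid density grid size.
#' @return a `woodnet_ks_spectrum`: list with `grid` (tibble log10_ks,
#'   density), `peaks` (tibble position, height, prominence, sorted by
#'   position), `bandwidth`, `n`, `degenerate`.
#' @export
ks_peaks <- function(pairs, bandwidth = NULL, min_prominence = 0.05,
                     ks_max = 5, n_grid = 1024) {
  stopifnot("Ks" %in% names(pairs))
  ks <- pairs$Ks[pairs$Ks > 0 & pairs$Ks <= ks_max & is.finite(pairs$Ks)]
  if (length(ks) < 2) abort("need >= 2 pairs with Ks in (0, ks_max]")
  lks <- log10(ks)
  if (length(unique(lks)) == 1) {
    return(structure(list(
      grid = tibble(log10_ks = unique(lks), density = Inf),
      peaks = tibble(position = unique(lks), height = Inf, prominence = Inf),
      bandwidth = 0, n = length(lks), degenerate = TRUE
    ), class = "woodnet_ks_spectrum"))
  }
  if (is.null(bandwidth)) bandwidth <- bw.nrd0(lks)
  d <- density(lks, bw = bandwidth, n = n_grid)
  peaks <- find_peaks_1d(d$x, d$y)
  peaks <- peaks %>%
    filter(.data$prominence >= min_prominence * max(d$y)) %>%
    arrange(.data$position)
  structure(list(
    grid = tibble(log10_ks = d$x, density = d$y),
    peaks = peaks, bandwidth = bandwidth, n = length(lks),
    degenerate = FALSE
  ), class = "woodnet_ks_spectrum")
}

# Local maxima of y with topographic prominence: for each peak walk out on
# both sides until higher ground (or the boundary); the base on each side
# is the minimum in that stretch, and prominence = height - max(bases).
find_peaks_1d <- function(x, y) {
  n <- length(y)
  is_peak <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(is_peak)) return(tibble(position = numeric(),
                                      height = numeric(),
                                      prominence = numeric()))
  prom <- vapply(is_peak, function(i) {
    h <- y[i]
    left <- i; lmin <- h
    while (left > 1 && y[left] <= h) {
      left <- left - 1L
      lmin <- min(lmin, y[left])
      if (y[left] > h) break
    }
    right <- i; rmin <- h
    while (right < n && y[right] <= h) {
      right <- right + 1L
      rmin <- min(rmin, y[right])
      if (y[right] > h) break
    }
    h - max(lmin, rmin)
  }, numeric(1))
  tibble(position = x[is_peak], height = y[is_peak], prominence = prom)
}

#' @export
print.woodnet_ks_spectrum <- function(x, ...) {
  cat("Ks spectrum over", x$n, "pairs:", nrow(x$peaks), "peak(s) at log10 Ks",
      paste(sprintf("%.3f", x$peaks$position), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy woodnet_ks_spectrum
#' @export
tidy.woodnet_ks_spectrum <- function(x, ...) x$peaks

#' Calibrate peak ages against an anchor duplication event
#'
#' Ages scale linearly in Ks (not log10 Ks):
#' `age(peak) = anchor_age * Ks(peak) / Ks(anchor)`. The default anchor is
#' the core-eudicot gamma event at 125 Ma.
#'
#' @param spectrum a `woodnet_ks_spectrum`.
#' @param anchor_peak index of the anchor peak in `spectrum$peaks`
#'   (default 1, the youngest), or a log10 Ks position to match the nearest
#'   peak.
#' @param anchor_age_ma anchor age in Ma (default 125).
#' @return the peaks tibble with an `age_ma` column.
#' @export
calibrate_ages <- function(spectrum, anchor_peak = 1, anchor_age_ma = 125) {
  stopifnot(inherits(spectrum, "woodnet_ks_spectrum"))
  pk <- spectrum$peaks
  if (!nrow(pk)) abort("spectrum has no peaks")
  idx <- if (anchor_peak == round(anchor_peak) &&
             anchor_peak >= 1 && anchor_peak <= nrow(pk)) {
    as.integer(anchor_peak)
  } else {
    which.min(abs(pk$position - anchor_peak))
  }
  anchor_ks <- 10^pk$position[idx]
  if (anchor_ks <= 0) abort("anchor Ks must be positive")
  pk %>%
    mutate(age_ma = anchor_age_ma * 10^.data$position / anchor_ks,
           anchor = row_number() == idx)
}

#' Assign syntelog pairs to duplication events
#'
#' Each pair joins the nearest peak in log10 Ks if within `window_log10`;
#' pairs equidistant between two peaks go to the older (larger Ks) peak.
#'
#' @param pairs tibble with a `Ks` column.
#' @param spectrum a `woodnet_ks_spectrum` with >= 1 peak.
#' @param window_log10 maximum |log10 Ks - peak| for assignment
#'   (default 0.15).
#' @param event_names optional names per peak (default `peak1`, ...).
#' @return `pairs` with `event` (NA when unassigned) and `event_peak`
#'   (peak position) columns.
#' @export
assign_events <- function(pairs, spectrum, window_log10 = 0.15,
                          event_names = NULL) {
  stopifnot(inherits(spectrum, "woodnet_ks_spectrum"))
  pk <- spectrum$peaks
  if (!nrow(pk)) abort("spectrum has no peaks")
  if (is.null(event_names)) event_names <- paste0("peak", seq_len(nrow(pk)))
  lks <- log10(pairs$Ks)
  idx <- vapply(lks, function(v) {
    if (!is.finite(v)) return(NA_integer_)
    d <- abs(pk$position - v)
    cand <- which(d == min(d))
    cand[length(cand)]   # tie: older (larger Ks) peak
  }, integer(1))
  dist <- abs(pk$position[idx] - lks)
  assigned <- !is.na(idx) & dist <= window_log10
  pairs %>%
    mutate(event = ifelse(assigned, event_names[idx], NA_character_),
           event_peak = ifelse(assigned, pk$position[idx], NA_real_))
}

#' Duplicate-class enrichment per cluster
#'
#' A gene is class-duplicated iff it belongs to at least one pair of
#' `class_of_interest`. One-sided Fisher per cluster against all clustered
#' genes; raw p < `alpha` is flagged (matching common practice for this
#' screen) and a BH-adjusted p is also reported.
#'
#' @param clusters tibble (`gene`, `cluster`), `NA` = unclustered.
#' @param pairs tibble with gene_a, gene_b, duplicate_class.
#' @param class_of_interest duplicate class label (default "WGM").
#' @param alpha raw-p flag threshold.
#' @return tibble: cluster, a, b, c, d, odds_ratio, p_value, adjusted_p,
#'   significant (raw p < alpha).
#' @export
duplicate_class_enrichment <- function(clusters, pairs,
                                       class_of_interest = "WGM",
                                       alpha = 0.05) {
  dup_genes <- unique(c(
    pairs$gene_a[pairs$duplicate_class == class_of_interest],
    pairs$gene_b[pairs$duplicate_class == class_of_interest]
  ))
  cl <- clusters %>% filter(!is.na(.data$cluster))
  pop <- cl$gene
  is_dup <- pop %in% dup_genes
  rows <- purrr::map_dfr(sort(unique(cl$cluster)), function(k) {
    in_cl <- cl$cluster == k
    a <- sum(in_cl & is_dup); b <- sum(in_cl & !is_dup)
    c_ <- sum(!in_cl & is_dup); d <- sum(!in_cl & !is_dup)
    tibble(cluster = k, a = a, b = b, c = c_, d = d)
  })
  rows %>%
    mutate(
      odds_ratio = ifelse(.data$b * .data$c == 0, Inf,
                          (.data$a * .data$d) / (.data$b * .data$c)),
      p_value = fisher_one_sided(.data$a, .data$b, .data$c, .data$d),
      adjusted_p = p.adjust(.data$p_value, method = "BH"),
      significant = .data$p_value < alpha
    )
}

#' Promoter-motif conservation between syntelogs
#'
#' The conserved-motif count of a pair is the number of distinct motifs
#' present upstream of both genes. Pairs are partitioned into same-cluster,
#' different-cluster and (>= 1) unclustered groups, and same-cluster counts
#' are tested against each other group with a one-sided Wilcoxon rank-sum
#' test (same-cluster greater).
#'
#' @param pairs tibble with gene_a, gene_b.
#' @param presence presence matrix covering both genes of every pair.
#' @param clusters tibble (`gene`, `cluster`), `NA` = unclustered.
#' @return list with `per_pair` (pairs + group + conserved_motifs) and
#'   `tests` (one row per comparison; skipped with a warning when a group
#'   is empty).
#' @export
syntelog_motif_conservation <- function(pairs, presence, clusters) {
  motifs <- setdiff(names(presence), "gene")
  pm <- as.matrix(presence[motifs])
  rownames(pm) <- presence$gene
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), presence$gene)
  if (length(missing)) {
    abort(paste("pair genes missing from the presence matrix:",
                paste(head(missing, 5), collapse = ", ")))
  }
  cl_map <- setNames(clusters$cluster, clusters$gene)
  per_pair <- pairs %>%
    mutate(
      conserved_motifs = vapply(seq_len(n()), function(i) {
        sum(pm[pairs$gene_a[i], ] & pm[pairs$gene_b[i], ])
      }, numeric(1)),
      cluster_a = unname(cl_map[.data$gene_a]),
      cluster_b = unname(cl_map[.data$gene_b]),
      group = dplyr::case_when(
        is.na(.data$cluster_a) | is.na(.data$cluster_b) ~ "unclustered",
        .data$cluster_a == .data$cluster_b ~ "same_cluster",
        TRUE ~ "different_cluster"
      )
    )
  same <- per_pair$conserved_motifs[per_pair$group == "same_cluster"]
  tests <- purrr::map_dfr(c("different_cluster", "unclustered"), function(g) {
    other <- per_pair$conserved_motifs[per_pair$group == g]
    if (!length(same) || !length(other)) {
      warn(sprintf("group with n = 0 in comparison same_cluster vs %s; skipped",
                   g))
      return(tibble(comparison = paste0("same_vs_", g), statistic = NA_real_,
                    p_value = NA_real_, method = NA_character_,
                    n_x = length(same), n_y = length(other)))
    }
    wilcoxon_greater(same, other) %>%
      mutate(comparison = paste0("same_vs_", g), .before = 1)
  })
  list(per_pair = per_pair, tests = tests)
}

#' Flag syntelog pairs under potential positive selection
#'
#' Flags pairs with `Ka/Ks > 1`; pairs with `Ks = 0` are excluded from the
#' ratio and counted separately. When clusters are supplied, mean Ka is
#' summarized for same-cluster versus different-cluster pairs.
#'
#' @param pairs tibble with gene_a, gene_b, Ks, Ka.
#' @param clusters optional tibble (`gene`, `cluster`).
#' @return list with `pairs` (adds ka_ks, flagged), `n_zero_ks`, and
#'   `summary` (mean Ka per group; NULL without clusters).
#' @export
ka_ks_flags <- function(pairs, clusters = NULL) {
  stopifnot(all(c("Ks", "Ka") %in% names(pairs)))
  ok <- pairs$Ks > 0
  out <- pairs[ok, ] %>%
    mutate(ka_ks = .data$Ka / .data$Ks, flagged = .data$ka_ks > 1)
  summary <- NULL
  if (!is.null(clusters)) {
    cl_map <- setNames(clusters$cluster, clusters$gene)
    grp <- dplyr::case_when(
      is.na(cl_map[out$gene_a]) | is.na(cl_map[out$gene_b]) ~ "unclustered",
      cl_map[out$gene_a] == cl_map[out$gene_b] ~ "same_cluster",
      TRUE ~ "different_cluster"
    )
    summary <- tibble(group = grp, Ka = out$Ka) %>%
      group_by(.data$group) %>%
      summarise(n = n(), mean_ka = mean(.data$Ka), .groups = "drop")
  }
  list(pairs = out, n_zero_ks = sum(!ok), summary = summary)
}
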
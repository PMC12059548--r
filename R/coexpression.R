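# Co-expression: tight consensus clustering with unclustered genes, and a
# signed weighted correlation network (soft power, topological overlap,
# modules, eigengenes).

#' Tight clustering with unclustered genes
#'
#' Tight cores from average-linkage hierarchical clustering of the
#' profile-correlation dissimilarity `1 - r`: the tree is cut at the
#' absolute height `1 - tau` with `tau = 1 - 0.3 t` (clipped to
#' \[0.5, 1\]), so members of a core correlate with it at `tau` on
#' average. Cores smaller than `min_size` are dissolved, and cores whose
#' mean pairwise member correlation falls below `tau` are rejected; all
#' remaining genes are unclustered (`NA`). Larger `t` cuts higher, giving
#' looser, larger clusters; the procedure is deterministic and invariant
#' to gene order.
#'
#' @param norm normalized tibble from [clust_normalize()] (`gene` +
#'   fraction columns).
#' @param t tightness parameter, >= 0.
#' @param min_size smallest allowed core.
#' @return tibble (`gene`, `cluster`) with `NA` for unclustered genes;
#'   cluster ids contiguous from 1, ordered by decreasing size. Attributes:
#'   `tightness`, `tau`, `method = "tight"`.
#' @export
tight_clusters <- function(norm, t = 0.5, min_size = 11) {
  if (t < 0) abort("`t` must be >= 0")
  m <- expr_matrix(norm)
  if (ncol(m) < 2) abort("need >= 2 fractions")
  n <- nrow(m)
  tau <- min(1, max(0.5, 1 - 0.3 * t))

  sds <- apply(m, 1, sd)
  r <- suppressWarnings(cor(t(m)))
  r[!is.finite(r)] <- -1      # flat genes never co-cluster
  diag(r) <- 1
  tree <- hclust(as.dist(1 - r), method = "average")
  cl <- cutree(tree, h = 1 - tau)

  assignment <- rep(NA_integer_, n)
  names(assignment) <- rownames(m)
  for (k in unique(cl)) {
    core <- which(cl == k & sds > 0)
    if (length(core) < min_size) next
    cc <- r[core, core]
    if (mean(cc[upper.tri(cc)]) < tau) next
    assignment[core] <- k
  }
  out <- tibble(gene = rownames(m), cluster = unname(assignment))
  out <- relabel_by_size(out)
  attr(out, "tightness") <- t
  attr(out, "tau") <- tau
  attr(out, "method") <- "tight"
  out
}

# Relabel cluster ids 1..K by decreasing size (ties by first gene id).
relabel_by_size <- function(assignment) {
  if (!any(!is.na(assignment$cluster))) return(assignment)
  sizes <- assignment %>%
    filter(!is.na(.data$cluster)) %>%
    group_by(.data$cluster) %>%
    summarise(n = n(), first = min(.data$gene), .groups = "drop") %>%
    arrange(desc(.data$n), .data$first)
  map <- setNames(seq_len(nrow(sizes)), sizes$cluster)
  assignment$cluster <- unname(map[as.character(assignment$cluster)])
  assignment
}

# Signed adjacency from Pearson correlation over fractions; constant genes
# get zero correlation and are flagged.
signed_adjacency <- function(m, beta) {
  sds <- apply(m, 1, sd)
  flat <- sds == 0
  r <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  if (any(!flat)) {
    r[!flat, !flat] <- cor(t(m[!flat, , drop = FALSE]))
  }
  a <- ((1 + r) / 2)^beta
  diag(a) <- 1
  list(adjacency = a, flat = rownames(m)[flat])
}

scale_free_fit <- function(a, n_bins = 10) {
  k <- rowSums(a) - 1
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(0)
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  summary(fit)$r.squared
}

#' Pick the soft-thresholding power by the scale-free criterion
#'
#' For each candidate power the signed adjacency
#' `a_ij = ((1 + r_ij)/2)^beta` is formed and the linear fit of
#' `log10 p(k)` versus `log10 k` (10 connectivity bins) scored by R^2.
#' Returns the smallest power reaching `r2_target`, else the argmax.
#'
#' @param norm normalized tibble (`gene` + fraction columns).
#' @param powers candidate powers, ascending.
#' @param r2_target scale-free fit target (default 0.8).
#' @return the chosen power (integer) with attribute `fit_table`.
#' @export
pick_soft_power <- function(norm, powers = c(1:10, 12, 14, 16, 18, 20),
                            r2_target = 0.8) {
  m <- expr_matrix(norm)
  if (nrow(m) < 4) abort("need >= 4 genes")
  r2 <- vapply(powers, function(b) {
    scale_free_fit(signed_adjacency(m, b)$adjacency)
  }, numeric(1))
  hit <- which(r2 >= r2_target)
  choice <- if (length(hit)) powers[hit[1]] else powers[which.max(r2)]
  structure(choice, fit_table = tibble(power = powers, r_squared = r2))
}

#' Signed adjacency and topological overlap
#'
#' `a_ij = ((1 + r_ij)/2)^beta` with Pearson r over fractions;
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) /
#' (min(k_i, k_j) + 1 - a_ij)` with `k_i = sum_{u != i} a_iu`, and
#' `TOM_ii = 1`.
#'
#' @param norm normalized tibble (`gene` + fraction columns).
#' @param beta soft power, >= 1.
#' @return a `woodnet_signed_network`: list with `beta`, `adjacency`,
#'   `tom` (symmetric matrices in \[0,1\]), `genes`, `flat_genes`.
#' @export
signed_tom <- function(norm, beta) {
  if (beta < 1) abort("`beta` must be >= 1")
  m <- expr_matrix(norm)
  sa <- signed_adjacency(m, beta)
  a <- sa$adjacency
  k <- rowSums(a) - 1
  num <- a %*% a - 2 * a   # sum over u != i,j of a_iu a_uj, minus a_ij
  num <- num + a           # + a_ij back per the TOM numerator
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  structure(list(beta = beta, adjacency = a, tom = tom,
                 genes = rownames(m), flat_genes = sa$flat),
            class = "woodnet_signed_network")
}

#' @export
print.woodnet_signed_network <- function(x, ...) {
  cat("signed co-expression network:", length(x$genes), "genes, beta =",
      x$beta, "\n")
  invisible(x)
}

#' Modules from average-linkage clustering of the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut statically at
#' `cut_height * max(merge height)`; modules smaller than
#' `min_module_size` are dissolved to unclustered. Raising `cut_height`
#' merges more and never increases the module count.
#'
#' @param net a `woodnet_signed_network` from [signed_tom()].
#' @param cut_height fraction of the maximum merge height at which the tree
#'   is cut (default 0.75, i.e. one quarter down from the top).
#' @param min_module_size smallest allowed module (default 30).
#' @return tibble (`gene`, `cluster`) with `NA` for unclustered genes;
#'   attributes `method = "wgcna"`, `cut_height`, `tree` (the hclust).
#' @export
wgcna_modules <- function(net, cut_height = 0.75, min_module_size = 30) {
  stopifnot(inherits(net, "woodnet_signed_network"))
  d <- as.dist(1 - net$tom)
  tree <- hclust(d, method = "average")
  h <- cut_height * max(tree$height)
  cl <- cutree(tree, h = h)
  tab <- table(cl)
  keep <- names(tab)[tab >= min_module_size]
  cl_out <- ifelse(as.character(cl) %in% keep, cl, NA_integer_)
  out <- tibble(gene = net$genes, cluster = as.integer(cl_out))
  out <- relabel_by_size(out)
  attr(out, "method") <- "wgcna"
  attr(out, "cut_height") <- cut_height
  attr(out, "tree") <- tree
  out
}

#' Module eigengene
#'
#' First right-singular vector of the gene-centered member-by-fraction
#' submatrix, sign-flipped to correlate positively with the module mean
#' profile, unit norm.
#'
#' @param norm normalized tibble (`gene` + fraction columns).
#' @param members character vector of member genes (>= 2).
#' @return tibble (`fraction`, `eigengene`) with attribute
#'   `variance_explained`.
#' @export
module_eigengene <- function(norm, members) {
  m <- expr_matrix(norm)
  members <- intersect(members, rownames(m))
  if (length(members) < 2) abort("need >= 2 member genes")
  sub <- m[members, , drop = FALSE]
  if (all(apply(sub, 1, sd) == 0)) abort("all member genes are flat")
  centered <- sub - rowMeans(sub)
  sv <- svd(centered)
  v <- sv$v[, 1]
  mean_profile <- colMeans(centered)
  if (cor(v, mean_profile) < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  out <- tibble(fraction = colnames(m), eigengene = v)
  attr(out, "variance_explained") <- sv$d[1]^2 / sum(sv$d^2)
  out
}

#' Eigengenes for every module of an assignment
#'
#' @param norm normalized tibble.
#' @param assignment tibble (`gene`, `cluster`).
#' @return tibble: fraction + one `ME<k>` column per module.
#' @export
module_eigengenes <- function(norm, assignment) {
  cl <- assignment %>% filter(!is.na(.data$cluster))
  out <- tibble(fraction = setdiff(names(norm), "gene"))
  for (k in sort(unique(cl$cluster))) {
    out[[paste0("ME", k)]] <-
      module_eigengene(norm, cl$gene[cl$cluster == k])$eigengene
  }
  out
}
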
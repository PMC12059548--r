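# Expression preprocessing: replicate averaging per tissue fraction,
# CLUST-style normalization, and removal of flat / lowly expressed genes.

#' Average replicates per tissue fraction
#'
#' @param expr expression tibble (`gene` + one numeric column per sample,
#'   TPM).
#' @param samples sample map tibble with columns `sample`, `fraction`
#'   (optionally `replicate`). Column order of the output follows the order
#'   of first appearance of each fraction in `samples`.
#' @return tibble: `gene` + one column per fraction (mean TPM).
#' @export
average_replicates <- function(expr, samples) {
  stopifnot(is.data.frame(expr), is.data.frame(samples),
            all(c("sample", "fraction") %in% names(samples)))
  m <- expr_matrix(expr)
  missing <- setdiff(colnames(m), samples$sample)
  if (length(missing)) {
    abort(paste("samples missing from the sample map:",
                paste(missing, collapse = ", ")))
  }
  fracs <- unique(samples$fraction)
  cols <- lapply(fracs, function(f) {
    s <- intersect(samples$sample[samples$fraction == f], colnames(m))
    if (!length(s)) abort(sprintf("fraction %s has zero samples", f))
    rowMeans(m[, s, drop = FALSE])
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(rownames(m), fracs)
  matrix_to_tibble(out)
}

# Quantile normalization across columns: each column's sorted values are
# replaced by the rank-average reference distribution; ties share the mean
# of the pooled reference values at the tied ranks.
quantile_normalize <- function(m) {
  if (ncol(m) < 2) return(m)
  ref <- rowMeans(apply(m, 2, sort))
  cs <- c(0, cumsum(ref))
  out <- apply(m, 2, function(col) {
    # a tie occupying ranks a..b receives mean(ref[a:b])
    a <- rank(col, ties.method = "min")
    b <- rank(col, ties.method = "max")
    (cs[b + 1] - cs[a]) / (b - a + 1)
  })
  dimnames(out) <- dimnames(m)
  out
}

#' CLUST-style normalization: log2, quantile, per-gene z-score
#'
#' Applies, in order: `log2(TPM + 1)`, quantile normalization across columns
#' (rank-average reference; ties share the mean reference value at the tied
#' ranks), then a per-gene z-score. Constant genes get an all-zero z-score
#' and are flagged flat. The transform order is recorded in the
#' `provenance` attribute; flat genes in `flat_genes`.
#'
#' @param expr tibble (`gene` + numeric columns; raw or fraction-averaged
#'   TPM).
#' @return tibble of the same shape with attributes `provenance` and
#'   `flat_genes`.
#' @export
clust_normalize <- function(expr) {
  m <- log2(expr_matrix(expr) + 1)
  # flat genes are detected on the input scale: the quantile step maps a
  # constant gene onto per-column reference values and would hide it
  in_sds <- apply(m, 1, sd)
  flat <- is.na(in_sds) | in_sds == 0
  q <- quantile_normalize(m)
  sds <- apply(q, 1, sd)
  sds[is.na(sds) | sds == 0] <- 1
  mus <- rowMeans(q)
  z <- (q - mus) / sds
  z[flat, ] <- 0
  out <- matrix_to_tibble(z)
  attr(out, "provenance") <- c("log2(x+1)", "quantile", "zscore")
  attr(out, "flat_genes") <- rownames(m)[flat]
  out
}

#' Filter flat and lowly expressed genes
#'
#' Keeps a gene iff its maximum TPM is at least `min_max_tpm` and
#' `(max + 1) / (min + 1)` is at least `min_fold`.
#'
#' @param expr tibble (`gene` + numeric TPM columns).
#' @param min_max_tpm minimum peak expression (default 1).
#' @param min_fold minimum pseudocounted fold change (default 1.5).
#' @return list with tibbles `kept` and `discarded`.
#' @export
filter_flat_genes <- function(expr, min_max_tpm = 1, min_fold = 1.5) {
  if (min_max_tpm < 0 || min_fold < 0) abort("thresholds must be >= 0")
  m <- expr_matrix(expr)
  mx <- apply(m, 1, max)
  mn <- apply(m, 1, min)
  keep <- mx >= min_max_tpm & (mx + 1) / (mn + 1) >= min_fold
  list(kept = expr[keep, , drop = FALSE],
       discarded = expr[!keep, , drop = FALSE])
}
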
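# Shared fixtures, built in code at test time.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Small expression scenario reused across files; cached per session.
.scenario_cache <- new.env(parent = emptyenv())

small_scenario <- function(seed = 7, ...) {
  key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.scenario_cache[[key]])) {
    cfg <- simulation_config(seed = seed, ...)
    sim <- simulate_expression(cfg)
    avg <- average_replicates(sim$expr, sim$samples)
    norm <- clust_normalize(filter_flat_genes(avg)$kept)
    .scenario_cache[[key]] <- list(cfg = cfg, sim = sim, avg = avg,
                                   norm = norm)
  }
  .scenario_cache[[key]]
}

# Independent brute-force PWM scan oracle: enumerate every offset and
# strand, score by direct log-odds sums, p-value left to the caller.
oracle_scan <- function(seq_chr, pwm, pseudocount = 0.01) {
  mat <- pwm$matrix + pseudocount
  mat <- mat / rowSums(mat)
  bg <- pwm$background
  L <- nrow(mat)
  bases <- strsplit(seq_chr, "")[[1]]
  revcomp <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
  out <- list()
  for (strand in c("+", "-")) {
    for (off in 0:(length(bases) - L)) {
      win <- bases[(off + 1):(off + L)]
      if (strand == "-") win <- rev(revcomp(win))
      sc <- 0
      for (l in seq_len(L)) {
        b <- win[l]
        if (b %in% c("A", "C", "G", "T")) {
          sc <- sc + round(1000 * log2(mat[l, b] / bg[b]))
        }
      }
      out[[length(out) + 1]] <- tibble(offset = off, strand = strand,
                                       score = sc / 1000)
    }
  }
  bind_rows(out)
}

# Independent one-sided Fisher oracle by explicit hypergeometric summation.
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  ks <- max(0, k - n_):min(k, m)
  probs <- exp(lchoose(m, ks) + lchoose(n_, k - ks) - lchoose(m + n_, k))
  sum(probs[ks >= a])
}

# Independent Wilcoxon enumeration oracle (rank-sum, alternative greater),
# written against the raw definition: enumerate which pooled positions go
# to group x.
oracle_wilcoxon_greater <- function(x, y) {
  pooled <- c(x, y)
  rk <- rank(pooled)
  nx <- length(x)
  obs <- sum(rk[seq_len(nx)])
  sets <- utils::combn(length(pooled), nx)
  stats <- apply(sets, 2, function(s) sum(rk[s]))
  mean(stats >= obs - 1e-9)
}

# Random informative PWM for scanner tests.
random_pwm <- function(id, L, seed, strength = 0.9) {
  withr::with_seed(seed, {
    cons <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    mat <- matrix((1 - strength) / 3, L, 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    mat[cbind(seq_len(L), match(cons, colnames(mat)))] <- strength
    woodnet:::new_pwm(id, mat)
  })
}

random_dna <- function(n, seed, alphabet = c("A", "C", "G", "T")) {
  withr::with_seed(seed,
    paste(sample(alphabet, n, replace = TRUE), collapse = ""))
}

# z-scored log2 profiles without the quantile step: used where a test needs
# exact zero-noise separability of the planted modules (the quantile map is
# rank-based and distorts tiny all-signal datasets).
zscore_norm <- function(expr) {
  m <- log2(as.matrix(expr[-1]) + 1)
  rownames(m) <- expr$gene
  z <- t(apply(m, 1, function(v) if (sd(v) == 0) v * 0 else scale(v)[, 1]))
  colnames(z) <- colnames(m)
  out <- tibble::as_tibble(z)
  out$gene <- rownames(m)
  out[c("gene", setdiff(names(out), "gene"))]
}
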
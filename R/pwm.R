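# Position weight matrices: MEME v4 text I/O, regularization, log-odds
# scanning of promoter windows on both strands, and exact p-values via
# dynamic programming on scores discretized to 1/1000 bit.

new_pwm <- function(id, matrix, background = rep(0.25, 4), family = NA) {
  colnames(matrix) <- DNA_BASES
  structure(list(id = id, matrix = matrix,
                 background = setNames(background, DNA_BASES),
                 family = family),
            class = "woodnet_pwm")
}

#' @export
print.woodnet_pwm <- function(x, ...) {
  cons <- paste(DNA_BASES[apply(x$matrix, 1, which.max)], collapse = "")
  cat("PWM", x$id, "length", nrow(x$matrix), "consensus", cons, "\n")
  invisible(x)
}

#' Regularize a PWM with a pseudocount
#'
#' Adds `pseudocount` to every cell and renormalizes each row to sum to 1.
#'
#' @param pwm a `woodnet_pwm`.
#' @param pseudocount value added per cell (default 0.01).
#' @return the regularized `woodnet_pwm`.
#' @export
pwm_regularize <- function(pwm, pseudocount = 0.01) {
  m <- pwm$matrix + pseudocount
  pwm$matrix <- m / rowSums(m)
  pwm$pseudocount <- pseudocount
  pwm
}

#' Read a MEME (version 4 text) motif file
#'
#' Parses `MOTIF` and `letter-probability matrix` blocks plus the
#' `Background letter frequencies` line. A `family` tag on the MOTIF line
#' (third token) is kept if present.
#'
#' @param path file path.
#' @return named list of `woodnet_pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bases <- toks[is.na(vals)]
    nums <- vals[!is.na(vals)]
    if (length(nums) == 4) bg <- nums[match(DNA_BASES, bases)]
  }
  motif_i <- grep("^MOTIF ", lines)
  pwms <- list()
  for (i in motif_i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    id <- toks[2]
    family <- if (length(toks) >= 3) toks[3] else NA
    j <- i
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j]))
      j <- j + 1
    if (j > length(lines)) abort(paste("no probability matrix for", id))
    w <- sub(".*w= *([0-9]+).*", "\\1", lines[j])
    w <- as.integer(w)
    rows <- lines[(j + 1):(j + w)]
    mat <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    pwms[[id]] <- new_pwm(id, mat, bg, family)
  }
  pwms
}

#' Write PWMs as a MEME (version 4 text) file
#'
#' @param pwms named list of `woodnet_pwm` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$background
  out <- c("MEME version 4", "",
           "ALPHABET= ACGT", "",
           "strands: + -", "",
           "Background letter frequencies",
           paste(sprintf("%s %.5f", DNA_BASES, bg), collapse = " "), "")
  for (p in pwms) {
    hdr <- if (is.na(p$family)) paste("MOTIF", p$id) else
      paste("MOTIF", p$id, p$family)
    out <- c(out, hdr,
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     nrow(p$matrix)),
             apply(p$matrix, 1, function(r) paste(sprintf("%.6f", r),
                                                  collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

# Integer score matrix in millibits: round(1000 * log2(p / bg)) per cell.
pwm_score_matrix <- function(pwm) {
  lw <- log2(sweep(pwm$matrix, 2, pwm$background, "/"))
  round(1000 * lw)
}

# Exact null distribution of the discretized score under the background:
# convolve the per-column score distributions. Returns the support offset
# and the tail function P(score >= s).
pwm_score_distribution <- function(pwm) {
  si <- pwm_score_matrix(pwm)
  bg <- pwm$background
  # iterative convolution on a dense integer grid
  dist <- c(1)   # pmf of the empty prefix: all mass at score 0
  cur_lo <- 0
  for (l in seq_len(nrow(si))) {
    col_scores <- si[l, ]
    new_lo <- cur_lo + min(col_scores)
    new_hi <- cur_lo + length(dist) - 1 + max(col_scores)
    new_dist <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      shift <- cur_lo + col_scores[b] - new_lo
      idx <- seq_along(dist) + shift
      new_dist[idx] <- new_dist[idx] + dist * bg[b]
    }
    dist <- new_dist
    cur_lo <- new_lo
  }
  tail <- rev(cumsum(rev(dist)))
  list(lo = cur_lo, hi = cur_lo + length(dist) - 1, tail = tail)
}

# P(score >= s) for integer millibit scores s (vectorized).
pwm_pvalue <- function(dist, s) {
  idx <- s - dist$lo + 1
  p <- numeric(length(s))
  p[idx <= 1] <- 1
  inside <- idx >= 1 & idx <= length(dist$tail)
  p[inside] <- dist$tail[idx[inside]]
  p[idx > length(dist$tail)] <- 0
  pmin(pmax(p, 0), 1)
}

encode_seq <- function(s) {
  match(strsplit(toupper(s), "")[[1]], DNA_BASES)  # N and others -> NA
}

# Window scores (millibits) for one encoded strand; NA bases contribute 0.
window_scores <- function(idx, si) {
  L <- nrow(si)
  n <- length(idx)
  if (n < L) return(integer(0))
  n_win <- n - L + 1
  scores <- numeric(n_win)
  for (l in seq_len(L)) {
    v <- unname(si[l, ])[idx[l:(l + n_win - 1)]]
    v[is.na(v)] <- 0
    scores <- scores + v
  }
  scores
}

reverse_complement_pwm <- function(pwm) {
  m <- pwm$matrix[rev(seq_len(nrow(pwm$matrix))), rev(seq_len(4)), drop = FALSE]
  colnames(m) <- DNA_BASES
  pwm$matrix <- m
  pwm$background <- setNames(pwm$background[rev(seq_len(4))], DNA_BASES)
  pwm
}

#' Scan promoters with a PWM on both strands
#'
#' Log-odds scores (bits, discretized to 1/1000 bit) at every offset and
#' strand; `N` bases contribute zero. The p-value of a score is the exact
#' tail probability of the discretized score under the background base
#' distribution, computed by dynamic programming. Hits with
#' `p <= p_threshold` are returned. A minus-strand hit's offset is the
#' 0-based position of its leftmost base on the forward window.
#'
#' @param promoters tibble with columns `gene`, `sequence`.
#' @param pwm a `woodnet_pwm` (regularized internally with `pseudocount`).
#' @param p_threshold maximum p-value to report (default 1e-4).
#' @param pseudocount regularization pseudocount (default 0.01).
#' @param background optional length-4 background override (A, C, G, T).
#' @return tibble: gene, motif, offset, strand, score (bits), p_value.
#' @export
scan_pwm <- function(promoters, pwm, p_threshold = 1e-4,
                     pseudocount = 0.01, background = NULL) {
  stopifnot(is.data.frame(promoters),
            all(c("gene", "sequence") %in% names(promoters)),
            inherits(pwm, "woodnet_pwm"))
  if (!is.null(background)) {
    pwm$background <- setNames(background / sum(background), DNA_BASES)
  }
  pwm <- pwm_regularize(pwm, pseudocount)
  si_fwd <- pwm_score_matrix(pwm)
  si_rev <- pwm_score_matrix(reverse_complement_pwm(pwm))
  dist <- pwm_score_distribution(pwm)

  res <- vector("list", nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    idx <- encode_seq(promoters$sequence[i])
    hits_i <- list()
    for (strand in c("+", "-")) {
      si <- if (strand == "+") si_fwd else si_rev
      sc <- window_scores(idx, si)
      if (!length(sc)) next
      p <- pwm_pvalue(dist, sc)
      keep <- which(p <= p_threshold)
      if (length(keep)) {
        hits_i[[strand]] <- tibble(
          gene = promoters$gene[i], motif = pwm$id,
          offset = keep - 1L, strand = strand,
          score = sc[keep] / 1000, p_value = p[keep]
        )
      }
    }
    res[[i]] <- if (length(hits_i)) bind_rows(hits_i) else NULL
  }
  out <- bind_rows(res)
  if (!nrow(out)) {
    out <- tibble(gene = character(), motif = character(), offset = integer(),
                  strand = character(), score = numeric(), p_value = numeric())
  }
  out
}

#' Scan promoters with a PWM library
#'
#' @inheritParams scan_pwm
#' @param pwms named list of `woodnet_pwm` objects.
#' @return row-bound hit tibble over all motifs.
#' @export
scan_pwms <- function(promoters, pwms, p_threshold = 1e-4,
                      pseudocount = 0.01, background = NULL) {
  bind_rows(lapply(pwms, function(p) {
    scan_pwm(promoters, p, p_threshold, pseudocount, background)
  }))
}

#' Gene-by-motif presence matrix
#'
#' @param hits hit tibble from [scan_pwm()]/[scan_pwms()].
#' @param genes all gene ids (rows).
#' @param motifs all motif ids (columns).
#' @return tibble: `gene` + one logical column per motif (TRUE iff >= 1
#'   hit at the threshold the hits were produced with).
#' @export
presence_matrix <- function(hits, genes, motifs) {
  out <- tibble(gene = genes)
  for (m in motifs) {
    hit_genes <- unique(hits$gene[hits$motif == m])
    out[[m]] <- genes %in% hit_genes
  }
  out
}
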
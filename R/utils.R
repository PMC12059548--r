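# Shared internal helpers.

DNA_BASES <- c("A", "C", "G", "T")

#' Extract the numeric matrix from a gene-by-column tibble
#'
#' Many functions carry expression as a tibble with a `gene` column plus one
#' numeric column per sample or fraction. This strips the id column and
#' returns the numeric part with gene rownames.
#' @noRd
expr_matrix <- function(x, id_col = "gene") {
  stopifnot(is.data.frame(x), id_col %in% names(x))
  m <- as.matrix(x[setdiff(names(x), id_col)])
  if (!is.numeric(m)) abort("expression columns must be numeric")
  rownames(m) <- x[[id_col]]
  m
}

#' Rebuild a gene tibble from a matrix
#' @noRd
matrix_to_tibble <- function(m, id_col = "gene") {
  out <- as_tibble(m)
  out[[id_col]] <- rownames(m)
  out[c(id_col, setdiff(names(out), id_col))]
}

#' Check that counts are positive integers, naming the offending field
#' @noRd
check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d (got %s)",
                  field, min, paste(x, collapse = ", ")))
  }
  as.integer(x)
}

check_prob <- function(x, field) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1]", field))
  }
  as.numeric(x)
}

#' Adjusted Rand index between two labelings
#'
#' Used by tests and the acceptance script to compare recovered clusters with
#' planted modules. `NA` labels are treated as one extra class.
#'
#' @param a,b label vectors of equal length; `NA` allowed.
#' @return numeric scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.character(a); b <- as.character(b)
  a[is.na(a)] <- ".NA."; b[is.na(b)] <- ".NA."
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1)
  (sij - expected) / (max_index - expected)
}

#' Run code with a locally seeded RNG, restoring global state afterwards
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
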
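# Strand-aware promoter extraction from a genome FASTA and GFF3 gene models.

#' Extract promoter windows upstream of annotated TSSs
#'
#' For a + strand gene the window is the half-open genomic interval
#' `[TSS - W, TSS)` on the forward strand; for a - strand gene it is
#' `[TSS, TSS + W)` reverse-complemented, where the TSS is the 5' end of
#' the gene feature (GFF3 `start` on +, `end` on -). Windows are clipped at
#' contig boundaries and flagged; `N` bases are preserved. Genes without a
#' strand are skipped with a warning; a contig absent from the FASTA is an
#' error naming it.
#'
#' @param genome a `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param annotation a `GenomicRanges::GRanges` or path to a GFF3 file;
#'   features with `type == feature_type` are used.
#' @param window promoter length W in bp (default 1000).
#' @param feature_type GFF3 feature type holding the gene span
#'   (default "gene"; falls back to "mRNA" if no genes are present).
#' @return tibble: gene, sequence, length, chrom, start, end (1-based,
#'   inclusive, forward-strand coordinates of the window), strand, clipped.
#' @export
extract_promoters <- function(genome, annotation, window = 1000,
                              feature_type = "gene") {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.character(annotation)) {
    annotation <- rtracklayer::import(annotation, format = "gff3")
  }
  gr <- annotation[as.character(annotation$type) == feature_type]
  if (!length(gr) && feature_type == "gene") {
    gr <- annotation[as.character(annotation$type) == "mRNA"]
  }
  if (!length(gr)) abort("no gene features in the annotation")
  ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  if (is.null(ids)) ids <- paste0("feature", seq_along(gr))

  res <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    strand <- as.character(GenomicRanges::strand(gr[i]))
    if (!strand %in% c("+", "-")) {
      warn(sprintf("gene %s has no strand; skipped", ids[i]))
      next
    }
    chrom <- as.character(GenomicRanges::seqnames(gr[i]))
    if (!chrom %in% names(genome)) {
      abort(sprintf("contig %s absent from the genome FASTA", chrom))
    }
    clen <- length(genome[[chrom]])
    if (strand == "+") {
      tss <- GenomicRanges::start(gr[i])      # 1-based first base
      s <- max(1, tss - window)
      e <- tss - 1
    } else {
      tss <- GenomicRanges::end(gr[i])
      s <- tss + 1
      e <- min(clen, tss + window)
    }
    if (e < s) {
      res[[i]] <- tibble(gene = ids[i], sequence = "", length = 0L,
                         chrom = chrom, start = NA_integer_, end = NA_integer_,
                         strand = strand, clipped = TRUE)
      next
    }
    seq <- as.character(Biostrings::subseq(genome[[chrom]], s, e))
    if (strand == "-") seq <- reverse_complement_chr(seq)
    res[[i]] <- tibble(gene = ids[i], sequence = seq, length = nchar(seq),
                       chrom = chrom, start = s, end = e, strand = strand,
                       clipped = nchar(seq) < window)
  }
  bind_rows(res)
}
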
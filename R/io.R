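# Readers and writers for the interchange formats used across the
# pipeline: BED 6+2 peaks, BED12 gene models, FASTA, expression TSV,
# GMT gene sets and RNK ranked lists. Coordinates are 0-based half-open
# on disk (BED convention) and 1-based closed in memory (GRanges).

#' Write peaks as BED 6+2
#'
#' Columns: chrom, start, end, name, score, strand, signal, q_value.
#'
#' @param peaks `GRanges` with name, signal, q_value metadata.
#' @param path Output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = peaks$name %||% sprintf("peak_%05d", seq_along(peaks)),
    score = 0L,
    strand = ".",
    signal = peaks$signal %||% 0,
    q_value = peaks$q_value %||% NA_real_)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks from BED 6+2
#'
#' @param path BED file with signal and q_value as columns 7-8.
#' @return `GRanges` with name, signal, q_value metadata.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(signal = "numeric",
                                          q_value = "numeric"))
  GenomicRanges::strand(gr) <- "*"
  gr
}

#' Write gene models as BED12
#'
#' @param genes `GRanges` with gene_id, strand and `blocks` metadata.
#' @param path Output file.
#' @export
write_genes_bed12 <- function(genes, path) {
  blocks <- genes$blocks
  starts0 <- GenomicRanges::start(genes) - 1L
  block_starts <- vapply(blocks, function(b)
    paste(IRanges::start(b) - 1L, collapse = ","), character(1))
  block_sizes <- vapply(blocks, function(b)
    paste(IRanges::width(b), collapse = ","), character(1))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(genes)),
    start = starts0,
    end = GenomicRanges::end(genes),
    name = genes$gene_id,
    score = 0L,
    strand = as.character(GenomicRanges::strand(genes)),
    thickStart = starts0,
    thickEnd = GenomicRanges::end(genes),
    itemRgb = "0,0,0",
    blockCount = lengths(blocks),
    blockSizes = block_sizes,
    blockStarts = block_starts)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED12
#'
#' @param path BED12 file.
#' @return `GRanges` with gene_id and `blocks` metadata (block starts
#'   relative to the gene start, 1-based, as produced by rtracklayer and
#'   by [generate_annotation()]).
#' @export
read_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr$gene_id <- gr$name
  gr
}

#' Write a genome (or peak sequences) as FASTA
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read FASTA sequences
#' @param path FASTA file.
#' @return `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write an expression table as TSV (plus a sample sheet)
#'
#' @param table An `expression_table`.
#' @param path Expression TSV (gene_id column then one column per
#'   sample).
#' @param samples_path Sample sheet TSV (sample_id, condition); defaults
#'   to `<path>.samples.tsv`.
#' @export
write_expression_tsv <- function(table, path,
                                 samples_path = paste0(path, ".samples.tsv")) {
  df <- data.frame(gene_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(table$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an expression table from TSV
#'
#' @param path Expression TSV written by [write_expression_tsv()].
#' @param samples_path Sample sheet TSV.
#' @return An `expression_table`.
#' @export
read_expression_tsv <- function(path,
                                samples_path = paste0(path, ".samples.tsv")) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  samples <- read.table(samples_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  expression_table(m, samples)
}

#' Write gene sets as GMT
#'
#' One set per line: id, description, then member genes, tab-separated.
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output file.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(id) {
    paste(c(id, id, gene_sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' Write a ranked list as a two-column RNK TSV
#' @param ranked A `ranked_list`.
#' @param path Output file.
#' @export
write_rnk <- function(ranked, path) {
  write.table(ranked[, c("gene_id", "score")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a ranked list from an RNK TSV
#' @param path Two-column TSV (gene_id, score).
#' @return A `ranked_list` sorted by non-increasing score, ties broken
#'   by gene id.
#' @export
read_rnk <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("gene_id", "score"),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$gene_id), ]
  rownames(df) <- NULL
  class(df) <- c("ranked_list", "data.frame")
  df
}
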
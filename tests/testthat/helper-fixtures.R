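# Shared fixture builders and brute-force oracles. Everything is
# generated in code; no data files.

make_peaks <- function(chrom, start, end, name = NULL, q_value = 0,
                       signal = 10) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  gr$name <- name %||% sprintf("p%03d", seq_along(gr))
  gr$q_value <- rep_len(q_value, length(gr))
  gr$signal <- rep_len(signal, length(gr))
  gr
}

make_genes <- function(chrom, start, end, strand, gene_id = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  gr$gene_id <- gene_id %||% sprintf("g%03d", seq_along(gr))
  gr$name <- gr$gene_id
  gr$blocks <- IRanges::IRangesList(lapply(GenomicRanges::width(gr),
                                           function(w) IRanges::IRanges(1, w)))
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_peak_fixture <- function(n, chrom_length = 1e5, width_range = c(50, 300),
                                chroms = "chr1", seed = 1) {
  set.seed(seed)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  st <- sample.int(chrom_length - max(w), n, replace = TRUE)
  make_peaks(sample(chroms, n, replace = TRUE), st, st + w - 1)
}

# O(n*m) all-pairs assignment checker mirroring the promoter-window rule
brute_force_assign <- function(peaks, genes, upstream_bp = 3000) {
  out <- list()
  for (i in seq_along(peaks)) {
    for (j in seq_along(genes)) {
      if (as.character(GenomicRanges::seqnames(peaks)[i]) !=
          as.character(GenomicRanges::seqnames(genes)[j])) next
      gs <- GenomicRanges::start(genes)[j]
      ge <- GenomicRanges::end(genes)[j]
      if (as.character(GenomicRanges::strand(genes)[j]) == "-") {
        ws <- gs; we <- ge + upstream_bp
      } else {
        ws <- max(gs - upstream_bp, 1); we <- ge
      }
      ps <- GenomicRanges::start(peaks)[i]
      pe <- GenomicRanges::end(peaks)[i]
      if (ps <= we && pe >= ws) {
        out[[length(out) + 1L]] <- data.frame(
          peak_id = peaks$name[i], gene_id = genes$gene_id[j],
          relation = if (ps <= ge && pe >= gs) "inside" else "upstream",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(peak_id = character(0), gene_id = character(0),
               relation = character(0), stringsAsFactors = FALSE)
}

# O(n*m) nearest edge-gap distances (0 for overlap/adjacency)
brute_force_distances <- function(peaks_a, peaks_b) {
  d <- rep(Inf, length(peaks_a))
  for (i in seq_along(peaks_a)) {
    for (j in seq_along(peaks_b)) {
      if (as.character(GenomicRanges::seqnames(peaks_a)[i]) !=
          as.character(GenomicRanges::seqnames(peaks_b)[j])) next
      as_ <- GenomicRanges::start(peaks_a)[i]; ae <- GenomicRanges::end(peaks_a)[i]
      bs <- GenomicRanges::start(peaks_b)[j]; be <- GenomicRanges::end(peaks_b)[j]
      gap <- if (bs > ae) bs - ae - 1 else if (as_ > be) as_ - be - 1 else 0
      d[i] <- min(d[i], gap)
    }
  }
  d
}

# direct summation of the hypergeometric upper tail from binomial
# coefficients, independent of phyper
oracle_hypergeom_tail <- function(k, N, K, n) {
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

random_expression_fixture <- function(n_genes = 50, seed = 1, noise_sd = 0.3) {
  set.seed(seed)
  ids <- sprintf("g%04d", seq_len(n_genes))
  m <- matrix(2^rnorm(n_genes * 4, 4, 1 + noise_sd), nrow = n_genes,
              dimnames = list(ids, c("A_r1", "A_r2", "B_r1", "B_r2")))
  expression_table(m, data.frame(
    sample_id = colnames(m),
    condition = c("A", "A", "B", "B"), stringsAsFactors = FALSE))
}
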
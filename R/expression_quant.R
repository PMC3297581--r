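#' Expression table container
#'
#' A gene x sample matrix of non-negative RPKM values with a sample
#' sheet assigning each sample to a condition. Every gene is present in
#' every sample and each condition has at least one sample.
#'
#' @param values Numeric matrix (genes x samples) with rownames (gene
#'   ids) and colnames (sample ids); all values must be >= 0.
#' @param samples data.frame with columns `sample_id`, `condition`,
#'   matching the matrix columns.
#' @return Object of class `expression_table`.
#' @export
expression_table <- function(values, samples) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must be a matrix with gene rownames and sample colnames")
  if (any(values < 0)) stop("rpkm values must be non-negative")
  if (!all(c("sample_id", "condition") %in% names(samples)))
    stop("samples needs sample_id and condition columns")
  if (!identical(sort(colnames(values)), sort(samples$sample_id)))
    stop("sample sheet does not match matrix columns")
  samples <- samples[match(colnames(values), samples$sample_id), ]
  if (length(unique(samples$condition)) < 1L) stop("need at least one condition")
  structure(list(values = values, samples = samples),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", unique(x$samples$condition),
                            table(x$samples$condition)[unique(x$samples$condition)]),
                    collapse = ", ")))
  invisible(x)
}

#' Per-condition mean RPKM
#'
#' @param table An `expression_table`.
#' @return Matrix genes x conditions of arithmetic mean RPKM.
#' @export
condition_means <- function(table) {
  stopifnot(is(table, "expression_table"))
  conds <- unique(table$samples$condition)
  out <- vapply(conds, function(cc) {
    rowMeans(table$values[, table$samples$condition == cc, drop = FALSE])
  }, numeric(nrow(table$values)))
  colnames(out) <- conds
  out
}

#' Allocate multireads to exons proportionally to unique-read density
#'
#' Each multiread group's count is split across its candidate exons in
#' proportion to the unique counts observed on those exons; when all
#' candidates have zero unique counts the split is uniform. The total
#' read mass is conserved exactly.
#'
#' @param unique_exon_counts data.frame with columns `exon_id`, `count`
#'   (and optionally gene_id/length, carried through).
#' @param multiread_groups data.frame with columns `group_id`, `exon_id`,
#'   `reads`, where `reads` is the group's total read count repeated on
#'   each member row.
#' @return data.frame of `unique_exon_counts` with added columns
#'   `allocated` (fractional multiread mass) and `total`.
#' @export
allocate_multireads <- function(unique_exon_counts, multiread_groups) {
  u <- unique_exon_counts
  if (any(u$count < 0)) stop("unique counts must be non-negative")
  if (nrow(multiread_groups) > 0) {
    if (any(multiread_groups$reads < 0)) stop("multiread counts must be non-negative")
    unknown <- setdiff(multiread_groups$exon_id, u$exon_id)
    if (length(unknown))
      stop("multiread group references unknown exon(s): ",
           paste(head(unknown, 5), collapse = ", "))
  }
  alloc <- setNames(numeric(nrow(u)), u$exon_id)
  if (nrow(multiread_groups) > 0) {
    for (g in split(multiread_groups, multiread_groups$group_id)) {
      reads <- unique(g$reads)
      if (length(reads) != 1L)
        stop("group ", g$group_id[1], " has inconsistent read counts")
      wts <- u$count[match(g$exon_id, u$exon_id)]
      frac <- if (sum(wts) == 0) rep(1 / nrow(g), nrow(g)) else wts / sum(wts)
      alloc[g$exon_id] <- alloc[g$exon_id] + reads * frac
    }
  }
  u$allocated <- unname(alloc)
  u$total <- u$count + u$allocated
  u
}

#' Reads per kilobase of exonic transcript per million mapped reads
#'
#' `rpkm = count / (exonic_length_bp/1000) / (total_mapped_reads/1e6)`.
#' The exonic length is the union of a gene's exons, not its genomic
#' span; fractional counts from multiread allocation flow through
#' unchanged.
#'
#' @param per_gene_counts Named numeric vector of (possibly fractional)
#'   read counts per gene.
#' @param exonic_length_bp Named numeric vector of exonic lengths,
#'   aligned with `per_gene_counts`.
#' @param total_mapped_reads Total mapped reads in the library.
#' @return Named numeric vector of RPKM values.
#' @export
compute_rpkm <- function(per_gene_counts, exonic_length_bp, total_mapped_reads) {
  if (total_mapped_reads <= 0) stop("total_mapped_reads must be positive")
  if (length(per_gene_counts) != length(exonic_length_bp))
    stop("counts and lengths must align")
  bad <- which(exonic_length_bp <= 0)
  if (length(bad))
    stop("zero exonic length for gene(s): ",
         paste(head(names(per_gene_counts)[bad] %||% bad, 5), collapse = ", "))
  per_gene_counts / (exonic_length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Quantify genes from exon counts and multiread groups
#'
#' Convenience wrapper: allocates multireads, sums exon totals per gene,
#' computes union exonic lengths from the annotation, and returns RPKM.
#'
#' @param genes `GRanges` with `gene_id` and `blocks` (exon) metadata.
#' @param unique_counts,multiread_groups As in [allocate_multireads()].
#' @param total_mapped_reads Library size used for normalisation.
#' @return data.frame gene_id, count, exonic_length, rpkm.
#' @export
quantify_genes <- function(genes, unique_counts, multiread_groups,
                           total_mapped_reads) {
  alloc <- allocate_multireads(unique_counts, multiread_groups)
  gene_counts <- tapply(alloc$total, alloc$gene_id, sum)
  exonic_len <- setNames(
    vapply(genes$blocks, function(b) sum(IRanges::width(IRanges::reduce(b))),
           numeric(1)),
    genes$gene_id)
  ids <- names(exonic_len)
  counts <- setNames(numeric(length(ids)), ids)
  counts[names(gene_counts)] <- gene_counts
  data.frame(gene_id = ids,
             count = unname(counts),
             exonic_length = unname(exonic_len),
             rpkm = unname(compute_rpkm(counts, exonic_len, total_mapped_reads)),
             stringsAsFactors = FALSE)
}

#' Call differential genes by fold change with a minimum-expression floor
#'
#' A gene is differential iff the larger condition mean divided by the
#' smaller is at least `fold_threshold` AND both condition means reach
#' `min_rpkm`. Direction follows the larger mean. Replicates are
#' summarised by the arithmetic mean per condition.
#'
#' @param table An `expression_table` with exactly two conditions.
#' @param fold_threshold Fold-change threshold (> 1), default 2.
#' @param min_rpkm Minimum mean RPKM required in both conditions,
#'   default 2.
#' @param condition_a Condition treated as "A" (numerator); defaults to
#'   the first condition in the sample sheet.
#' @return data.frame gene_id, mean_a, mean_b, fold_change (A over B),
#'   direction (up_in_A/up_in_B/unchanged), passes_min_expression, is_de.
#' @export
call_differential <- function(table, fold_threshold = 2, min_rpkm = 2,
                              condition_a = NULL) {
  stopifnot(is(table, "expression_table"))
  if (fold_threshold <= 1) stop("fold_threshold must exceed 1")
  conds <- unique(table$samples$condition)
  if (length(conds) != 2L) stop("exactly two conditions required")
  condition_a <- condition_a %||% conds[1]
  if (!condition_a %in% conds) stop("missing condition: ", condition_a)
  condition_b <- setdiff(conds, condition_a)
  m <- condition_means(table)
  mean_a <- m[, condition_a]
  mean_b <- m[, condition_b]
  ratio <- pmax(mean_a, mean_b) / pmin(mean_a, mean_b)
  ratio[pmax(mean_a, mean_b) == 0] <- 1       # both zero: unchanged
  passes_min <- mean_a >= min_rpkm & mean_b >= min_rpkm
  is_de <- ratio >= fold_threshold & passes_min
  fc <- ifelse(mean_a == 0 & mean_b == 0, 1, mean_a / mean_b)
  direction <- ifelse(!is_de, "unchanged",
                      ifelse(mean_a > mean_b, "up_in_A", "up_in_B"))
  data.frame(gene_id = rownames(m), mean_a = unname(mean_a),
             mean_b = unname(mean_b), fold_change = unname(fc),
             direction = direction,
             passes_min_expression = unname(passes_min),
             is_de = unname(is_de),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene Z-score display transform
#'
#' `Z = (x - mu) / sigma` where x is log2(rpkm + pseudocount) and mu,
#' sigma are the mean and sample standard deviation of the gene across
#' samples. Genes with sigma = 0 map to all-zero rows.
#'
#' @param table An `expression_table`.
#' @param pseudocount Added before log2 (default 0.5).
#' @return Matrix of Z scores, same dimensions as the input values.
#' @export
zscore_transform <- function(table, pseudocount = 0.5) {
  stopifnot(is(table, "expression_table"))
  x <- log2(table$values + pseudocount)
  mu <- rowMeans(x)
  sigma <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(sigma == 0, 1, sigma)
  z[sigma == 0, ] <- 0
  z
}

#' Rank genes by fold change between the two conditions
#'
#' Score is `log2((mean_A + eps)/(mean_B + eps))`; genes are sorted by
#' decreasing score so the most up-regulated genes in condition A are at
#' the top, with ties broken lexicographically by gene id so the order
#' is strict and deterministic.
#'
#' @param table An `expression_table` with two conditions.
#' @param condition_a Condition placed at the top of the list; defaults
#'   to the first condition in the sample sheet.
#' @param pseudocount Added to both means before the ratio (default 0.5).
#' @return data.frame of class `ranked_list` with columns gene_id, score
#'   (non-increasing).
#' @export
rank_by_fold_change <- function(table, condition_a = NULL, pseudocount = 0.5) {
  stopifnot(is(table, "expression_table"))
  conds <- unique(table$samples$condition)
  if (length(conds) != 2L) stop("exactly two conditions required")
  condition_a <- condition_a %||% conds[1]
  condition_b <- setdiff(conds, condition_a)
  m <- condition_means(table)
  score <- log2((m[, condition_a] + pseudocount) /
                (m[, condition_b] + pseudocount))
  ord <- order(-score, rownames(m))
  out <- data.frame(gene_id = rownames(m)[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}
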
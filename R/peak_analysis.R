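#' Filter peaks by q-value
#'
#' Retains peaks whose multiple-testing-corrected significance (q-value)
#' is at or below the threshold, preserving input order.
#'
#' @param peaks `GRanges` with a `q_value` metadata column.
#' @param q_threshold Significance cutoff in (0, 1]; default 0.001.
#' @return The retained subset of `peaks`.
#' @export
filter_peaks <- function(peaks, q_threshold = 0.001) {
  stopifnot(is(peaks, "GRanges"), !is.null(peaks$q_value))
  if (q_threshold <= 0 || q_threshold > 1)
    stop("q_threshold must lie in (0, 1]")
  peaks[peaks$q_value <= q_threshold]
}

#' Assign peaks to genes by promoter-window or gene-body overlap
#'
#' A peak is assigned to a gene if it overlaps the gene body (exonic and
#' intronic regions alike) or the window extending `upstream_bp` from the
#' transcription start site. Upstream is strand-aware: the TSS of a minus
#' strand gene is its right end and the window extends rightward. A peak
#' may be assigned to several genes; the per-factor target gene set is
#' the union of assigned genes.
#'
#' @param peaks `GRanges` of peaks with a `name` column (ids generated if
#'   absent).
#' @param genes `GRanges` of gene models with `gene_id` and strand.
#' @param upstream_bp Upstream window in bp (default 3000).
#' @return List of class `target_assignment`: `assignments` (data.frame
#'   peak_id, gene_id, relation in {upstream, inside}), `target_genes`
#'   (sorted unique gene ids), `n_peaks`, `n_assigned`,
#'   `fraction_assigned`, `unassigned_peaks`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, upstream_bp = 3000) {
  stopifnot(is(peaks, "GRanges"), is(genes, "GRanges"),
            !is.null(genes$gene_id))
  if (upstream_bp < 0) stop("upstream_bp must be non-negative")
  peak_ids <- peaks$name %||% sprintf("peak_%05d", seq_along(peaks))
  missing_chrom <- !as.character(GenomeInfoDb::seqnames(peaks)) %in%
    as.character(GenomeInfoDb::seqlevelsInUse(genes))
  if (any(missing_chrom))
    warning(sprintf("%d peak(s) on chromosome(s) absent from the annotation; counted unassigned",
                    sum(missing_chrom)))
  # strand-aware upstream extension of the gene span (clamped at 1)
  ext_start <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                      GenomicRanges::start(genes),
                      pmax(GenomicRanges::start(genes) - upstream_bp, 1L))
  ext_end <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                    GenomicRanges::end(genes) + upstream_bp,
                    GenomicRanges::end(genes))
  ext <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                IRanges::IRanges(ext_start, ext_end))
  p <- GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(peaks)),
                              IRanges::ranges(peaks))
  hits <- GenomicRanges::findOverlaps(
    p, ext, ignore.strand = TRUE,
    type = "any", minoverlap = 1L)
  # relation: a peak touching the gene body records the more specific "inside"
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  in_body <- GenomicRanges::start(p)[q] <= GenomicRanges::end(genes)[s] &
    GenomicRanges::end(p)[q] >= GenomicRanges::start(genes)[s]
  assignments <- data.frame(
    peak_id = peak_ids[q],
    gene_id = genes$gene_id[s],
    relation = ifelse(in_body, "inside", "upstream"),
    stringsAsFactors = FALSE)
  assigned <- unique(assignments$peak_id)
  structure(list(
    assignments = assignments,
    target_genes = sort(unique(assignments$gene_id)),
    n_peaks = length(peaks),
    n_assigned = length(assigned),
    fraction_assigned = if (length(peaks)) length(assigned) / length(peaks) else NA_real_,
    unassigned_peaks = setdiff(peak_ids, assigned)
  ), class = "target_assignment")
}

#' @export
print.target_assignment <- function(x, ...) {
  cat(sprintf("target assignment: %d/%d peaks assigned (%.1f%%) to %d target genes\n",
              x$n_assigned, x$n_peaks, 100 * x$fraction_assigned,
              length(x$target_genes)))
  invisible(x)
}
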
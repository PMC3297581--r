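#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of at least
#' k common elements when a set of size n is drawn without replacement
#' from a universe of N elements of which K are marked. Computed through
#' the log-space machinery of [stats::phyper()], which stays accurate at
#' the extreme tails that arise for genome-scale overlaps.
#'
#' @param k Observed overlap(s); may be a vector.
#' @param N Universe size.
#' @param K Size of the first (marked) set.
#' @param n Size of the second (drawn) set.
#' @return Probability in (0, 1]; exactly 1 when k = 0.
#' @export
hypergeom_tail <- function(k, N, K, n) {
  if (K > N || n > N) stop("K and n must not exceed N")
  if (any(k < 0) || any(k > pmin(K, n)))
    stop("k must lie in [0, min(K, n)]")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Target-set overlap with hypergeometric significance
#'
#' Intersects two target gene sets within a universe, reporting raw and
#' truncated whole-number percentages (72.59\% prints as 72, matching
#' the field's reporting convention) and the hypergeometric upper-tail
#' p-value of the intersection.
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe Character vector of all gene ids considered.
#' @return List of class `cobind_overlap`: n_targets_a, n_targets_b,
#'   n_common, universe_size, pct_of_a, pct_of_b (truncated integers),
#'   pct_of_a_raw, pct_of_b_raw, hypergeom_p, common_genes.
#' @export
target_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  off <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(off))
    stop("set element(s) outside universe: ",
         paste(head(off, 10), collapse = ", "))
  common <- intersect(set_a, set_b)
  k <- length(common)
  structure(list(
    n_targets_a = length(set_a),
    n_targets_b = length(set_b),
    n_common = k,
    universe_size = length(universe),
    pct_of_a = trunc_pct(k, length(set_a)),
    pct_of_b = trunc_pct(k, length(set_b)),
    pct_of_a_raw = if (length(set_a)) 100 * k / length(set_a) else NA_real_,
    pct_of_b_raw = if (length(set_b)) 100 * k / length(set_b) else NA_real_,
    hypergeom_p = hypergeom_tail(k, length(universe), length(set_a),
                                 length(set_b)),
    common_genes = sort(common)
  ), class = "cobind_overlap")
}

#' @export
print.cobind_overlap <- function(x, ...) {
  cat(sprintf(
    "target overlap: %d common of %d (A) and %d (B) in universe %d\n  %d%% of A, %d%% of B; hypergeometric p = %.6g\n",
    x$n_common, x$n_targets_a, x$n_targets_b, x$universe_size,
    x$pct_of_a, x$pct_of_b, x$hypergeom_p))
  invisible(x)
}

#' Nearest-peak distances between two peak sets
#'
#' For every A peak, the distance to the nearest B peak on the same
#' chromosome: 0 when any B peak overlaps (or is immediately adjacent to)
#' the A peak, otherwise the minimum edge gap in bp. A peaks on
#' chromosomes with no B peaks receive distance `Inf`; they are excluded
#' from the windowed numerator but counted in its denominator. The
#' windowed summary counts distances `<= window_bp` (inclusive, i.e.
#' "within" the window).
#'
#' @param peaks_a,peaks_b Non-empty `GRanges`.
#' @param window_bp Proximity window in bp (default 500).
#' @param hist_breaks Bin edges (bp) for the distance histogram.
#' @return List of class `peak_distances`: `distances` (per A peak, in A
#'   order), `n_within_window`, `window_bp`, `fraction_within`, and
#'   `histogram` (data.frame bin_start, bin_end, count; finite distances
#'   beyond the last break fall in an open-ended final bin).
#' @export
nearest_peak_distances <- function(peaks_a, peaks_b, window_bp = 500,
                                   hist_breaks = seq(0, 5000, by = 250)) {
  stopifnot(is(peaks_a, "GRanges"), is(peaks_b, "GRanges"))
  if (length(peaks_a) == 0L) stop("A peak set is empty")
  if (length(peaks_b) == 0L) stop("B peak set is empty")
  shared <- intersect(as.character(GenomeInfoDb::seqlevelsInUse(peaks_a)),
                      as.character(GenomeInfoDb::seqlevelsInUse(peaks_b)))
  a <- GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(peaks_a)),
                              IRanges::ranges(peaks_a))
  b <- GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(peaks_b)),
                              IRanges::ranges(peaks_b))
  d <- rep(Inf, length(a))
  if (length(shared) == 0L) {
    warning("no shared chromosome between the peak sets; all distances Inf")
  } else {
    # seqlevels-mismatch warnings are expected: unmatched chromosomes are
    # handled explicitly as Inf distances
    hits <- suppressWarnings(
      GenomicRanges::distanceToNearest(a, b, ignore.strand = TRUE))
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  }
  n_within <- sum(d <= window_bp)
  fin <- d[is.finite(d)]
  edges <- unique(c(hist_breaks, Inf))
  counts <- as.vector(table(cut(fin, breaks = edges, right = FALSE,
                                include.lowest = TRUE)))
  histogram <- data.frame(bin_start = head(edges, -1),
                          bin_end = edges[-1],
                          count = counts)
  structure(list(
    distances = d,
    n_peaks_a = length(a),
    n_within_window = n_within,
    window_bp = window_bp,
    fraction_within = n_within / length(a),
    histogram = histogram
  ), class = "peak_distances")
}

#' @export
print.peak_distances <- function(x, ...) {
  cat(sprintf(
    "nearest-peak distances: %d/%d A peaks (%.1f%%) within %d bp of a B peak\n",
    x$n_within_window, x$n_peaks_a, 100 * x$fraction_within, x$window_bp))
  invisible(x)
}

#' Assemble the three-approach co-binding report
#'
#' Combines the target-set overlap (with hypergeometric significance)
#' and the nearest-peak proximity summary into a single report of the
#' statistics used to establish co-regulation by two factors.
#'
#' @param targets_a,targets_b Target gene sets of the two factors.
#' @param universe Gene universe for the hypergeometric test.
#' @param peaks_a,peaks_b Filtered peak sets (`GRanges`).
#' @param window_bp Proximity window (default 500).
#' @param motif_occurrence Optional `motif_occurrence` object whose
#'   per-factor union fractions are folded into the report.
#' @return List of class `cobinding_report` with `overlap`, `proximity`
#'   and optional `motif_fractions` components.
#' @export
cobinding_report <- function(targets_a, targets_b, universe,
                             peaks_a, peaks_b, window_bp = 500,
                             motif_occurrence = NULL) {
  overlap <- target_overlap(targets_a, targets_b, universe)
  proximity <- nearest_peak_distances(peaks_a, peaks_b, window_bp = window_bp)
  motif_fractions <- NULL
  if (!is.null(motif_occurrence) &&
      identical(motif_occurrence$status, "ok")) {
    motif_fractions <- as.list(motif_occurrence$fraction_per_factor)
  }
  structure(list(overlap = overlap, proximity = proximity,
                 motif_fractions = motif_fractions),
            class = "cobinding_report")
}

#' @export
print.cobinding_report <- function(x, ...) {
  print(x$overlap)
  print(x$proximity)
  if (!is.null(x$motif_fractions)) {
    for (f in names(x$motif_fractions))
      cat(sprintf("  motif union occurrence (%s): %.1f%%\n",
                  f, 100 * x$motif_fractions[[f]]))
  }
  invisible(x)
}
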
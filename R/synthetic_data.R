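#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the study conditions the analysis was designed for:
#' a genome-scale gene universe (5000 genes on a 40 Mb chromosome), two
#' peak sets with a 48\% co-bound fraction at half-normal edge distances
#' (sd 150 bp), motif occurrence rates of 0.44/0.54 for the two planted
#' factors, a 2+2 replicate expression design with 300 up- and 300
#' down-regulated genes at a 2 log2-unit effect, 80\% of up-regulated
#' genes drawn from the designated target set, and replicate noise of
#' 0.25 log2 units.
#'
#' @param seed Root seed; every generator derives its own stream from it.
#' @param n_genes Number of genes to place.
#' @param chrom_length Chromosome length in bp.
#' @param n_chroms Number of chromosomes (genes split evenly across them).
#' @param n_peaks_a,n_peaks_b True peak counts for factors A and B.
#' @param cobind_fraction Fraction of A peaks given a nearby B partner.
#' @param cobind_distance_sd SD (bp) of the half-normal edge-distance
#'   kernel for co-bound pairs.
#' @param peak_width Peak width in bp (fixed width).
#' @param decoy_fraction Fraction of extra decoy peaks (q-value > 0.001)
#'   appended to each set.
#' @param motif_occurrence Named proportions: fraction of peaks receiving
#'   one planted instance of each motif id.
#' @param n_up,n_down Differentially expressed gene counts.
#' @param target_up_bias Fraction of up-regulated genes drawn from the
#'   target set.
#' @param fold_change_magnitude Planted effect size in log2 units.
#' @param noise_sd Replicate noise in log2 units.
#' @param n_replicates Replicates per condition.
#' @param conditions Labels of the two conditions (A first).
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2 expression.
#' @param multiread_fraction Fraction of the read library mapping to
#'   multiple locations.
#' @param library_size Total simulated mapped reads.
#' @param n_multiread_groups Number of multiread equivalence groups.
#' @param gene_length_range Min/max gene length in bp.
#' @param base_composition Genome base probabilities (A,C,G,T).
#' @return Validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_genes = 5000,
                         chrom_length = 4e7,
                         n_chroms = 1,
                         n_peaks_a = 5000,
                         n_peaks_b = 6000,
                         cobind_fraction = 0.48,
                         cobind_distance_sd = 150,
                         peak_width = 250,
                         decoy_fraction = 0.1,
                         motif_occurrence = c(TCF7_v1 = 0.44, RUNX1_v1 = 0.54),
                         n_up = 300,
                         n_down = 300,
                         target_up_bias = 0.8,
                         fold_change_magnitude = 2,
                         noise_sd = 0.25,
                         n_replicates = 2,
                         conditions = c("CD34pos", "CD34neg"),
                         baseline_log2_mean = 5,
                         baseline_log2_sd = 1.5,
                         multiread_fraction = 0.15,
                         library_size = 1e6,
                         n_multiread_groups = 200,
                         gene_length_range = c(1000, 4000),
                         base_composition = rep(0.25, 4)) {
  cfg <- as.list(environment())
  props <- c(cfg$cobind_fraction, cfg$decoy_fraction, cfg$motif_occurrence,
             cfg$target_up_bias, cfg$multiread_fraction)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]")
  counts <- c(cfg$chrom_length, cfg$n_peaks_a, cfg$n_peaks_b,
              cfg$peak_width, cfg$n_replicates, cfg$library_size)
  if (any(counts <= 0)) stop("counts and lengths must be positive")
  if (cfg$n_genes < 0 || cfg$n_up < 0 || cfg$n_down < 0)
    stop("gene counts must be non-negative")
  if (cfg$n_up + cfg$n_down > cfg$n_genes)
    stop("n_up + n_down must not exceed n_genes")
  if (length(cfg$conditions) != 2L) stop("exactly two conditions required")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic gene annotation and genome
#'
#' Places stranded, non-overlapping genes with pairwise gaps and terminal
#' flanks of at least 3000 bp, each with 1-4 exons spanning the gene ends,
#' on an i.i.d. background genome of configurable base composition.
#' Deterministic given the config seed.
#'
#' @param cfg A `synth_config`.
#' @return List with `genes` (a `GRanges` with `gene_id`, `name` and
#'   BED12-style `blocks` metadata) and `genome` (a `DNAStringSet`).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(is(cfg, "synth_config"))
  with_seed(derive_seed(cfg$seed, "annotation"), {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    genome <- Biostrings::DNAStringSet(vapply(
      chroms, function(ch) random_dna(cfg$chrom_length, cfg$base_composition),
      character(1)))
    names(genome) <- chroms
    per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
    all_genes <- list()
    gid <- 0L
    for (ci in seq_len(cfg$n_chroms)) {
      ng <- per_chrom[ci]
      if (ng == 0L) next
      lens <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                     ng, replace = TRUE)
      min_gap <- 3000
      slack <- cfg$chrom_length - sum(lens) - (ng + 1) * min_gap
      if (slack < 0)
        stop(sprintf(
          "capacity error: cannot place %d genes with >=3 kb gaps on a %d bp chromosome",
          ng, as.integer(cfg$chrom_length)))
      u <- runif(ng + 1)
      extra <- floor(slack * u / sum(u))
      gaps <- min_gap + extra
      starts <- cumsum(gaps[seq_len(ng)]) + cumsum(c(0, head(lens, -1))) + 1
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      blocks <- lapply(lens, function(len) {
        k <- sample.int(4L, 1L)
        nb <- 2L * k - 1L                     # exon,intron,...,exon
        rw <- runif(nb) + 0.2
        widths <- pmax(floor(len * rw / sum(rw)), 1L)
        widths[nb] <- widths[nb] + (len - sum(widths))
        if (widths[nb] < 1L) { widths <- c(len); nb <- 1L }
        ends <- cumsum(widths)
        starts_b <- ends - widths + 1L
        keep <- seq(1L, nb, by = 2L)
        IRanges::IRanges(start = starts_b[keep], end = ends[keep])
      })
      ids <- sprintf("gene_%05d", gid + seq_len(ng))
      gid <- gid + ng
      gr <- GenomicRanges::GRanges(
        seqnames = chroms[ci],
        ranges = IRanges::IRanges(start = starts, width = lens),
        strand = strand)
      gr$gene_id <- ids
      gr$name <- ids
      gr$blocks <- IRanges::IRangesList(blocks)
      all_genes[[ci]] <- gr
    }
    genes <- if (length(all_genes)) do.call(c, all_genes) else
      GenomicRanges::GRanges(gene_id = character(0), name = character(0))
    GenomeInfoDb::seqlevels(genes) <- chroms
    GenomeInfoDb::seqlengths(genes) <- rep(cfg$chrom_length, cfg$n_chroms)
    list(genes = genes, genome = genome)
  })
}

# uniform peak placement helper (1-based closed coordinates)
place_uniform_peaks <- function(n, chroms, chrom_length, width) {
  if (n == 0L)
    return(GenomicRanges::GRanges())
  ch <- sample(chroms, n, replace = TRUE)
  st <- sample.int(chrom_length - width, n, replace = TRUE)
  GenomicRanges::GRanges(ch, IRanges::IRanges(start = st, width = width))
}

#' Generate two peak sets with planted co-binding
#'
#' Exactly `round(cobind_fraction * n_peaks_a)` A peaks receive a partner
#' B peak whose edge distance is drawn from a half-normal kernel
#' `|Normal(0, cobind_distance_sd)|`; all remaining peaks are placed
#' uniformly. True peaks carry q-values below 0.001; a `decoy_fraction`
#' of extra peaks with q-values above 0.001 is appended to each set so
#' that significance filtering restores the true sets exactly.
#'
#' @param cfg A `synth_config`.
#' @param annotation Output of [generate_annotation()] (used for
#'   chromosome names and bounds).
#' @return List: `peaks_a`, `peaks_b` (`GRanges` with name, signal,
#'   q_value), and `truth` (data.frame peak_a, peak_b, planted_gap).
#' @export
generate_peak_sets <- function(cfg, annotation) {
  stopifnot(is(cfg, "synth_config"))
  n_cobind <- round(cfg$cobind_fraction * cfg$n_peaks_a)
  if (n_cobind > cfg$n_peaks_b)
    stop("cobind_fraction * n_peaks_a exceeds n_peaks_b")
  chroms <- names(annotation$genome)
  L <- cfg$chrom_length
  w <- cfg$peak_width
  with_seed(derive_seed(cfg$seed, "peaks"), {
    peaks_a <- place_uniform_peaks(cfg$n_peaks_a, chroms, L, w)
    peaks_a$name <- sprintf("A_%05d", seq_len(cfg$n_peaks_a))
    cob_idx <- sample.int(cfg$n_peaks_a, n_cobind)
    gaps <- round(abs(rnorm(n_cobind, 0, cfg$cobind_distance_sd)))
    side <- sample(c(-1L, 1L), n_cobind, replace = TRUE)
    a_start <- GenomicRanges::start(peaks_a)[cob_idx]
    a_end <- GenomicRanges::end(peaks_a)[cob_idx]
    b_start <- ifelse(side > 0, a_end + gaps + 1L, a_start - gaps - w)
    # flip side when the partner would fall off the chromosome
    flip <- b_start < 1L | (b_start + w - 1L) > L
    b_start[flip] <- ifelse(side[flip] > 0,
                            a_start[flip] - gaps[flip] - w,
                            a_end[flip] + gaps[flip] + 1L)
    b_start <- pmin(pmax(b_start, 1L), L - w)
    partner <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(peaks_a)[cob_idx],
      IRanges::IRanges(start = b_start, width = w))
    free_b <- place_uniform_peaks(cfg$n_peaks_b - n_cobind, chroms, L, w)
    peaks_b <- c(partner, free_b)
    peaks_b$name <- sprintf("B_%05d", seq_len(cfg$n_peaks_b))
    peaks_a$q_value <- runif(length(peaks_a)) * 0.001
    peaks_b$q_value <- runif(length(peaks_b)) * 0.001
    peaks_a$signal <- 10 + rnorm(length(peaks_a), 0, 2)
    peaks_b$signal <- 10 + rnorm(length(peaks_b), 0, 2)
    add_decoys <- function(pk, prefix) {
      nd <- round(cfg$decoy_fraction * length(pk))
      if (nd == 0L) return(pk)
      d <- place_uniform_peaks(nd, chroms, L, w)
      d$name <- sprintf("%s_decoy_%05d", prefix, seq_len(nd))
      d$q_value <- 0.001 + runif(nd) * 0.049
      d$signal <- 2 + rnorm(nd, 0, 1)
      c(pk, d)
    }
    truth <- data.frame(
      peak_a = peaks_a$name[cob_idx],
      peak_b = sprintf("B_%05d", seq_len(n_cobind)),
      planted_gap = gaps,
      stringsAsFactors = FALSE)
    list(peaks_a = add_decoys(peaks_a, "A"),
         peaks_b = add_decoys(peaks_b, "B"),
         truth = truth)
  })
}

#' Plant motif instances into peak sequences
#'
#' Extracts each peak's sequence from the genome, then for every motif id
#' in `cfg$motif_occurrence` writes one sampled motif instance into an
#' exact `round(rate * n_peaks)` seeded selection of peaks, at a uniform
#' position on a uniform strand. Edits are recorded in a truth table.
#'
#' @param cfg A `synth_config`.
#' @param peaks `GRanges` of peaks with a `name` column.
#' @param genome `DNAStringSet` genome.
#' @param pwms Named list of `pwm` objects covering the motif ids in
#'   `cfg$motif_occurrence`; defaults to the flattened [default_pwms()].
#' @param planting_threshold_fraction Instances are resampled until they
#'   score at least this fraction of the motif's maximum log-odds, so
#'   every planted instance is detectable when scanned at the planting
#'   threshold (default 0.8).
#' @return List: `sequences` (named character vector of edited peak
#'   sequences) and `truth` (data.frame peak_id, motif_id, position,
#'   strand, instance, score).
#' @export
plant_motifs <- function(cfg, peaks, genome,
                         pwms = unlist(default_pwms(), recursive = FALSE,
                                       use.names = FALSE),
                         planting_threshold_fraction = 0.8) {
  stopifnot(is(cfg, "synth_config"), is(peaks, "GRanges"))
  names(pwms) <- vapply(pwms, function(p) p$motif_id, character(1))
  missing <- setdiff(names(cfg$motif_occurrence), names(pwms))
  if (length(missing))
    stop("no PWM supplied for motif id(s): ", paste(missing, collapse = ", "))
  seqs <- extract_range_seqs(genome, peaks)
  n <- length(seqs)
  truth <- list()
  with_seed(derive_seed(cfg$seed, "motifs"), {
    for (mid in names(cfg$motif_occurrence)) {
      p <- pwms[[mid]]
      w <- pwm_width(p)
      if (any(nchar(seqs) < w))
        stop(sprintf("motif %s (width %d) is wider than a peak", mid, w))
      n_plant <- round(cfg$motif_occurrence[[mid]] * n)
      if (n_plant == 0L) next
      sel <- sample.int(n, n_plant)
      lodds <- pwm_log_odds(p)
      min_score <- planting_threshold_fraction * pwm_max_score(p)
      for (i in sel) {
        # rejection-sample an instance until it clears the planting
        # threshold, so planted occurrences are detectable by the scanner
        for (try in seq_len(1000L)) {
          inst_idx <- vapply(seq_len(w), function(j)
            sample.int(4L, 1L, prob = p$probs[, j]), integer(1))
          score <- sum(lodds[cbind(inst_idx, seq_len(w))])
          if (score >= min_score) break
        }
        if (score < min_score) {           # give up on sampling: consensus
          inst_idx <- apply(p$probs, 2, which.max)
          score <- sum(lodds[cbind(inst_idx, seq_len(w))])
        }
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") inst_idx <- rev(complement_idx(inst_idx))
        inst <- paste(DNA_BASES[inst_idx], collapse = "")
        pos <- sample.int(nchar(seqs[i]) - w + 1L, 1L)
        substr(seqs[i], pos, pos + w - 1L) <- inst
        truth[[length(truth) + 1L]] <- data.frame(
          peak_id = names(seqs)[i], motif_id = mid, position = pos,
          strand = strand, instance = inst, score = score,
          stringsAsFactors = FALSE)
      }
    }
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(peak_id = character(0), motif_id = character(0),
               position = integer(0), strand = character(0),
               instance = character(0), score = numeric(0),
               stringsAsFactors = FALSE)
  list(sequences = seqs, truth = truth)
}

#' Generate an expression table with planted differential structure
#'
#' Baseline log2 expression is i.i.d. normal; `n_up` genes gain
#' `fold_change_magnitude` log2 units in condition A (a `target_up_bias`
#' fraction of them drawn from `target_set`), `n_down` genes lose the
#' same amount, replicate noise is Normal(0, noise_sd), and values are
#' back-transformed so all RPKM are non-negative.
#'
#' @param cfg A `synth_config`.
#' @param genes `GRanges` with a `gene_id` column, or a character vector
#'   of gene ids.
#' @param target_set Character vector of gene ids (subset of the genes).
#' @return List: `table` (an [expression_table()]) and `truth`
#'   (data.frame gene_id, direction, is_target).
#' @export
generate_expression <- function(cfg, genes, target_set) {
  stopifnot(is(cfg, "synth_config"))
  ids <- if (is(genes, "GRanges")) genes$gene_id else as.character(genes)
  if (!all(target_set %in% ids)) stop("target_set must be a subset of gene ids")
  n <- length(ids)
  n_up_targets <- round(cfg$target_up_bias * cfg$n_up)
  if (n_up_targets > length(target_set))
    stop("target_up_bias * n_up exceeds the size of target_set")
  with_seed(derive_seed(cfg$seed, "expression"), {
    base <- rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    up_t <- sample(target_set, n_up_targets)
    pool <- setdiff(ids, up_t)
    up_rest <- if (cfg$n_up > n_up_targets)
      sample(setdiff(pool, target_set), cfg$n_up - n_up_targets) else character(0)
    up <- c(up_t, up_rest)
    down <- sample(setdiff(ids, up), cfg$n_down)
    effect <- setNames(numeric(n), ids)
    effect[up] <- cfg$fold_change_magnitude
    effect[down] <- -cfg$fold_change_magnitude
    nrep <- cfg$n_replicates
    sample_ids <- c(paste0(cfg$conditions[1], "_rep", seq_len(nrep)),
                    paste0(cfg$conditions[2], "_rep", seq_len(nrep)))
    condition <- rep(cfg$conditions, each = nrep)
    x <- matrix(base, nrow = n, ncol = 2 * nrep,
                dimnames = list(ids, sample_ids))
    x[, condition == cfg$conditions[1]] <-
      x[, condition == cfg$conditions[1]] + effect
    x <- x + matrix(rnorm(length(x), 0, cfg$noise_sd), nrow = n)
    tbl <- expression_table(2^x,
                            data.frame(sample_id = sample_ids,
                                       condition = condition,
                                       stringsAsFactors = FALSE))
    truth <- data.frame(
      gene_id = c(up, down),
      direction = rep(c("up", "down"), c(length(up), length(down))),
      is_target = c(up, down) %in% target_set,
      stringsAsFactors = FALSE)
    list(table = tbl, truth = truth)
  })
}

#' Generate per-exon unique read counts and multiread groups
#'
#' Splits a simulated read library into uniquely mapped per-exon counts
#' and groups of multireads, each group listing 2+ candidate exons and a
#' read count. The total of unique plus multiread counts equals the
#' requested library size exactly.
#'
#' @param cfg A `synth_config` (`multiread_fraction` must be < 1).
#' @param genes `GRanges` with `gene_id` and `blocks` metadata (exons).
#' @return List: `unique_counts` (data.frame exon_id, gene_id, length,
#'   count), `multiread_groups` (data.frame group_id, exon_id, reads;
#'   `reads` is the group total, repeated on each member row), and
#'   `library_size`.
#' @export
generate_read_counts <- function(cfg, genes) {
  stopifnot(is(cfg, "synth_config"))
  if (cfg$multiread_fraction >= 1) stop("multiread_fraction must be < 1")
  blocks <- genes$blocks
  exon_gene <- rep(genes$gene_id, lengths(blocks))
  exon_len <- unlist(lapply(blocks, IRanges::width), use.names = FALSE)
  n_exons <- length(exon_len)
  exon_id <- sprintf("%s_exon%d",
                     exon_gene,
                     unlist(lapply(lengths(blocks), seq_len), use.names = FALSE))
  with_seed(derive_seed(cfg$seed, "reads"), {
    gene_factor <- setNames(2^rnorm(length(genes$gene_id), 0, 1.5),
                            genes$gene_id)
    wts <- exon_len * gene_factor[exon_gene]
    n_multi <- round(cfg$multiread_fraction * cfg$library_size)
    n_unique <- cfg$library_size - n_multi
    ucounts <- as.vector(rmultinom(1, n_unique, wts / sum(wts)))
    unique_counts <- data.frame(exon_id = exon_id, gene_id = exon_gene,
                                length = exon_len, count = ucounts,
                                stringsAsFactors = FALSE)
    groups <- NULL
    if (n_multi > 0L) {
      ng <- min(cfg$n_multiread_groups, n_multi)
      gcounts <- as.vector(rmultinom(1, n_multi, rep(1, ng)))
      keep <- which(gcounts > 0)
      rows <- lapply(seq_along(keep), function(k) {
        g <- keep[k]
        nc <- sample(2:4, 1L)
        members <- sample.int(n_exons, nc)
        data.frame(group_id = sprintf("mgroup_%04d", g),
                   exon_id = exon_id[members],
                   reads = gcounts[g], stringsAsFactors = FALSE)
      })
      groups <- do.call(rbind, rows)
    } else {
      groups <- data.frame(group_id = character(0), exon_id = character(0),
                           reads = numeric(0), stringsAsFactors = FALSE)
    }
    list(unique_counts = unique_counts, multiread_groups = groups,
         library_size = cfg$library_size)
  })
}
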
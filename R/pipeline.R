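#' Pipeline configuration
#'
#' Bundles the synthetic-data block with every analysis threshold. All
#' randomness flows from the synth block's root seed, split per stage;
#' `seed` here feeds the enrichment permutations and motif-discovery
#' restarts.
#'
#' @param synth A [synth_config()] describing the data to generate.
#' @param q_threshold Peak q-value cutoff (default 0.001).
#' @param upstream_bp Promoter window for peak assignment (default 3000).
#' @param fold_threshold,min_rpkm Differential-expression rule (defaults
#'   2 and 2).
#' @param proximity_window Nearest-peak window in bp (default 500).
#' @param motif_threshold Scan threshold as a fraction of each motif's
#'   maximum log-odds score (default 0.8).
#' @param n_discovery_sequences Bound sequences sampled for de novo
#'   discovery (default 600).
#' @param discovery_width De novo motif width (default 12).
#' @param n_restarts EM restarts (default 10).
#' @param n_permutations GSEA permutations (default 1000).
#' @param seed Seed for enrichment/discovery stages (default the synth
#'   seed).
#' @param out_dir Default output directory for [run_pipeline()].
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            q_threshold = 0.001,
                            upstream_bp = 3000,
                            fold_threshold = 2,
                            min_rpkm = 2,
                            proximity_window = 500,
                            motif_threshold = 0.8,
                            n_discovery_sequences = 600,
                            discovery_width = 12,
                            n_restarts = 10,
                            n_permutations = 1000,
                            seed = synth$seed,
                            out_dir = "tfcobind_out") {
  stopifnot(is(synth, "synth_config"))
  if (q_threshold <= 0 || q_threshold > 1) stop("q_threshold must lie in (0, 1]")
  if (fold_threshold <= 1) stop("fold_threshold must exceed 1")
  if (min_rpkm < 0) stop("min_rpkm must be non-negative")
  if (proximity_window < 0) stop("proximity_window must be non-negative")
  if (motif_threshold <= 0 || motif_threshold > 1)
    stop("motif_threshold must lie in (0, 1]")
  if (upstream_bp < 0) stop("upstream_bp must be non-negative")
  if (n_permutations < 100) stop("n_permutations must be at least 100")
  structure(as.list(environment()), class = "pipeline_config")
}

#' A small, fast demonstration configuration
#'
#' Scaled-down study conditions suitable for examples and smoke tests:
#' 400 genes on a 4 Mb chromosome, 400/500 peaks, 200 discovery
#' sequences and 200 permutations.
#'
#' @param seed Root seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1) {
  pipeline_config(
    synth = synth_config(seed = seed, n_genes = 400, chrom_length = 4e6,
                         n_peaks_a = 400, n_peaks_b = 500,
                         n_up = 60, n_down = 60, library_size = 2e5),
    n_discovery_sequences = 200,
    n_permutations = 200,
    seed = seed)
}

log_line <- function(stage, msg, ...) {
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}

# Canonical JSON of a config, used both on disk and for the hash stamp.
config_json <- function(config) {
  plain <- unclass(config)
  plain$synth <- unclass(plain$synth)
  jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(config_json(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full integrative analysis
#'
#' Generates (or will later load) the data streams, then runs every
#' analysis stage in the order expression, binding, co-binding,
#' enrichment: q-value filtering, peak-to-gene assignment, target-set
#' overlap with hypergeometric significance, nearest-peak proximity,
#' motif occurrence and de novo discovery, RPKM quantification with
#' multiread allocation, fold-change differential expression, and
#' pre-ranked GSEA of both factors' targets. All stage outputs are
#' written under `out_dir` together with a machine-readable JSON report
#' stamped with the config hash and seed; a rerun with the same config
#' is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (default `config$out_dir`).
#' @return The report, invisibly, as a named list (also written to
#'   `report.json`).
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  stopifnot(is(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$synth
  hash <- config_hash(config)
  writeLines(config_json(config), file.path(out_dir, "config.json"))

  log_line("synth", "generating annotation: %d genes on %d chromosome(s)",
           cfg$n_genes, cfg$n_chroms)
  ann <- generate_annotation(cfg)
  write_genes_bed12(ann$genes, file.path(out_dir, "genes.bed12"))
  write_fasta(ann$genome, file.path(out_dir, "genome.fa"))

  log_line("synth", "generating peak sets: %d A, %d B, cobind fraction %.2f",
           cfg$n_peaks_a, cfg$n_peaks_b, cfg$cobind_fraction)
  pk <- generate_peak_sets(cfg, ann)
  write_peaks_bed(pk$peaks_a, file.path(out_dir, "peaks_a.bed"))
  write_peaks_bed(pk$peaks_b, file.path(out_dir, "peaks_b.bed"))
  write.table(pk$truth, file.path(out_dir, "truth_cobinding.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log_line("assign", "filtering peaks at q <= %g", config$q_threshold)
  fa <- filter_peaks(pk$peaks_a, config$q_threshold)
  fb <- filter_peaks(pk$peaks_b, config$q_threshold)
  asg_a <- assign_peaks_to_genes(fa, ann$genes, config$upstream_bp)
  asg_b <- assign_peaks_to_genes(fb, ann$genes, config$upstream_bp)
  write.table(asg_a$assignments, file.path(out_dir, "assignment_a.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(asg_b$assignments, file.path(out_dir, "assignment_b.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(list(targets_a = asg_a$target_genes,
                 targets_b = asg_b$target_genes),
            file.path(out_dir, "targets.gmt"))
  log_line("assign", "factor A: %d/%d peaks -> %d targets; factor B: %d/%d -> %d",
           asg_a$n_assigned, asg_a$n_peaks, length(asg_a$target_genes),
           asg_b$n_assigned, asg_b$n_peaks, length(asg_b$target_genes))

  log_line("synth", "generating expression with factor-A targets up-biased")
  expr <- generate_expression(cfg, ann$genes, asg_a$target_genes)
  write_expression_tsv(expr$table, file.path(out_dir, "expression.tsv"))
  write.table(expr$truth, file.path(out_dir, "truth_expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log_line("quantify", "simulating %d reads (%.0f%% multireads)",
           cfg$library_size, 100 * cfg$multiread_fraction)
  rc <- generate_read_counts(cfg, ann$genes)
  quant <- quantify_genes(ann$genes, rc$unique_counts, rc$multiread_groups,
                          rc$library_size)
  write.table(quant, file.path(out_dir, "rpkm_from_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log_line("motif", "planting motifs and scanning occurrence")
  planted <- plant_motifs(cfg, fa, ann$genome)
  write_fasta(planted$sequences, file.path(out_dir, "peak_sequences_a.fa"))
  write.table(planted$truth, file.path(out_dir, "truth_motifs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  occ <- peak_motif_occurrence(planted$sequences, default_pwms(),
                               config$motif_threshold)
  n_disc <- min(config$n_discovery_sequences, length(planted$sequences))
  log_line("motif", "de novo discovery from %d sampled sequences", n_disc)
  disc_seqs <- sample_bound_sequences(planted$sequences, n = n_disc,
                                      seed = derive_seed(config$seed, "sample"))
  disc <- discover_motif(disc_seqs, width = config$discovery_width,
                         n_restarts = config$n_restarts,
                         seed = derive_seed(config$seed, "discover"))
  cmp <- compare_motifs(default_pwms()$TCF7$TCF7_v1, disc$pwm)

  log_line("cobind", "overlap + proximity statistics")
  report_cb <- cobinding_report(asg_a$target_genes, asg_b$target_genes,
                                ann$genes$gene_id, fa, fb,
                                window_bp = config$proximity_window,
                                motif_occurrence = occ)
  # background-corrected recovery of the planted parameters, using the
  # truth tables: the non-planted peaks measure the chance rate
  d <- report_cb$proximity$distances
  planted_prox <- fa$name %in% pk$truth$peak_a
  bg_prox <- if (any(!planted_prox)) {
    mean(d[!planted_prox] <= config$proximity_window)
  } else 0
  recovered_cobind <- if (bg_prox < 1) {
    (report_cb$proximity$fraction_within - bg_prox) / (1 - bg_prox)
  } else NA_real_
  motif_recovery <- lapply(names(cfg$motif_occurrence), function(mid) {
    hits <- occ$hits[, mid]
    is_planted <- names(hits) %in%
      planted$truth$peak_id[planted$truth$motif_id == mid]
    fpr <- if (any(!is_planted)) mean(hits[!is_planted]) else 0
    list(observed = mean(hits),
         sensitivity = if (any(is_planted)) mean(hits[is_planted]) else NA,
         background_fpr = fpr,
         recovered = if (fpr < 1) (mean(hits) - fpr) / (1 - fpr) else NA)
  })
  names(motif_recovery) <- names(cfg$motif_occurrence)
  write.table(report_cb$proximity$histogram,
              file.path(out_dir, "distance_histogram.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log_line("enrich", "DE calling and pre-ranked GSEA (%d permutations)",
           config$n_permutations)
  de <- call_differential(expr$table, config$fold_threshold, config$min_rpkm)
  write.table(de, file.path(out_dir, "differential_expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ranked <- rank_by_fold_change(expr$table)
  write_rnk(ranked, file.path(out_dir, "ranked.rnk"))
  gsea <- gsea_preranked(ranked,
                         list(targets_a = asg_a$target_genes,
                              targets_b = asg_b$target_genes),
                         n_permutations = config$n_permutations,
                         seed = derive_seed(config$seed, "enrich"))
  write.table(gsea$results, file.path(out_dir, "gsea_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rs <- gsea$scores$targets_a$running_sum
  write.table(data.frame(position = seq_along(rs), running_sum = rs),
              file.path(out_dir, "running_sum_targets_a.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    meta = list(config_hash = hash, seed = cfg$seed,
                analysis_seed = config$seed),
    peaks = list(
      n_peaks_a_input = length(pk$peaks_a),
      n_peaks_b_input = length(pk$peaks_b),
      n_peaks_a_filtered = length(fa),
      n_peaks_b_filtered = length(fb),
      q_threshold = config$q_threshold),
    assignment = list(
      upstream_bp = config$upstream_bp,
      n_targets_a = length(asg_a$target_genes),
      n_targets_b = length(asg_b$target_genes),
      fraction_assigned_a = asg_a$fraction_assigned,
      fraction_assigned_b = asg_b$fraction_assigned),
    cobinding = list(
      n_common = report_cb$overlap$n_common,
      pct_of_a = report_cb$overlap$pct_of_a,
      pct_of_b = report_cb$overlap$pct_of_b,
      pct_of_a_raw = report_cb$overlap$pct_of_a_raw,
      pct_of_b_raw = report_cb$overlap$pct_of_b_raw,
      universe_size = report_cb$overlap$universe_size,
      hypergeom_p = report_cb$overlap$hypergeom_p,
      window_bp = report_cb$proximity$window_bp,
      n_within_window = report_cb$proximity$n_within_window,
      fraction_within = report_cb$proximity$fraction_within,
      background_fraction_within = bg_prox,
      recovered_cobind_fraction = recovered_cobind,
      planted_cobind_fraction = cfg$cobind_fraction),
    motif = list(
      threshold_fraction = config$motif_threshold,
      fraction_per_motif = as.list(occ$fraction_per_motif),
      fraction_per_factor = as.list(occ$fraction_per_factor),
      planted_occurrence = as.list(cfg$motif_occurrence),
      recovery = motif_recovery,
      de_novo_consensus = pwm_consensus(disc$pwm),
      de_novo_converged = disc$converged,
      comparison_to_known = cmp),
    expression = list(
      fold_threshold = config$fold_threshold,
      min_rpkm = config$min_rpkm,
      n_de = sum(de$is_de),
      n_up_in_a = sum(de$direction == "up_in_A"),
      n_up_in_b = sum(de$direction == "up_in_B")),
    enrichment = c(list(permutation_mode = gsea$permutation_mode,
                        n_permutations = gsea$n_permutations),
                   split(gsea$results[, c("size", "es", "nes", "nominal_p",
                                          "fdr_q")],
                         gsea$results$gene_set_id))
  )
  report$enrichment <- lapply(report$enrichment, function(x)
    if (is.data.frame(x)) as.list(x) else x)
  validate_report(report)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("report", "written to %s", file.path(out_dir, "report.json"))
  invisible(report)
}

#' Validate a pipeline report against the shipped schema
#'
#' Checks that every required field of the report schema
#' (`inst/extdata/report-schema.json`) is present.
#'
#' @param report A report list as produced by [run_pipeline()].
#' @return TRUE invisibly; errors listing missing fields otherwise.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("extdata", "report-schema.json",
                             package = "tfcobind")
  if (schema_path == "")
    schema_path <- file.path("inst", "extdata", "report-schema.json")
  schema <- jsonlite::read_json(schema_path)
  missing <- character(0)
  for (section in names(schema$required)) {
    if (is.null(report[[section]])) {
      missing <- c(missing, section)
      next
    }
    for (field in unlist(schema$required[[section]])) {
      if (is.null(report[[section]][[field]]))
        missing <- c(missing, paste(section, field, sep = "."))
    }
  }
  if (length(missing))
    stop("report is missing required field(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
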
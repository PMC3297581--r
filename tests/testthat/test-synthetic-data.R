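test_that("config validation rejects out-of-range parameters", {
  expect_error(synth_config(cobind_fraction = 1.2), "proportions")
  expect_error(synth_config(n_up = 3000, n_down = 3000, n_genes = 5000),
               "n_up")
  expect_error(synth_config(chrom_length = 0), "positive")
})

test_that("annotation with zero genes still emits a genome", {
  cfg <- synth_config(n_genes = 0, chrom_length = 1e4, n_up = 0, n_down = 0)
  ann <- generate_annotation(cfg)
  expect_length(ann$genes, 0)
  expect_equal(sum(Biostrings::width(ann$genome)), 1e4)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 1, n_genes = 30, chrom_length = 5e5,
                      n_peaks_a = 40, n_peaks_b = 50, n_up = 5, n_down = 5)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_identical(as.data.frame(a1$genes), as.data.frame(a2$genes))
  p1 <- generate_peak_sets(cfg, a1)
  p2 <- generate_peak_sets(cfg, a2)
  expect_identical(as.data.frame(p1$peaks_a), as.data.frame(p2$peaks_a))
  expect_identical(p1$truth, p2$truth)
  e1 <- generate_expression(cfg, a1$genes, a1$genes$gene_id[1:10])
  e2 <- generate_expression(cfg, a2$genes, a2$genes$gene_id[1:10])
  expect_identical(e1$table$values, e2$table$values)
  r1 <- generate_read_counts(cfg, a1$genes)
  r2 <- generate_read_counts(cfg, a2$genes)
  expect_identical(r1, r2)
})

test_that("placed genes keep >= 3 kb pairwise gaps (interval sweep)", {
  cfg <- synth_config(seed = 3, n_genes = 100, chrom_length = 2e6,
                      n_up = 0, n_down = 0)
  genes <- generate_annotation(cfg)$genes
  expect_length(genes, 100)
  st <- GenomicRanges::start(genes); en <- GenomicRanges::end(genes)
  min_gap <- Inf
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i == j) next
      min_gap <- min(min_gap, max(st[j] - en[i] - 1, st[i] - en[j] - 1))
    }
  }
  expect_gte(min_gap, 3000)
  # exons sorted, non-overlapping, spanning the gene
  for (i in seq_along(genes)) {
    b <- genes$blocks[[i]]
    expect_true(all(diff(IRanges::start(b)) > 0))
    expect_true(all(IRanges::start(b)[-1] > head(IRanges::end(b), -1)))
  }
})

test_that("impossible gene placement raises a capacity error", {
  cfg <- synth_config(n_genes = 100, chrom_length = 1e5, n_up = 0, n_down = 0)
  expect_error(generate_annotation(cfg), "capacity")
})

test_that("degenerate co-binding kernel places every partner at edge distance zero", {
  cfg <- synth_config(seed = 2, n_genes = 0, chrom_length = 1e6,
                      n_peaks_a = 50, n_peaks_b = 60, cobind_fraction = 1,
                      cobind_distance_sd = 0, decoy_fraction = 0,
                      n_up = 0, n_down = 0)
  ann <- generate_annotation(cfg)
  pk <- generate_peak_sets(cfg, ann)
  expect_equal(nrow(pk$truth), 50)
  nd <- nearest_peak_distances(pk$peaks_a, pk$peaks_b)
  expect_true(all(nd$distances == 0))
})

test_that("zero co-binding yields an empty truth table and infeasible demands error", {
  cfg <- synth_config(seed = 2, n_genes = 0, chrom_length = 1e6,
                      n_peaks_a = 50, n_peaks_b = 60, cobind_fraction = 0,
                      n_up = 0, n_down = 0)
  pk <- generate_peak_sets(cfg, generate_annotation(cfg))
  expect_equal(nrow(pk$truth), 0)
  bad <- synth_config(n_genes = 0, chrom_length = 1e6, n_peaks_a = 100,
                      n_peaks_b = 10, cobind_fraction = 0.5,
                      n_up = 0, n_down = 0)
  expect_error(generate_peak_sets(bad, generate_annotation(bad)),
               "exceeds n_peaks_b")
})

test_that("peak truth tables account for each planted pair exactly once", {
  cfg <- synth_config(seed = 5, n_genes = 0, chrom_length = 2e6,
                      n_peaks_a = 200, n_peaks_b = 250,
                      cobind_fraction = 0.4, n_up = 0, n_down = 0)
  pk <- generate_peak_sets(cfg, generate_annotation(cfg))
  expect_equal(nrow(pk$truth), round(0.4 * 200))
  expect_false(any(duplicated(pk$truth$peak_a)))
  expect_false(any(duplicated(pk$truth$peak_b)))
  expect_true(all(pk$truth$peak_a %in% pk$peaks_a$name))
  expect_true(all(pk$truth$peak_b %in% pk$peaks_b$name))
  # q-value contract: true peaks significant, decoys not
  decoy <- grepl("decoy", pk$peaks_a$name)
  expect_true(all(pk$peaks_a$q_value[!decoy] <= 0.001))
  expect_true(all(pk$peaks_a$q_value[decoy] > 0.001))
})

test_that("full-occurrence planting leaves a scannable hit in every peak", {
  cfg <- synth_config(seed = 4, n_genes = 0, chrom_length = 1e6,
                      n_peaks_a = 60, n_peaks_b = 60, decoy_fraction = 0,
                      motif_occurrence = c(TCF7_v1 = 1), n_up = 0, n_down = 0)
  ann <- generate_annotation(cfg)
  pk <- generate_peak_sets(cfg, ann)
  planted <- plant_motifs(cfg, pk$peaks_a, ann$genome)
  expect_equal(nrow(planted$truth), 60)
  motif <- default_pwms()$TCF7$TCF7_v1
  hits <- vapply(planted$sequences, function(s)
    nrow(scan_pwm(s, motif, threshold_fraction = 0.8)) >= 1, logical(1))
  expect_true(all(hits))
})

test_that("a motif wider than the peaks cannot be planted", {
  cfg <- synth_config(seed = 4, n_genes = 0, chrom_length = 1e5,
                      n_peaks_a = 10, n_peaks_b = 10, peak_width = 8,
                      motif_occurrence = c(TCF7_v1 = 1), n_up = 0, n_down = 0)
  ann <- generate_annotation(cfg)
  pk <- generate_peak_sets(cfg, ann)
  expect_error(plant_motifs(cfg, pk$peaks_a, ann$genome), "wider")
})

test_that("expression planting respects the target bias and its feasibility bound", {
  ids <- sprintf("g%04d", 1:500)
  targets <- ids[1:200]
  cfg <- synth_config(seed = 6, n_genes = 500, n_up = 100, n_down = 50,
                      target_up_bias = 1)
  ex <- generate_expression(cfg, ids, targets)
  up <- ex$truth$gene_id[ex$truth$direction == "up"]
  expect_length(up, 100)
  expect_true(all(up %in% targets))
  expect_false(any(duplicated(ex$truth$gene_id)))
  expect_true(all(ex$table$values >= 0))
  cfg_bad <- synth_config(seed = 6, n_genes = 500, n_up = 300,
                          target_up_bias = 1, n_down = 0)
  expect_error(generate_expression(cfg_bad, ids, targets), "exceeds")
})

test_that("a null effect size produces no more DE calls than a replicate-permutation null", {
  ids <- sprintf("g%04d", 1:2000)
  cfg <- synth_config(seed = 7, n_genes = 2000, n_up = 200, n_down = 200,
                      fold_change_magnitude = 0, noise_sd = 0.25)
  ex <- generate_expression(cfg, ids, ids[1:400])
  de <- call_differential(ex$table)
  # permutation null: reassign condition labels across replicates
  perm_counts <- vapply(1:20, function(b) {
    set.seed(b)
    samples <- ex$table$samples
    samples$condition <- sample(samples$condition)
    sum(call_differential(expression_table(ex$table$values, samples))$is_de)
  }, numeric(1))
  expect_lte(sum(de$is_de), max(quantile(perm_counts, 0.99), 5))
})

test_that("read-count generation conserves the library and honours multiread_fraction", {
  cfg <- synth_config(seed = 8, n_genes = 40, chrom_length = 1e6,
                      library_size = 5e4, multiread_fraction = 0.2,
                      n_up = 0, n_down = 0)
  genes <- generate_annotation(cfg)$genes
  rc <- generate_read_counts(cfg, genes)
  group_totals <- tapply(rc$multiread_groups$reads,
                         rc$multiread_groups$group_id, function(x) x[1])
  expect_equal(sum(rc$unique_counts$count) + sum(group_totals), 5e4)
  expect_true(all(table(rc$multiread_groups$group_id) >= 2))
  cfg0 <- synth_config(seed = 8, n_genes = 40, chrom_length = 1e6,
                       library_size = 5e4, multiread_fraction = 0,
                       n_up = 0, n_down = 0)
  rc0 <- generate_read_counts(cfg0, genes)
  expect_equal(nrow(rc0$multiread_groups), 0)
  expect_equal(sum(rc0$unique_counts$count), 5e4)
  cfg_bad <- synth_config(n_genes = 40, chrom_length = 1e6, n_up = 0,
                          n_down = 0)
  cfg_bad$multiread_fraction <- 1
  expect_error(generate_read_counts(cfg_bad, genes), "multiread_fraction")
})
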
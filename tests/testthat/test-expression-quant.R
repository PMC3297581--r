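test_that("multiread allocation splits proportionally with a uniform fallback", {
  u <- data.frame(exon_id = c("e1", "e2"), count = c(30, 10),
                  stringsAsFactors = FALSE)
  g <- data.frame(group_id = "m1", exon_id = c("e1", "e2"), reads = 10,
                  stringsAsFactors = FALSE)
  out <- allocate_multireads(u, g)
  expect_equal(out$allocated, c(7.5, 2.5))
  u0 <- data.frame(exon_id = c("e1", "e2"), count = c(0, 0))
  expect_equal(allocate_multireads(u0, g)$allocated, c(5, 5))
  expect_error(allocate_multireads(
    data.frame(exon_id = "e1", count = -1), g[0, ]), "non-negative")
})

test_that("multiread allocation conserves total read mass on random tables", {
  for (case in 1:100) {
    set.seed(case)
    ne <- sample(3:12, 1)
    u <- data.frame(exon_id = sprintf("e%02d", 1:ne),
                    count = sample(0:50, ne, replace = TRUE),
                    stringsAsFactors = FALSE)
    ngroups <- sample(1:5, 1)
    g <- do.call(rbind, lapply(1:ngroups, function(k) {
      members <- sample(ne, sample(2:min(4, ne), 1))
      data.frame(group_id = paste0("m", k), exon_id = u$exon_id[members],
                 reads = sample(0:30, 1), stringsAsFactors = FALSE)
    }))
    out <- allocate_multireads(u, g)
    group_totals <- tapply(g$reads, g$group_id, function(x) x[1])
    expect_equal(sum(out$total), sum(u$count) + sum(group_totals),
                 tolerance = 1e-9)
  }
})

test_that("RPKM follows the definition and rejects zero-length genes", {
  expect_equal(unname(compute_rpkm(100, 2000, 1e6)), 50)
  expect_equal(unname(compute_rpkm(0, 500, 1e6)), 0)
  expect_error(compute_rpkm(c(gA = 5), c(gA = 0), 1e6), "gA")
  # linearity in counts at fixed library size
  counts <- c(a = 12, b = 7, c = 0)
  lens <- c(a = 1500, b = 800, c = 2000)
  expect_equal(compute_rpkm(2 * counts, lens, 5e5),
               2 * compute_rpkm(counts, lens, 5e5))
})

test_that("gene quantification matches brute-force recomputation from raw tables", {
  for (case in 1:50) {
    set.seed(case + 100)
    genes <- make_genes("chr1", c(1000, 9000, 20000), c(4000, 12000, 26000),
                        c("+", "-", "+"))
    genes$blocks <- IRanges::IRangesList(
      IRanges::IRanges(c(1, 2001), c(500, 3001)),
      IRanges::IRanges(1, 3001),
      IRanges::IRanges(c(1, 3001, 5001), c(1000, 4000, 6001)))
    exon_id <- c("g001_e1", "g001_e2", "g002_e1", "g003_e1", "g003_e2",
                 "g003_e3")
    gene_of <- c("g001", "g001", "g002", "g003", "g003", "g003")
    u <- data.frame(exon_id = exon_id, gene_id = gene_of,
                    length = c(500, 1001, 3001, 1000, 1000, 1001),
                    count = sample(0:200, 6, replace = TRUE),
                    stringsAsFactors = FALSE)
    g <- data.frame(group_id = c("m1", "m1", "m2", "m2"),
                    exon_id = exon_id[c(1, 3, 4, 6)],
                    reads = c(20, 20, 9, 9), stringsAsFactors = FALSE)
    total <- 2e5
    q <- quantify_genes(genes, u, g, total)
    # independent recomputation with explicit loops
    alloc <- u$count
    names(alloc) <- u$exon_id
    w1 <- u$count[c(1, 3)]
    alloc[c(1, 3)] <- alloc[c(1, 3)] +
      if (sum(w1) == 0) c(10, 10) else 20 * w1 / sum(w1)
    w2 <- u$count[c(4, 6)]
    alloc[c(4, 6)] <- alloc[c(4, 6)] +
      if (sum(w2) == 0) c(4.5, 4.5) else 9 * w2 / sum(w2)
    for (gid in unique(gene_of)) {
      cnt <- sum(alloc[gene_of == gid])
      len <- sum(IRanges::width(genes$blocks[[which(genes$gene_id == gid)]]))
      expect_equal(q$rpkm[q$gene_id == gid],
                   cnt / (len / 1000) / (total / 1e6), tolerance = 1e-9)
    }
  }
})

test_that("the DE rule applies fold change and minimum expression jointly", {
  m <- rbind(g1 = c(4, 4, 2, 2), g2 = c(100, 100, 1, 1), g3 = c(3, 3, 3, 3))
  colnames(m) <- c("A1", "A2", "B1", "B2")
  tbl <- expression_table(m, data.frame(sample_id = colnames(m),
                                        condition = c("A", "A", "B", "B")))
  de <- call_differential(tbl, fold_threshold = 2, min_rpkm = 2)
  expect_equal(de$direction[de$gene_id == "g1"], "up_in_A")
  # strong fold change but below the 2-RPKM floor in one condition
  expect_equal(de$direction[de$gene_id == "g2"], "unchanged")
  expect_false(de$passes_min_expression[de$gene_id == "g2"])
  expect_equal(de$direction[de$gene_id == "g3"], "unchanged")
  expect_error(call_differential(tbl, fold_threshold = 1), "exceed")
})

test_that("DE calls are antisymmetric under condition-label swap", {
  tbl <- random_expression_fixture(n_genes = 200, seed = 42)
  de <- call_differential(tbl)
  swapped <- expression_table(tbl$values, transform(tbl$samples,
    condition = ifelse(condition == "A", "B", "A")))
  de_sw <- call_differential(swapped, condition_a = "A")
  expect_equal(de$gene_id[de$direction == "up_in_A"],
               de_sw$gene_id[de_sw$direction == "up_in_B"])
  expect_equal(de$gene_id[de$direction == "up_in_B"],
               de_sw$gene_id[de_sw$direction == "up_in_A"])
  expect_equal(de$is_de, de_sw$is_de)
})

test_that("Z transform normalises per gene and zeroes constant genes", {
  m <- rbind(g1 = c(1, 1, 1, 1), g2 = c(1, 2, 4, 8))
  colnames(m) <- paste0("s", 1:4)
  tbl <- expression_table(m, data.frame(sample_id = colnames(m),
                                        condition = rep(c("A", "B"), 2)))
  z <- zscore_transform(tbl)
  expect_equal(unname(z["g1", ]), rep(0, 4))
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(sd(z["g2", ]), 1, tolerance = 1e-12)
  # two-sample closed form: +/- 1/sqrt(2) under the sample-sd convention
  m2 <- rbind(g = c(2, 8))
  colnames(m2) <- c("s1", "s2")
  t2 <- expression_table(m2, data.frame(sample_id = c("s1", "s2"),
                                        condition = c("A", "B")))
  expect_equal(unname(zscore_transform(t2)["g", ]),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  tblr <- random_expression_fixture(n_genes = 100, seed = 9)
  expect_true(all(abs(rowMeans(zscore_transform(tblr))) < 1e-9))
})

test_that("fold-change ranking is strict, antisymmetric, and consistent with DE", {
  tbl <- random_expression_fixture(n_genes = 300, seed = 11)
  ranked <- rank_by_fold_change(tbl, condition_a = "A")
  expect_false(any(duplicated(ranked$gene_id)))
  expect_true(all(diff(ranked$score) <= 0))
  # swapping the conditions reverses the order exactly (scores distinct here)
  rev_ranked <- rank_by_fold_change(tbl, condition_a = "B")
  expect_equal(rev_ranked$gene_id, rev(ranked$gene_id))
  expect_equal(rev_ranked$score, -rev(ranked$score), tolerance = 1e-12)
  # every DE-up gene outranks every DE-down gene
  de <- call_differential(tbl, fold_threshold = 1.5, min_rpkm = 0.5)
  pos <- match(de$gene_id[de$direction == "up_in_A"], ranked$gene_id)
  neg <- match(de$gene_id[de$direction == "up_in_B"], ranked$gene_id)
  if (length(pos) && length(neg)) expect_lt(max(pos), min(neg))
})
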
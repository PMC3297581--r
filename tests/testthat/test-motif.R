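hexamer_pwm <- function() {
  probs <- matrix(0.05, nrow = 4, ncol = 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("A", "C", "G", "T", "A", "C")
  for (j in 1:6) probs[cons[j], j] <- 0.85
  pwm(probs, "hex")
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}

test_that("PWM construction validates and normalises columns", {
  p <- hexamer_pwm()
  expect_equal(colSums(p$probs), rep(1, 6))
  expect_equal(pwm_consensus(p), "ACGTAC")
  expect_error(pwm(matrix(0.25, 4, 3), "too_narrow"), "width")
  expect_error(pwm(matrix(-1, 4, 6), "neg"), "non-negative")
  # transposed input is accepted
  expect_equal(pwm(t(p$probs), "t")$probs, p$probs, ignore_attr = TRUE)
})

test_that("scanning the consensus yields the maximal score on the forward strand", {
  p <- hexamer_pwm()
  hits <- scan_pwm(pwm_consensus(p), p, score_threshold = pwm_max_score(p))
  expect_equal(nrow(hits[hits$strand == "+", ]), 1)
  expect_equal(hits$score[hits$strand == "+"], pwm_max_score(p))
  expect_equal(nrow(scan_pwm("ACG", p)), 0)     # shorter than the motif
  # windows containing N are skipped
  expect_equal(nrow(scan_pwm("ACGNAC", p, score_threshold = -100)), 0)
})

test_that("hit counts over every hexamer equal the enumeration oracle", {
  p <- hexamer_pwm()
  thr <- 0.8 * pwm_max_score(p)
  lodds <- log2(pmax(p$probs, 1e-12) / 0.25)
  kmers <- all_kmers(6)
  oracle_scores <- vapply(kmers, function(s) {
    b <- strsplit(s, "")[[1]]
    sum(vapply(1:6, function(j) lodds[b[j], j], numeric(1)))
  }, numeric(1))
  scan_fwd <- vapply(kmers, function(s) {
    h <- scan_pwm(s, p, score_threshold = thr)
    any(h$strand == "+")
  }, logical(1))
  expect_equal(sum(scan_fwd), sum(oracle_scores >= thr))
  expect_equal(unname(which(scan_fwd)), unname(which(oracle_scores >= thr)))
})

test_that("scanner scores are additive over positions and strand-symmetric", {
  p <- hexamer_pwm()
  set.seed(40)
  for (case in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    hits <- scan_pwm(s, p, score_threshold = -Inf)
    lodds <- log2(pmax(p$probs, 1e-12) / 0.25)
    for (r in which(hits$strand == "+")) {
      win <- strsplit(substr(s, hits$position[r], hits$position[r] + 5), "")[[1]]
      expect_equal(hits$score[r],
                   sum(vapply(1:6, function(j) lodds[win[j], j], numeric(1))),
                   tolerance = 1e-12)
    }
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    h1 <- scan_pwm(s, p, score_threshold = 0)
    h2 <- scan_pwm(rc, p, score_threshold = 0)
    expect_equal(nrow(h1), nrow(h2))
    expect_equal(sum(h1$strand == "+"), sum(h2$strand == "-"))
  }
})

test_that("per-peak occurrence takes the non-duplicate union over versions", {
  pwms <- default_pwms()
  set.seed(41)
  seqs <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- sprintf("pk%02d", 1:40)
  # plant version 1 in the first 10 peaks and version 2 in peaks 6-15
  v1 <- pwm_consensus(pwms$TCF7$TCF7_v1); v2 <- pwm_consensus(pwms$TCF7$TCF7_v2)
  for (i in 1:10) substr(seqs[i], 10, 9 + nchar(v1)) <- v1
  for (i in 6:15) substr(seqs[i], 60, 59 + nchar(v2)) <- v2
  occ <- peak_motif_occurrence(seqs, pwms)
  expect_true(all(occ$union_hits[1:15, "TCF7"]))
  expect_gte(occ$fraction_per_factor[["TCF7"]],
             max(occ$fraction_per_motif[c("TCF7_v1", "TCF7_v2")]))
  # invariant to peak order
  occ_perm <- peak_motif_occurrence(seqs[sample(40)], pwms)
  expect_equal(sort(rownames(occ$hits)[occ$hits[, "TCF7_v1"]]),
               sort(rownames(occ_perm$hits)[occ_perm$hits[, "TCF7_v1"]]))
  empty <- peak_motif_occurrence(character(0), pwms)
  expect_equal(empty$status, "empty")
})

test_that("bound-sequence sampling is seeded, unique and order-stable", {
  set.seed(42)
  seqs <- setNames(
    vapply(1:9696 %% 7 + 10, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)),
    sprintf("peak_%04d", 1:9696))
  s600 <- sample_bound_sequences(seqs, n = 600, seed = 5)
  expect_length(s600, 600)
  expect_false(any(duplicated(names(s600))))
  expect_identical(s600, sample_bound_sequences(seqs, n = 600, seed = 5))
  all_of_them <- sample_bound_sequences(seqs, n = length(seqs), seed = 5)
  expect_identical(names(all_of_them), names(seqs))
  expect_error(sample_bound_sequences(seqs[1:10], n = 11, seed = 1), "sample")
})

test_that("EM recovers a degenerate planted k-mer and keeps likelihood monotone", {
  set.seed(43)
  core <- "TTACGCGT"
  seqs <- vapply(1:60, function(i) {
    bg <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
    pos <- sample(1:(40 - 8), 1)
    s <- bg
    s[pos:(pos + 7)] <- strsplit(core, "")[[1]]
    paste(s, collapse = "")
  }, character(1))
  fit <- discover_motif(seqs, width = 8, n_restarts = 5, seed = 2)
  cons <- pwm_consensus(fit$pwm)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(core)))
  expect_true(cons %in% c(core, rc))
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_equal(colSums(fit$pwm$probs), rep(1, 8), tolerance = 1e-9)
  expect_error(discover_motif(seqs[1:10], width = 8), "at least 50")
})

test_that("motif comparison identifies identity, reverse complement and registers", {
  p1 <- default_pwms()$TCF7$TCF7_v1
  self <- compare_motifs(p1, p1)
  expect_equal(self$offset, 0)
  expect_equal(self$orientation, "same")
  expect_equal(self$similarity, 1)
  rc <- tfcobind:::pwm_revcomp(p1)
  flip <- compare_motifs(p1, rc)
  expect_equal(flip$orientation, "complementary")
  expect_equal(flip$similarity, 1, tolerance = 1e-12)
  # two motifs sharing a 10-column core at a 2-column shift
  set.seed(44)
  core <- matrix(runif(40), 4, 10)
  core <- sweep(core, 2, colSums(core), "/")
  flank <- function() { f <- matrix(runif(8), 4, 2); sweep(f, 2, colSums(f), "/") }
  pa <- pwm(cbind(flank(), core), "a")
  pb <- pwm(cbind(core, flank()), "b")
  best <- compare_motifs(pa, pb)
  expect_equal(best$offset, 2)
  expect_equal(best$orientation, "same")
  expect_equal(best$n_aligned, 10)
  expect_gt(best$similarity, 0.99)
})
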
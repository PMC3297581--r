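#' Construct a position weight matrix
#'
#' A PWM stores per-position base probabilities for a binding motif,
#' scored against a background distribution as log2 odds.
#'
#' @param probs Numeric matrix of base probabilities, either 4 x width with
#'   rows A,C,G,T or width x 4 with columns A,C,G,T.
#' @param motif_id Character scalar identifying the motif.
#' @param background Background base probabilities (A,C,G,T); must sum to 1.
#' @param source Free-text provenance label (e.g. "known-version-1",
#'   "de-novo").
#' @param pseudocount Added to every cell before renormalisation, so that
#'   no probability is exactly zero. Use 0 to keep `probs` as given
#'   (they must then already be positive columns summing to 1).
#' @return An object of class `pwm`: a list with elements `motif_id`,
#'   `probs` (4 x width, rows A,C,G,T), `background`, `source`.
#' @export
pwm <- function(probs, motif_id, background = rep(0.25, 4),
                source = "unspecified", pseudocount = 0) {
  if (!is.matrix(probs)) stop("probs must be a matrix")
  if (nrow(probs) != 4L && ncol(probs) == 4L) probs <- t(probs)
  if (nrow(probs) != 4L) stop("probs must have 4 rows (A,C,G,T)")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  probs <- probs + pseudocount
  probs <- sweep(probs, 2, colSums(probs), "/")
  if (ncol(probs) < 4L) stop("motif width must be >= 4")
  if (any(abs(colSums(probs) - 1) > 1e-9))
    stop("each position must sum to 1 after regularization")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  rownames(probs) <- DNA_BASES
  structure(list(motif_id = motif_id, probs = probs,
                 background = background, source = source),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (width %d, source: %s)\n  consensus: %s\n",
              x$motif_id, pwm_width(x), x$source, pwm_consensus(x)))
  invisible(x)
}

#' @rdname pwm
#' @param x A `pwm` object.
#' @export
pwm_width <- function(x) ncol(x$probs)

#' @rdname pwm
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$probs, 2, which.max)], collapse = "")
}

# log2-odds score matrix (4 x width) of a pwm against its background.
pwm_log_odds <- function(x) log2(pmax(x$probs, 1e-12) / x$background)

#' Maximum achievable log-odds score of a PWM
#' @param x A `pwm` object.
#' @export
pwm_max_score <- function(x) sum(apply(pwm_log_odds(x), 2, max))

# Reverse complement of a pwm: reverse positions, swap A<->T and C<->G.
pwm_revcomp <- function(x) {
  p <- x$probs[c("T", "G", "C", "A"), rev(seq_len(ncol(x$probs))), drop = FALSE]
  rownames(p) <- DNA_BASES
  pwm(p, motif_id = paste0(x$motif_id, "_rc"),
      background = x$background[c(4, 3, 2, 1)], source = x$source)
}

#' Built-in known motifs for the two factors
#'
#' Two versions each of a TCF7/LEF-family motif (CTTTG[AT][AT] core) and a
#' RUNX-family motif (TGTGGT core). These are synthetic stand-ins
#' constructed from the published consensus sequences, not database
#' downloads; they serve as the default "known motif" set for occurrence
#' scanning, motif planting and comparison with de novo discoveries.
#'
#' @return Named list of factors, each a named list of `pwm` objects.
#' @export
default_pwms <- function() {
  from_consensus <- function(cons, id, strong = 0.85) {
    w <- nchar(cons)
    probs <- matrix((1 - strong) / 3, nrow = 4, ncol = w,
                    dimnames = list(DNA_BASES, NULL))
    letters <- strsplit(cons, "")[[1]]
    for (j in seq_len(w)) {
      if (letters[j] == "W") {        # A or T
        probs[, j] <- c(0.45, 0.05, 0.05, 0.45)
      } else if (letters[j] == "Y") { # C or T
        probs[, j] <- c(0.05, 0.45, 0.05, 0.45)
      } else {
        probs[letters[j], j] <- strong
      }
    }
    pwm(probs, motif_id = id, source = "known")
  }
  list(
    TCF7 = list(
      TCF7_v1 = from_consensus("CCTTTGWWCT", "TCF7_v1"),
      TCF7_v2 = from_consensus("ACTTTGWWGC", "TCF7_v2")
    ),
    RUNX1 = list(
      RUNX1_v1 = from_consensus("TGTGGTTW", "RUNX1_v1"),
      RUNX1_v2 = from_consensus("TGYGGTCA", "RUNX1_v2")
    )
  )
}

# Score every window of an index vector against a 4 x w log-odds matrix.
# Returns numeric vector of window scores (window start positions on the
# given index vector); windows containing NA (padding or N) score -Inf.
score_windows_idx <- function(idx, lodds) {
  w <- ncol(lodds)
  n <- length(idx)
  if (n < w) return(numeric(0))
  nw <- n - w + 1L
  s <- numeric(nw)
  for (j in seq_len(w)) {
    s <- s + lodds[cbind(idx[j:(nw + j - 1L)], j)]
  }
  s[is.na(s)] <- -Inf
  s
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window is scored as the sum of per-position log2 odds
#' `log2(p_j(base)/bg(base))`; windows containing N are skipped.
#' Reverse-strand hits are reported at the window's start position on the
#' forward strand.
#'
#' @param sequence A character string or `Biostrings::DNAString`.
#' @param pwm A `pwm` object.
#' @param score_threshold Minimum log-odds score to report; default is
#'   `threshold_fraction` of the maximum achievable score.
#' @param threshold_fraction Fraction of `pwm_max_score(pwm)` used when
#'   `score_threshold` is NULL (default 0.8).
#' @return data.frame with columns position, strand, score. Empty if the
#'   sequence is shorter than the motif width.
#' @export
scan_pwm <- function(sequence, pwm, score_threshold = NULL,
                     threshold_fraction = 0.8) {
  stopifnot(is(pwm, "pwm"))
  if (is.null(score_threshold))
    score_threshold <- threshold_fraction * pwm_max_score(pwm)
  idx <- dna_to_idx(sequence)
  w <- pwm_width(pwm)
  empty <- data.frame(position = integer(0), strand = character(0),
                      score = numeric(0))
  if (length(idx) < w) return(empty)
  fwd <- score_windows_idx(idx, pwm_log_odds(pwm))
  rev <- score_windows_idx(idx, pwm_log_odds(pwm_revcomp(pwm)))
  fi <- which(fwd >= score_threshold)
  ri <- which(rev >= score_threshold)
  hits <- rbind(
    data.frame(position = fi, strand = rep("+", length(fi)),
               score = fwd[fi]),
    data.frame(position = ri, strand = rep("-", length(ri)),
               score = rev[ri])
  )
  hits[order(hits$position, hits$strand), , drop = FALSE]
}

# Fast max-window-score for many sequences at once. seqs: character vector
# or DNAStringSet. Returns matrix n x 2 (best forward, best reverse score).
max_scores_batch <- function(seqs, pwm) {
  seqs <- as.character(seqs)
  n <- length(seqs)
  w <- pwm_width(pwm)
  lens <- nchar(seqs)
  L <- max(lens)
  idx <- matrix(NA_integer_, nrow = n, ncol = L)
  for (i in seq_len(n)) idx[i, seq_len(lens[i])] <- dna_to_idx(seqs[i])
  best <- function(lodds) {
    out <- rep(-Inf, n)
    if (L < w) return(out)
    for (p in seq_len(L - w + 1L)) {
      s <- numeric(n)
      for (j in seq_len(w)) s <- s + lodds[cbind(idx[, p + j - 1L], j)]
      s[is.na(s)] <- -Inf
      out <- pmax(out, s)
    }
    out
  }
  cbind(forward = best(pwm_log_odds(pwm)),
        reverse = best(pwm_log_odds(pwm_revcomp(pwm))))
}

#' Per-peak motif occurrence with multi-version union
#'
#' For each peak sequence and each motif version, records whether the
#' scanner finds at least one hit at the given threshold rule; per factor,
#' versions are combined as a non-duplicate union (a peak with hits for
#' several versions counts once).
#'
#' @param peak_sequences Named character vector or `DNAStringSet`, one
#'   sequence per peak; names are peak ids.
#' @param pwms_by_factor Named list (factor -> named list of `pwm`).
#' @param threshold_fraction Scan threshold as a fraction of each motif's
#'   maximum achievable log-odds score (default 0.8).
#' @return List of class `motif_occurrence` with per-peak logical hit
#'   matrix (`hits`), per-factor union columns (`union_hits`), per-motif
#'   and per-factor occurrence fractions, and the threshold rule used.
#'   With zero peaks returns `status = "empty"` and no fractions.
#' @export
peak_motif_occurrence <- function(peak_sequences, pwms_by_factor,
                                  threshold_fraction = 0.8) {
  seqs <- setNames(as.character(peak_sequences), names(peak_sequences))
  if (length(seqs) == 0L) {
    return(structure(list(status = "empty", n_peaks = 0L),
                     class = "motif_occurrence"))
  }
  if (any(is.na(seqs)) || is.null(names(seqs)) || any(names(seqs) == ""))
    stop("every peak must have a named, non-missing sequence")
  all_pwms <- unlist(pwms_by_factor, recursive = FALSE, use.names = FALSE)
  ids <- vapply(all_pwms, function(p) p$motif_id, character(1))
  hits <- matrix(FALSE, nrow = length(seqs), ncol = length(all_pwms),
                 dimnames = list(names(seqs), ids))
  for (k in seq_along(all_pwms)) {
    p <- all_pwms[[k]]
    thr <- threshold_fraction * pwm_max_score(p)
    sc <- max_scores_batch(seqs, p)
    hits[, k] <- sc[, 1] >= thr | sc[, 2] >= thr
  }
  union_hits <- vapply(pwms_by_factor, function(fp) {
    vids <- vapply(fp, function(p) p$motif_id, character(1))
    rowSums(hits[, vids, drop = FALSE]) > 0
  }, logical(length(seqs)))
  if (is.null(dim(union_hits)))
    union_hits <- matrix(union_hits, ncol = length(pwms_by_factor),
                         dimnames = list(names(seqs), names(pwms_by_factor)))
  structure(list(
    status = "ok",
    n_peaks = length(seqs),
    hits = hits,
    union_hits = union_hits,
    fraction_per_motif = colMeans(hits),
    fraction_per_factor = colMeans(union_hits),
    threshold_fraction = threshold_fraction
  ), class = "motif_occurrence")
}

#' @export
print.motif_occurrence <- function(x, ...) {
  if (identical(x$status, "empty")) {
    cat("motif occurrence: no peaks\n")
    return(invisible(x))
  }
  cat(sprintf("motif occurrence over %d peaks (threshold %.0f%% of max score)\n",
              x$n_peaks, 100 * x$threshold_fraction))
  for (f in names(x$fraction_per_factor))
    cat(sprintf("  %s union: %.1f%%\n", f, 100 * x$fraction_per_factor[[f]]))
  invisible(x)
}

#' Sample bound sequences for de novo motif discovery
#'
#' Seeded sampling without replacement of peak sequences. Accepts either a
#' set of peaks plus the genome, or pre-extracted sequences directly.
#'
#' @param peaks A `GRanges` of peaks (requires `genome`) or a named
#'   `DNAStringSet`/character vector of peak sequences.
#' @param genome A `DNAStringSet` genome, or NULL when `peaks` already
#'   holds sequences.
#' @param n Number of sequences to draw; must not exceed the peak count.
#' @param seed Integer seed; the same seed yields the identical sample.
#' @return Named character vector of sequences in original peak order.
#' @export
sample_bound_sequences <- function(peaks, genome = NULL, n, seed = 1) {
  if (is(peaks, "GRanges")) {
    if (is.null(genome)) stop("genome required when peaks are ranges")
    seqs <- extract_range_seqs(genome, peaks)
  } else {
    seqs <- setNames(as.character(peaks), names(peaks))
    if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  }
  if (n > length(seqs))
    stop(sprintf("cannot sample %d sequences from %d peaks", n, length(seqs)))
  sel <- with_seed(seed, sort(sample.int(length(seqs), n)))
  seqs[sel]
}

#' De novo motif discovery by ZOOPS EM
#'
#' Fits a zero-or-one-occurrence-per-sequence motif model with uniform
#' background by expectation-maximisation: each sequence carries a motif
#' instance at an unknown position with probability gamma, or is pure
#' background. The best of `n_restarts` seeded restarts by log-likelihood
#' is returned. Probability estimates use a pseudocount of 0.25 per cell.
#'
#' @param sequences Character vector or `DNAStringSet` of at least 50
#'   sequences, each at least `width` long.
#' @param width Motif width (default 12).
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param max_iter Maximum EM iterations per restart (default 200).
#' @param tol Relative convergence tolerance on the log-likelihood
#'   (default 1e-6).
#' @return List of class `discovered_motif`: `pwm` (source "de-novo"),
#'   `site_posterior` (n x windows matrix of site probabilities),
#'   `gamma`, `loglik_trace` of the winning restart, and `converged`.
#'   A warning is raised (and `converged = FALSE`) if the best restart
#'   hit `max_iter` without meeting `tol`.
#' @export
discover_motif <- function(sequences, width = 12, n_restarts = 10, seed = 1,
                           max_iter = 200, tol = 1e-6) {
  seqs <- as.character(sequences)
  if (length(seqs) < 50) stop("need at least 50 sequences")
  lens <- nchar(seqs)
  if (any(lens < width)) stop("every sequence must be at least `width` long")
  n <- length(seqs)
  L <- max(lens)
  idx <- matrix(NA_integer_, nrow = n, ncol = L)
  for (i in seq_len(n)) idx[i, seq_len(lens[i])] <- dna_to_idx(seqs[i])
  nw <- L - width + 1L
  # valid[i,p]: window p lies inside sequence i and contains no N
  # log-motif scores are computed against log(0.25) background
  base_slices <- lapply(seq_len(width), function(j) idx[, j:(nw + j - 1L), drop = FALSE])
  valid <- Reduce("&", lapply(base_slices, function(m) !is.na(m)))
  w_count <- pmax(rowSums(valid), 1L)

  run_em <- function(restart_seed) {
    theta <- with_seed(restart_seed, {
      i0 <- sample.int(n, 1L)
      p0 <- sample.int(lens[i0] - width + 1L, 1L)
      th <- matrix(0.15, nrow = 4, ncol = width, dimnames = list(DNA_BASES, NULL))
      seed_bases <- idx[i0, p0:(p0 + width - 1L)]
      for (j in seq_len(width)) if (!is.na(seed_bases[j])) th[seed_bases[j], j] <- 0.55
      sweep(th, 2, colSums(th), "/")
    })
    gamma <- 0.5
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    lbg <- width * log(0.25)
    Z <- NULL
    for (iter in seq_len(max_iter)) {
      lth <- log(pmax(theta, 1e-12))
      S <- matrix(0, nrow = n, ncol = nw)
      for (j in seq_len(width)) {
        v <- lth[cbind(as.vector(base_slices[[j]]), j)]
        dim(v) <- c(n, nw)
        S <- S + v
      }
      S[!valid] <- NA
      lr <- S - lbg                      # log likelihood-ratio motif vs bg
      m <- apply(lr, 1, max, na.rm = TRUE)
      er <- exp(lr - m)
      er[!valid] <- 0
      sum_r <- rowSums(er)               # sum_p ratio / exp(m)
      mix <- (1 - gamma) + (gamma / w_count) * exp(m) * sum_r
      ll <- sum(log(mix))
      Z <- (gamma / w_count) * exp(m) * er / mix   # posterior site at p
      Q <- rowSums(Z)
      # M-step
      counts <- matrix(0.25, nrow = 4, ncol = width)
      for (j in seq_len(width)) {
        bj <- base_slices[[j]]
        for (b in 1:4) counts[b, j] <- counts[b, j] + sum(Z[!is.na(bj) & bj == b])
      }
      theta <- sweep(counts, 2, colSums(counts), "/")
      gamma <- min(max(mean(Q), 1e-6), 1 - 1e-6)
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(theta = theta, gamma = gamma, loglik = ll_trace[length(ll_trace)],
         trace = ll_trace, converged = converged, Z = Z)
  }

  restart_seeds <- vapply(seq_len(n_restarts),
                          function(r) derive_seed(seed, paste0("em", r)),
                          integer(1))
  fits <- lapply(restart_seeds, run_em)
  best <- fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best iterate")
  structure(list(
    pwm = pwm(best$theta, motif_id = "de_novo", source = "de-novo"),
    site_posterior = best$Z,
    gamma = best$gamma,
    loglik_trace = best$trace,
    converged = best$converged
  ), class = "discovered_motif")
}

#' @export
print.discovered_motif <- function(x, ...) {
  cat(sprintf("de novo motif (width %d): %s  [gamma %.2f, %s]\n",
              pwm_width(x$pwm), pwm_consensus(x$pwm), x$gamma,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Pearson correlation of two probability 4-vectors with a deterministic
# rule for zero-variance columns: identical constants -> 1, else 0.
column_cor <- function(a, b) {
  if (sd(a) < 1e-12 || sd(b) < 1e-12) {
    return(if (max(abs(a - b)) < 1e-9) 1 else 0)
  }
  cor(a, b)
}

#' Align and compare two PWMs
#'
#' Slides `pwm_b` (and its reverse complement) across `pwm_a` over every
#' offset with at least `min_overlap` aligned columns. Similarity of an
#' alignment is the mean Pearson correlation of the aligned probability
#' columns; the consensus-letter match count over the aligned columns is
#' also reported. The best alignment is chosen by similarity, with ties
#' broken by larger overlap, then smaller absolute offset, then the same
#' orientation before the complementary one.
#'
#' @param pwm_a,pwm_b `pwm` objects.
#' @param min_overlap Minimum aligned columns (default 4).
#' @return List: offset (of pwm_b column 1 relative to pwm_a column 1),
#'   orientation ("same"/"complementary"), n_aligned, similarity,
#'   consensus_matches.
#' @export
compare_motifs <- function(pwm_a, pwm_b, min_overlap = 4) {
  stopifnot(is(pwm_a, "pwm"), is(pwm_b, "pwm"))
  wa <- pwm_width(pwm_a)
  orientations <- list(same = pwm_b, complementary = pwm_revcomp(pwm_b))
  best <- NULL
  for (ori in names(orientations)) {
    pb <- orientations[[ori]]
    wb <- pwm_width(pb)
    for (off in seq(-(wb - min_overlap), wa - min_overlap)) {
      a_cols <- max(1, 1 + off):min(wa, wb + off)
      b_cols <- a_cols - off
      n_al <- length(a_cols)
      if (n_al < min_overlap) next
      sims <- vapply(seq_len(n_al), function(i) {
        column_cor(pwm_a$probs[, a_cols[i]], pb$probs[, b_cols[i]])
      }, numeric(1))
      cons_match <- sum(apply(pwm_a$probs[, a_cols, drop = FALSE], 2, which.max) ==
                        apply(pb$probs[, b_cols, drop = FALSE], 2, which.max))
      cand <- list(offset = off, orientation = ori, n_aligned = n_al,
                   similarity = mean(sims), consensus_matches = cons_match)
      if (is.null(best) ||
          cand$similarity > best$similarity + 1e-12 ||
          (abs(cand$similarity - best$similarity) <= 1e-12 &&
           (cand$n_aligned > best$n_aligned ||
            (cand$n_aligned == best$n_aligned &&
             abs(cand$offset) < abs(best$offset))))) {
        best <- cand
      }
    }
  }
  best
}

#' @importFrom stats sd
NULL
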
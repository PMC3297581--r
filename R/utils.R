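#' @importFrom methods is
#' @importFrom stats rnorm runif phyper cor setNames rmultinom
#' @importFrom utils head modifyList write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Derive a stage-specific seed from a root seed. Keeps results below
# .Machine$integer.max so the value is always a valid 32-bit seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 1103 + h * 12007) %% 2147483629)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# i.i.d. random DNA of length n as a single character string.
random_dna <- function(n, base_composition = rep(0.25, 4)) {
  stopifnot(length(base_composition) == 4L,
            abs(sum(base_composition) - 1) < 1e-9)
  if (n == 0L) return("")
  idx <- sample.int(4L, n, replace = TRUE, prob = base_composition)
  rawToChar(as.raw(c(65L, 67L, 71L, 84L)[idx]))
}

# Complement of base indices (1=A,2=C,3=G,4=T); NA passes through.
complement_idx <- function(idx) c(4L, 3L, 2L, 1L)[idx]

# Encode a DNA character string as integer indices into A,C,G,T; other
# letters (N, IUPAC ambiguity) become NA.
dna_to_idx <- function(x) {
  match(strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1]], DNA_BASES)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Extract sequences for ranges from an in-memory DNAStringSet genome,
# returned as a named character vector in range order.
extract_range_seqs <- function(genome, gr) {
  ids <- gr$name %||% as.character(seq_along(gr))
  out <- character(length(gr))
  for (ch in unique(as.character(GenomeInfoDb::seqnames(gr)))) {
    sel <- which(as.character(GenomeInfoDb::seqnames(gr)) == ch)
    if (!ch %in% names(genome)) stop("chromosome absent from genome: ", ch)
    out[sel] <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::ranges(gr)[sel]))
  }
  setNames(out, ids)
}

# Truncation toward zero to whole percents, the convention used for all
# reported overlap percentages (72.59% prints as 72).
trunc_pct <- function(k, n) {
  if (n == 0) return(NA_integer_)
  as.integer(trunc(100 * k / n))
}
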
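---
title: "Methods: co-binding analysis, enrichment statistics and the synthetic validation surface"
author: "tfcobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-binding analysis, enrichment statistics and the synthetic validation surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models
and rules each stage implements, the parameters that matter and their
defaults, the numerical conventions, what the synthetic-data generator
does and does not emulate, and the design choices made where more than
one reasonable convention exists.

## The analysis in one paragraph

Two transcription factors are profiled by ChIP-Seq in a cell state of
interest; RNA-Seq compares that state against its differentiated
counterpart. Peaks filtered at q ≤ 0.001 are assigned to genes through
a 3 kb promoter window or gene-body overlap, giving each factor a
target-gene set. Co-regulation is then argued three ways: the target
sets overlap far beyond chance (hypergeometric tail), the peaks of one
factor sit near the peaks of the other (nearest-peak distances within
500 bp), and each factor's motif occurs in the other factor's peaks
(PWM scanning, supported by de novo motif discovery). Finally,
pre-ranked GSEA asks whether the binding targets concentrate among the
genes up-regulated in the profiled state, tying binding to the
expression program.

## Peak filtering and target assignment

Coordinates follow the BED convention on disk (0-based half-open) and
GRanges in memory (1-based closed); rtracklayer performs the
conversion. The q-value filter retains peaks with `q_value <=
q_threshold` (default 0.001, inclusive).

A peak is assigned to a gene when it overlaps, by at least 1 bp, the
interval `[tx_start - upstream_bp, tx_end)` for + strand genes or
`[tx_start, tx_end + upstream_bp)` for − strand genes (`upstream_bp`
default 3000). Conventions fixed here, because the rule alone does not
determine them:

* *Upstream is strand-aware*: the TSS of a − strand gene is its right
  end and its promoter window extends rightward.
* *"Overlap" means ≥ 1 bp intersection* — no summit logic, since
  summits are not part of the data model.
* *Multi-gene hits are kept.* A peak in the promoter of one gene and
  the body of another counts for both; target sets are unions.
* A peak touching both the upstream window and the gene body is
  recorded with the more specific relation, `inside`; `upstream` is
  reserved for peaks only in the window. The source analyses do not
  reveal which bookkeeping they used; the distinction affects only the
  relation label, never membership.
* Exonic and intronic positions are deliberately not distinguished:
  the assignment rule includes the whole gene body.

Boundary behaviour is pinned by tests: with a TSS at BED position
10000 and a 3000 nt window, the peak `[6999,7000)` is out and
`[7000,7001)` is in.

## Co-binding statistics

**Target-set overlap.** For sets A and B inside a universe of size N,
significance is the upper tail P(X ≥ k) of the hypergeometric
distribution with K = |A|, n = |B|, k = |A ∩ B|, computed through
`phyper` in log space so genome-scale tails do not lose precision.
Reported percentages are truncated toward zero (72.59% prints as 72):
truncation, not rounding, is what reproduces the published style of
reporting, and both raw and truncated values are emitted. The universe
defaults to the supplied annotation's gene ids and is a parameter —
results are only comparable for a stated universe.

A note on extreme tails: for published-scale inputs (universe 24901,
sets of 7976 and 5393 sharing 3915 genes) the standard tail is far
below double-precision underflow (log10 p ≈ −1900). Published
intersection p-values of order 1e-56 for counts like these cannot be
reproduced by a standard hypergeometric tail under any parameter
reading we tried; the implementation keeps the standard definition and
reports the value it computes.

**Nearest-peak proximity.** For every A peak, the distance to the
nearest B peak on the same chromosome: 0 when any B peak overlaps or is
immediately adjacent, otherwise the edge gap in bp. Summit-to-summit
distance was rejected for the same reason as above. The windowed
summary counts distances ≤ `window_bp` (inclusive — "within 500 nt"
includes 500), with A peaks on chromosomes that lack B peaks held in
the denominator at distance ∞. The observed fraction within the window
mixes true co-binding with chance proximity; the generator's truth
table lets the pipeline subtract the chance rate (measured on
non-planted peaks) and report a background-corrected estimate.

**Motif occurrence.** Sequences are scanned with per-position log2
odds, `sum_j log2(p_j(base)/bg(base))`, on both strands; windows
containing N are skipped rather than imputed. The hit threshold is a
fraction of each motif's maximum achievable score (default 0.8). No
published match threshold exists for the occurrence percentages this
style of table reports, so occurrence figures are always reported with
the threshold attached and are treated as threshold-dependent, not as
absolute constants. Multiple versions of a factor's motif combine as a
non-duplicate union: a peak with hits for two versions counts once.
The built-in motif set contains two TCF/LEF-like and two RUNX-like
matrices constructed in code from their consensus sequences; they are
synthetic stand-ins for database entries, used for planting, scanning
and comparison, and labelled as such.

## De novo motif discovery

`discover_motif` fits a ZOOPS model (zero or one occurrence per
sequence) by EM against a uniform background: each sequence carries a
motif instance at an unknown position with probability γ. EM was
chosen over Gibbs sampling so that a seed fully determines the result;
restarts (default 10) are seeded independently and the best
log-likelihood wins. Numerical conventions: pseudocount 0.25 per
matrix cell at every M-step; γ clamped to (1e-6, 1−1e-6); convergence
declared when the log-likelihood changes by less than a relative 1e-6;
non-convergence returns the best iterate with a warning rather than
failing. The likelihood is monotone by construction and the test suite
asserts it.

Motif comparison slides one PWM (and its reverse complement) across the
other over all offsets with ≥ 4 aligned columns; similarity is the mean
Pearson correlation of aligned probability columns, with
consensus-letter matches reported alongside. Ties break toward larger
overlap, then smaller |offset|, then same orientation, making the best
alignment unique.

## Expression quantification, DE and ranking

Multireads are allocated in a single pass: each group's count is split
across its candidate exons proportional to unique-read counts, with a
uniform split when all candidates have zero unique reads. The
allocation rule is described in its source as a probability computed
from unique-read density, without an explicit iteration scheme;
single-pass is the minimal faithful reading, and total read mass is
conserved to 1e-9 by test.

RPKM = count / (exonic kb) / (million mapped reads), where exonic
length is the union of exons, never the genomic span. Whether "total
reads" counts all mapped reads or exonic reads only is not specified by
the method's description; the library size is therefore an explicit
argument, and the pipeline passes all simulated mapped reads.

Differential expression is a pure fold-change rule, not a variance
model: gene is DE iff max(meanA, meanB)/min(meanA, meanB) ≥
`fold_threshold` and both condition means reach `min_rpkm`. Defaults
are 2.0 and 2.0; both are parameters because the knockdown analyses in
this style of study use 1.5-fold. Replicates are combined by the
arithmetic mean of RPKM per condition before the ratio — the combiner
is not stated in the source description of per-cell-type values from
2+2 replicates, and the arithmetic mean is the simplest choice
consistent with RPKM being already library-normalised.

Ranked lists score each gene as log2((meanA + ε)/(meanB + ε)) with
ε = 0.5 RPKM. The pseudocount is not part of the DE rule (which uses
raw means); it only protects log-ratios and Z displays from division by
zero while leaving a >100-fold observable dynamic range. Ties are
broken lexicographically by gene id so every ranking is strict and
reproducible. The Z display transform is Z = (x − μ)/σ with x =
log2(rpkm + ε) and the sample (n−1) standard deviation; σ = 0 rows map
to all zeros.

## Pre-ranked GSEA

The weighted enrichment score walks the ranked list: members add
|s|^p / Σ_set |s|^p, non-members subtract 1/(N − N_h); ES is the
running-sum extremum of largest magnitude, signed. p = 1 (the default
weighted statistic). The running sum ends at zero and ES is invariant
to positive rescaling of the scores, both asserted in tests; the
implementation is also cross-checked against an independent
implementation (fgsea) on random instances.

Significance uses **gene-set resampling**: null sets of equal size
drawn uniformly from the ranked universe. Phenotype permutation is
degenerate with two replicates per condition, which is exactly the
design the pipeline's tables have, so resampling is the default and
the permutation mode is recorded in the output metadata.

The nominal p-value is a +1-corrected two-sided estimator on |ES|:
p = (1 + #{|ES_null| ≥ |ES|}) / (1 + n_perm). Two properties drove
this choice, and we verified each by simulation: (i) for randomly drawn
sets the p-values are uniform (5% ± 3% fall below 0.05 across 200
replicates), which fails for estimators that condition the numerator on
the ES sign while dividing by all permutations; and (ii) a result
stronger than every permutation reports the floor 1/(n_perm + 1) — at
1000 permutations, 0.000999 — rather than an impossible zero, matching
the "P near 0" display convention without overstating certainty. NES
divides ES by the mean |ES| of same-sign nulls; the FDR q-value is the
standard NES-ratio across all sets tested, clipped to [0, 1]. Exact
published q-values depend on the deposited data and the desktop tool's
tie-handling and are out of scope.

## The synthetic-data generator

The generator's defaults are the study conditions the analysis was
built for, and they are fixed, not tuning knobs: 5000 genes on a 40 Mb
chromosome (1–4 kb genes, 1–4 exons, ≥ 3 kb separations), 5000/6000
peaks of width 250 bp, a co-bound fraction of 0.48 with half-normal
edge distances (sd 150 bp), motif occurrence 0.44 (TCF-like) and 0.54
(RUNX-like) in factor-A peaks, a 2+2 replicate expression design with
300 up- and 300 down-regulated genes at 2 log2 units effect and 0.25
log2 units replicate noise, 80% of up-regulated genes drawn from the
factor-A target set, a 1e6-read library with 15% multireads, and 600
sequences sampled for de novo discovery at width 12.

Choices worth explaining:

* *Background genome is i.i.d. uniform A/C/G/T* (composition
  configurable). This is the simplest null under which a scanner's
  false-positive rate is measurable and interpretable.
* *Co-bound partners use a half-normal edge-distance kernel.* The
  analysis only consumes a windowed distance summary, so the kernel
  needs the right scale, not a mechanism; sd 150 bp puts ~99.9% of
  planted partners inside the 500 bp window.
* *Planted motif instances are rejection-sampled to score above the
  planting threshold* (default 0.8 of the maximum log-odds). Without
  this, softly sampled instances are frequently undetectable at any
  fixed threshold and "occurrence" would not be a recoverable
  parameter. The truth table records every edit; later edits can
  overwrite earlier ones when two motifs land on the same bases, which
  is why measured sensitivity is slightly below 1 at high occurrence
  rates.
* *Decoy peaks (q > 0.001) are appended beyond the requested counts*,
  so significance filtering restores exactly the true sets and planted
  fractions keep their denominators.
* *Truth tables are first-class outputs.* Tests and the pipeline's
  recovery estimates never re-infer ground truth.
* *Read counts conserve the library exactly*: unique counts are a
  multinomial over exons (length × lognormal gene factor), multireads
  a multinomial over groups of 2–4 candidate exons.

What the generator does **not** emulate — and therefore what passing
recovery tests do and do not show: no read-level ChIP signal,
fragment-length or shift modelling, no GC or mappability bias, no
correlation between binding and expression beyond the planted target
bias, no isoforms, and uniform background rather than real genomic
sequence composition. Recovery of planted parameters demonstrates that
the statistics measure what they claim under the stated model; it does
not certify performance on real data with structured noise.

## Determinism and problem sizes

Every generator and every stochastic analysis stage derives its own
stream from a root seed via a fixed per-stage hash, so reruns with the
same configuration are bit-identical (the pipeline report embeds the
config hash and seed, and the test suite asserts byte-identity of
reruns). The shipped configurations use the full study scale for the
acceptance script (5000 genes, 5000/6000 peaks, 1000 permutations,
about two minutes on one CPU) and scaled-down versions
(`demo_config()`: 400 genes, 400/500 peaks, 200 permutations) for
examples and smoke tests; the scaled versions exist for convenience
and change no defaults of the study-scale configuration.

## Known limitations

* The hypergeometric overlap treats genes as exchangeable; gene length
  and peak density covary in real data, which inflates overlap. A
  shuffling-based co-occurrence null is deliberately out of scope.
* Motif occurrence percentages are threshold-dependent by nature; they
  are comparable only at a stated threshold rule.
* Single-pass multiread allocation does not iterate to a fixed point;
  genes whose unique-read counts are all zero fall back to uniform
  splits.
* The DE rule has no variance model, by design fidelity: with two
  replicates it is a fold-change filter, and its false-positive
  behaviour is characterised against a replicate-permutation null in
  the tests rather than controlled analytically.
* FDR q-values from gene-set resampling are conservative for strongly
  overlapping sets (the two factors' target sets share most of their
  genes).
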
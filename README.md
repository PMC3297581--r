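# tfcobind

Integrative ChIP-Seq + RNA-Seq analysis of transcription-factor
co-binding, for regulatory genomicists who want to ask: *do two
transcription factors act coordinately on a shared target-gene program,
and is that program tied to a cell-state switch?* The motivating setting
is a pair of hematopoietic factors (a TCF/LEF-family factor and a
RUNX-family factor) binding in a self-renewing CD34+ progenitor state,
but every stage is generic.

The package implements the full analysis as reusable, tested stages:

1. **Peak filtering and target assignment.** Peaks are kept at a
   q-value cutoff (default q ≤ 0.001) and assigned to a gene when they
   overlap the gene body or the 3 kb strand-aware window upstream of the
   TSS. The union of assigned genes is the factor's target set.
2. **Co-binding statistics** (three complementary approaches):
   - *Target-set overlap.* For target sets A and B in a universe of N
     genes, the chance of an intersection of at least
     k = \|A ∩ B\| genes is the hypergeometric upper tail
     P(X ≥ k), X ~ Hypergeom(N, K=\|A\|, n=\|B\|). Percentages are
     reported truncated to whole percents, the field's convention.
   - *Peak proximity.* For every A peak, the edge-gap distance to the
     nearest B peak (0 for overlap), summarised as the fraction within
     an inclusive 500 bp window.
   - *Motif occurrence.* PWM log-odds scanning of peak sequences on
     both strands, with per-factor non-duplicate union over motif
     versions, plus ZOOPS EM de novo motif discovery and
     motif-to-motif alignment (Pearson column correlation).
3. **Expression quantification and ranking.** RPKM with fractional
   multiread allocation proportional to unique-read density; a
   fold-change differential-expression rule (≥ 2-fold with ≥ 2 RPKM in
   both conditions, both parameters); per-gene Z display transform;
   fold-change-ranked gene lists.
4. **Pre-ranked GSEA.** The weighted enrichment score
   ES = extremum of the running sum (hits add \|s\|^p / Σ\|s\|^p,
   misses subtract 1/(N − N_h)), with permutation significance, NES and
   FDR from a gene-set resampling null.
5. **A synthetic-data generator** that plants known co-binding
   fractions, motif occurrence rates, and target-biased differential
   expression, emitting truth tables so every downstream statistic can
   be checked against ground truth — this is the package's validation
   surface, and the pipeline runs on it end to end.

## Worked example

The published-scale overlap arithmetic, directly:

```r
library(tfcobind)
ov <- target_overlap(sprintf("g%05d", 1:7976),
                     sprintf("g%05d", c(1:3915, 7977:9454)),
                     sprintf("g%05d", 1:24901))
print(ov)
#> target overlap: 3915 common of 7976 (A) and 5393 (B) in universe 24901
#>   49% of A, 72% of B; hypergeometric p = 0
```

(49% and 72% are truncated percents; the upper-tail p-value underflows
double precision — see the vignette on why such intersections are
astronomically unlikely.)

The full pipeline on a small synthetic dataset with planted structure:

```r
rep <- run_pipeline(demo_config(seed = 1), out_dir = "demo_out")
#> [synth] generating annotation: 400 genes on 1 chromosome(s)
#> [synth] generating peak sets: 400 A, 500 B, cobind fraction 0.48
#> [assign] factor A: 216/400 peaks -> 166 targets; factor B: 279/500 -> 206
#> ...
#> [report] written to demo_out/report.json

rep$cobinding$fraction_within            # 0.5925  (planted + background)
rep$cobinding$recovered_cobind_fraction  # 0.48    (background-corrected)
rep$motif$fraction_per_factor            # TCF7 0.43, RUNX1 0.5525
rep$enrichment$targets_a$es              # 0.584
rep$enrichment$targets_a$nominal_p       # 0.00498 (= 1/201 at 200 permutations)
```

59% of A peaks lie within 500 bp of a B peak; subtracting the chance
rate measured on non-planted peaks recovers the planted co-bound
fraction of 0.48 exactly. Binding targets of factor A are strongly
enriched among genes up-regulated in condition A (positive ES, p at the
permutation floor), mirroring how co-binding evidence and expression
enrichment are combined to argue for co-regulation of a cell state.

A thin CLI wraps the same functions (`exec/tfcobind` after install):
`tfcobind run --config cfg.json --out outdir`, plus `synth`, `quantify`,
`assign`, `cobind`, `motif`, `enrich` subcommands.

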
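# spatialMTR

Regional missense-intolerance analysis for prioritising pathogenic missense
variants in severe early-onset disorders such as developmental and epileptic
encephalopathies (DEEs). Written for analysts who hold case/control variant
tables (e.g. de novo mutation lists from trio sequencing), population
variation, protein structures and alignments, and want per-position
intolerance tracks plus the enrichment statistics that compare cohorts
against them.

## What it computes

**Missense Tolerance Ratio (MTR).** For a window $W$ of codons around a
focal position,

$$\mathrm{MTR}(W) = \frac{o_{mis}/(o_{mis}+o_{syn})}{e_{mis}/(e_{mis}+e_{syn})}$$

where $o$ counts distinct observed missense/synonymous variants in $W$ and
$e$ counts the possible single-nucleotide substitutions of each class under
the standard genetic code. Values below 1 mean the population shows fewer
missense variants than the sequence allows — purifying selection. Shipped
window sizes: 41 codons (v1) and 21 codons (v2).

**MTR3D.** The same ratio with the window replaced by the set of codons
whose mapped residues lie within a radius (default 8 Å) of the focal
residue's C-alpha in a protein structure, after aligning the protein
sequence to the structure's residues (`map_sequence_to_structure()`,
`select_structure()` preferring experimental structures and the highest
sequence/structure match fraction).

**MTRX.** A random-forest consensus over MTR v1, MTR v2, MTR3D and relative
solvent accessibility (Shrake–Rupley), emitting P(deleterious) in [0, 1].
The combiner is trainable (`train_mtrx()`) with a shipped synthetic-label
self-test recipe; published weights are not redistributed.

**Conservation.** Per-column Jensen–Shannon divergence from a multiple
sequence alignment against BLOSUM62 background frequencies, window-smoothed,
with gap handling.

**Enrichment statistics.** Percentile rank scores, strict threshold
classification with printed-style integer percentages
(`fraction_intolerant()`), two-sample Wilcoxon rank-sum group tests
(`compare_groups()`), pairwise Spearman predictor correlations, and a
lollipop-plot data export.

**Synthetic study generator.** Every input the pipeline consumes can be
generated with planted ground truth — genes, population variation depleted
in planted intolerant regions, case cohorts enriched there, toy structures
with controllable spatial neighbourhoods, alignments with conserved blocks —
so the whole analysis is testable without any download
(`synthetic_cohort_spec()`, `generate_study()`).

## Worked example

A 300-codon gene with missense observation suppressed five-fold in codons
101–175; the sliding-window ratio recovers the planted region, and a folded
contact lets the spatial score see depletion that the sequence window at
codon 30 cannot:

```r
library(spatialMTR)

g      <- generate_gene(300, seed = 42, gene_id = "DEMO1")
region <- data.frame(start = 101, end = 175)
pop    <- generate_population_variants(g, density = 4.5, regions = region,
                                       multiplier = 0.2, seed = 43)
mtr    <- compute_mtr(g, pop, window_spec(21))
mtr
#> <IntoleranceTrack DEMO1 / MTR_21: 300 positions, 300 scored>

round(mean(mtr$score[101:175]), 3)    # inside the planted region
#> [1] 0.56
round(mean(mtr$score[-(101:175)]), 3) # outside
#> [1] 0.978

cutoff <- percentile_threshold(mtr, 25)
round(cutoff, 3)
#> [1] 0.847

# fold codon 140 (depleted region) onto codon 30 (tolerant context)
st <- generate_structure(g, "folded", contact_pairs = list(c(30, 140, 6)))
m3 <- compute_mtr3d(g, pop, st$mapping, st$structure, radius = 8)
round(c(MTR_21 = mtr$score[30], MTR3D = m3$score[30]), 3)
#>  MTR_21  MTR3D
#>   1.004   0.759

# classify four case variants against the pooled cutoff
case <- variant_set(data.frame(
  gene_id = "DEMO1", codon_index = c(110, 130, 150, 42),
  ref_aa = substring(g$protein_seq, c(110, 130, 150, 42),
                     c(110, 130, 150, 42)),
  alt_aa = "K", consequence = "missense", cohort = "case"), label = "case")
fraction_intolerant(score_variants(list(DEMO1 = mtr), case), cutoff,
                    group = "case")
#> <EnrichmentResult case: 3 of 4 (75%) < 0.847>
```

Three of the four case variants sit in the planted region and fall below
the data-derived 25th-percentile cutoff; the variant at codon 42 does not.
The full pipeline (`run_analysis()`) does this at study scale: 34 genes,
cohorts of 276/454/762 variants, all four threshold blocks, group tests,
correlation matrices and a JSON report that is byte-identical on rerun with
the same seed.

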
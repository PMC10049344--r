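---
title: "Sequence and spatial missense tolerance: models, parameters and design choices"
author: "spatialMTR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence and spatial missense tolerance: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialMTR)
```

## The problem

Severe, early-onset disorders such as developmental and epileptic
encephalopathies (DEEs) are dominated by de novo missense mutations, but a
patient exome contains many benign missense variants too. Regional
intolerance scores help separate the two: a region of a protein where the
general population shows far fewer missense variants than the local codon
composition would allow is under purifying selection, and a patient variant
falling there is a stronger pathogenicity candidate. This package implements
that idea in three forms — a sliding window along the codon sequence, a
spatial window on the folded protein, and a machine-learned consensus — plus
the conservation scoring and case/control statistics used to evaluate them.

## The tolerance ratio

For a window $W$ of codons, with $o_{mis}$ and $o_{syn}$ the numbers of
*distinct* observed missense and synonymous variants in $W$, and $e_{mis}$,
$e_{syn}$ the numbers of *possible* single-nucleotide substitutions of each
class over the codons of $W$ (each codon contributes its 9 possible SNVs,
classified by the standard genetic code; nonsense possibilities are
excluded):

$$\mathrm{MTR}(W) \;=\;
\frac{o_{mis} / (o_{mis} + o_{syn})}{e_{mis} / (e_{mis} + e_{syn})}$$

Values near 1 mean missense variation is observed in proportion to
opportunity (tolerance); values below 1 mean missense depletion
(intolerance). `compute_mtr()` slides a symmetric window of odd size over
every codon; the two conventional sizes are 41 codons (v1) and 21 codons
(v2), both shipped as defaults in `analysis_config()`.

Numerical and boundary choices, each of which was genuinely open:

* **Window truncation.** Windows are clipped to `[1, L]` near the termini
  (asymmetric windows) rather than dropping terminal codons, so every codon
  receives a score when observations exist.
* **Empty windows.** A window with no observed missense or synonymous
  variant yields a *missing* score, not 0 or 1: the ratio is undefined
  there, and downstream counts are always over variants "with a valid
  score". A window with only synonymous observations is a genuine 0.
* **Uniqueness.** Observed variants are counted as distinct variant keys,
  never allele counts; duplicated records cannot inflate the numerator
  (this makes the score invariant to duplication of the input list, which
  is tested).
* **Possibility counting.** The expected side uses unweighted SNV
  possibility counts. No per-site mutability or CpG weighting and no
  coverage correction is applied; a mutation-rate-calibrated denominator is
  out of scope and would change absolute values but not the
  observed-versus-expected logic.
* **Variant keys.** Cohort variants are keyed at the amino-acid level
  `(gene, position, ref, alt)`. Population variant sets additionally carry
  the alternate codon: two different nucleotide changes producing the same
  synonymous outcome are distinct observations of standing variation, and
  collapsing them would bias the observed synonymous count downward and
  push null scores above 1. The generator emits this column; user tables
  without it are simply keyed at the amino-acid level.

## Thresholds and percentiles

Classification is always *strict* (`score < cutoff`), matching a "top
q% most intolerant" reading. `percentile_threshold()` pools all non-missing
scores and takes the lower-interpolation order statistic
(index $\lfloor (n-1)q/100 \rfloor + 1$). On real exome-wide data the
published 25th percentile corresponds to a cutoff of 0.78; that constant is
shipped as a default *configuration* value in `analysis_config()`, while
synthetic exomes derive their own pooled percentile — both appear in every
report so the two are never conflated. The same applies to the published
spatial-score cutoffs (0.75 intolerant, 0.5 strongly intolerant) and the
consensus cutoff (0.75, damaging direction *above*).

## The spatial score

`compute_mtr3d()` replaces the sequence window with the set of codons whose
mapped residues lie within a Euclidean radius of the focal residue's
representative atom. The same ratio, the same conventions; only the window
changes. Choices:

* **Representative atom.** C-alpha, the standard for residue-level contact
  definitions; residues lacking it are flagged and excluded from
  neighbourhoods. Configurable via `read_structure(rep_atom=)`.
* **Radius.** Default 8 Å, a common residue-contact scale; the exact radius
  behind the published spatial scores is not restated in the source
  material, so it is an explicit parameter (`analysis_config(radius=)`)
  recorded in every report rather than a hidden constant.
* **Consistency.** Unmapped neighbourhood residues contribute to neither
  the observed nor the expected sums, keeping numerator and denominator
  over the same codon set. Codons without a mapped residue are missing —
  a valid spatial score exists only where the sequence-to-structure mapping
  succeeds, which is why spatially scored variant counts are always
  smaller than sequence-scored ones.
* **Equivalence check.** On a synthetic extended chain (3.8 Å spacing) a
  radius strictly between 10 and 11 backbone steps makes the spatial
  neighbourhood exactly the 21-codon window, and the two tracks must agree
  bit for bit (all counts are integers, so no floating tolerance is
  needed). The test uses 39 Å: exactly 38 Å sits on a floating-point knife
  edge, since `10 * 3.8` need not round to precisely 38.

## Structures, mapping and selection

`read_structure()` parses one protein chain from a PDB file (first model;
highest-occupancy conformer per atom when alternate locations exist;
insertion codes give distinct residue identities).
`map_sequence_to_structure()` aligns the gene's protein sequence to the
structure's residue sequence with an affine-gap, identity-scored alignment
whose end gaps are free on the gene side, so a partial structure maps onto
the region it covers. The fraction of aligned pairs whose amino acids agree
(`match_fraction`) is the selection criterion: `select_structure()` prefers
experimental structures over homology models, then the highest match
fraction, with deterministic tie-breaks (more pairs, then lexicographic
id). Passing a variant position restricts candidates to structures covering
it, so different partial structures may serve different variants.

Relative solvent accessibility uses Shrake–Rupley sphere sampling (960
deterministic golden-spiral points per atom, probe 1.4 Å) over van der
Waals radii by element, summed per residue and normalised by
theoretical maximal accessible areas per amino acid (`MAX_ASA`). The
sampler is validated against the closed form $4\pi (r+r_p)^2$ for an
isolated sphere.

## The consensus combiner

`train_mtrx()` fits a random forest (500 trees) on four features — the
41- and 21-codon tolerance ratios, the spatial ratio, and RSA — and emits
P(deleterious) in [0, 1], higher = more likely damaging. The published
consensus model's training data and weights are not redistributable, so
the package ships the *trainable* combiner plus a synthetic-label recipe
(`mtrx_synthetic_labels()`: deleterious iff the 21-codon ratio < 0.5, a
noise-free separable task) used for the self-test
(`mtrx_self_test()`: stratified 80/20 holdout, default seed 20230307).
Every report records the training provenance. Rows with any missing
feature are excluded from training and score as missing, mirroring the
"valid score" bookkeeping. Fixing the seed makes training and scoring
reproducible bit for bit.

## Conservation

`column_jsd()` scores one alignment column as the Jensen–Shannon
divergence between the column's pseudocounted amino-acid distribution
(pseudocount 1/50 per letter) and a background distribution — the BLOSUM62
marginal frequencies by default, uniform on request. Entropies are in bits,
which bounds the divergence by 1 and gives a [0, 1] score with higher =
more conserved. `windowed_conservation()` smooths with flanking columns,
$s_i = (1-\lambda)\,j_i + \lambda\,\overline{j}_{\mathrm{flank}}$
(window 3 columns each side, $\lambda = 0.5$), and marks columns with more
than 30% gaps missing — conservation cannot be measured confidently
through gaps. Alignment columns are taken to correspond 1:1 to gene codon
positions with the gene as ungapped reference row; building alignments is
out of scope (they are inputs or generator products).

On the synthetic study the per-position Pearson correlation between
conservation and the tolerance ratio is strongly *negative*, because the
generator plants conserved blocks exactly where missense observation is
depleted — high divergence, low ratio. Real data shows far weaker and
differently signed relationships; that correlation is one of the real-data
quantities this package recomputes only when a user supplies real inputs.

## Enrichment statistics

* `rank_scores()`: percentile rank scores in [0, 1] (average ranks for
  ties, min to 0, max to 1), oriented so higher = more damaging;
  predictors where low raw values are damaging (the tolerance ratios,
  SIFT, FATHMM) are inverted before ranking.
* `fraction_intolerant()`: strict threshold classification with the
  percentage rounded half-away-from-zero to an integer, the way results
  tables print it.
* `compare_groups()`: the default group test is the two-sample Wilcoxon
  rank-sum (Mann–Whitney). The compared cohorts are independent samples of
  unequal size, for which a signed-rank test is undefined; a paired
  signed-rank option exists for genuinely paired designs. Two-sided by
  default. Raw p-values are reported per predictor; a Benjamini–Hochberg
  column is available but off by default.
* `pairwise_correlations()`: Spearman by default, pairwise-complete, with
  per-cell sample sizes; columns with fewer than 3 complete pairs against
  every other column are excluded with a warning.

## The synthetic study

`generate_study()` is the package's test bed and defines its study
conditions; all generators are pure functions of (parameters, seed) and
restore the caller's RNG state. Defaults
(`synthetic_cohort_spec()`):

| parameter | default | rationale |
|---|---|---|
| genes | 34, lengths 200–600 codons | the size of a curated DEE panel; desk-scale lengths (real channel genes are longer, which only adds computation, not structure) |
| depletion region | one per gene, 25% of codons, missense observation × 0.2 | a quarter of the protein under strong constraint, the scale of a functional domain |
| population density | 4.5 observed variants per codon (of 9 possible SNVs) | a deeply sampled aggregate population in which half of all possible substitutions have been seen |
| case enrichment | 3× relative draw probability from depleted regions | gives an expected 50% of case variants in regions covering 25% of codons — a strong but not degenerate signal |
| cohort sizes | 276 cases, 454 and 762 controls | the trio-sequencing case/control design the statistics are aimed at |

What the generator emulates: missense-specific depletion with unaffected
synonymous variation; case cohorts preferentially ascertained from
constrained regions; partial structure availability; conserved alignment
blocks coinciding with constrained regions. What it does not: real
allele-frequency spectra, trinucleotide mutation-rate structure, coverage
artefacts, transcript ambiguity, or realistic protein folds (topologies
are an extended chain, an ideal helix — radius 2.3 Å, rise 1.5 Å, 100° per
residue — and arc-folded chains hitting requested contact distances).
Passing tests therefore demonstrate correctness of the machinery and
recoverability of planted signal under clean conditions, not performance
on real exomes.

A note on the helix fixture: ideal alpha-helix C-alpha geometry places
residue $i+3$ *closer* to $i$ than $i+2$ (≈5.1 Å vs ≈5.4 Å), so no radius
captures exactly `{i-2, …, i+2}` on a helix; exact-window neighbourhood
tests use the extended chain, and helix tests assert the true geometry
(3.8 Å steps, the $i,i{+}3$ turn contact).

## Problem sizes and reproducibility

The shipped experiments use the default conditions above: single-study
analyses run in seconds; the multi-seed calibration checks use 100 seeds
for region recovery and cohort comparisons and 500 seeds for the null
uniformity of rank-test p-values, sizes at which the binomial error on a
"≥ 95 of 100 seeds" criterion is small while the whole suite stays
desk-scale. `scripts/acceptance.R` regenerates every reported quantity
from scratch from a single `--seed`.

## Known limitations

* One transcript per gene; multi-transcript collapsing is the caller's
  responsibility (records disagreeing with the gene model are rejected
  with a logged count, not silently kept).
* Missense-only analysis: multi-nucleotide and indel records are dropped
  at read time with a count.
* Single chain per structure; no quaternary assemblies, no mmCIF.
* The unweighted expected-side possibility count (no mutability model)
  makes absolute scores comparable within a dataset but not directly to
  scores computed with a calibrated mutation model.
* Published real-data values (the 0.78 exome-wide cutoff itself, real
  per-predictor test p-values, the real conservation–tolerance
  correlation, published consensus-model scores) depend on inputs that are
  not redistributable here; the pipeline recomputes them when a user
  supplies those inputs, and the synthetic suite tests the machinery in
  their place.
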
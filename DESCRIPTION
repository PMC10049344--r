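Package: spatialMTR
Title: Sequence and Spatial Missense Tolerance Scoring for Variant Prioritisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regional missense constraint analysis for prioritising pathogenic
    missense variants in severe early-onset disorders such as developmental and
    epileptic encephalopathies. Implements the sliding-window Missense Tolerance
    Ratio (MTR) over gene codons, its spatial analogue (MTR3D) computed over
    residue neighbourhoods on protein structures, a random-forest consensus
    combiner (MTRX) over MTR, MTR3D and relative solvent accessibility, and
    Jensen-Shannon-divergence conservation from multiple sequence alignments.
    Also provides the case/control enrichment statistics used to compare de
    novo mutation cohorts against controls (fraction-intolerant classification,
    rank-score percentiles, rank-based group tests, pairwise predictor
    correlations) and a fully synthetic data generator -- genes, population
    variation depleted in planted intolerant regions, enriched case cohorts,
    toy structures and alignments -- so the whole pipeline is testable without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    seqinr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
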
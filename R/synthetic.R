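# Synthetic study generator: genes as random sense-codon sequences,
# population variation depleted of missense in planted intolerant regions,
# case cohorts preferentially drawn from those regions, toy structures with
# controllable spatial neighbourhoods, and alignments with planted conserved
# blocks. Every generator is a pure function of (parameters, seed): the
# caller's RNG state is saved and restored.

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Synthetic cohort specification
#'
#' The study conditions for the synthetic pipeline: gene panel size, planted
#' missense-depletion regions, population variant density, and cohort sizes
#' mirroring a trio-sequencing case/control design (276 case de novo
#' variants against control groups of 454 and 762).
#'
#' @param n_genes Number of genes (default 34, the size of a curated
#'   disease gene panel).
#' @param gene_length_range Codon length range genes are drawn from.
#' @param depletion_coverage Fraction of each gene's codons covered by its
#'   planted intolerant region (default 0.25).
#' @param depletion_multiplier Multiplier (< 1) on the missense observation
#'   probability inside planted regions (default 0.2).
#' @param population_density Expected observed population variants per codon
#'   outside depleted regions, out of the 9 possible substitutions
#'   (default 4.5, i.e. half of all possible substitutions observed --
#'   a deeply sampled population).
#' @param case_enrichment Relative probability that a case variant falls in
#'   a depletion region versus outside (default 3).
#' @param n_case Case cohort size (default 276).
#' @param n_controls Control cohort sizes (default `c(454, 762)`).
#' @param n_dee_genes How many genes carry the disease-panel flag
#'   (default 15).
#' @param gc_bias P(G or C) per generated base (default 0.5).
#' @return A `SyntheticCohortSpec` list.
#' @export
synthetic_cohort_spec <- function(n_genes = 34L,
                                  gene_length_range = c(200L, 600L),
                                  depletion_coverage = 0.25,
                                  depletion_multiplier = 0.2,
                                  population_density = 4.5,
                                  case_enrichment = 3,
                                  n_case = 276L,
                                  n_controls = c(454L, 762L),
                                  n_dee_genes = 15L,
                                  gc_bias = 0.5) {
  stopifnot(depletion_multiplier > 0, depletion_multiplier <= 1,
            depletion_coverage >= 0, depletion_coverage < 1,
            population_density > 0, population_density <= 9,
            case_enrichment > 0, n_genes >= 1)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 depletion_coverage = depletion_coverage,
                 depletion_multiplier = depletion_multiplier,
                 population_density = population_density,
                 case_enrichment = case_enrichment,
                 n_case = as.integer(n_case),
                 n_controls = as.integer(n_controls),
                 n_dee_genes = as.integer(min(n_dee_genes, n_genes)),
                 gc_bias = gc_bias),
            class = "SyntheticCohortSpec")
}

#' Generate a random gene model
#'
#' Random sense codons (no internal stops), base composition controlled by
#' `gc_bias`; translation consistency holds by construction.
#'
#' @param length Gene length in codons (>= 10).
#' @param gc_bias P(G or C) per base.
#' @param seed Integer seed; the same seed reproduces the gene bit for bit.
#' @param gene_id Gene identifier.
#' @param is_dee_gene Disease-panel flag.
#' @return A `GeneModel`.
#' @export
generate_gene <- function(length, gc_bias = 0.5, seed = NULL,
                          gene_id = "geneS1", is_dee_gene = FALSE) {
  stopifnot(length >= 10)
  .with_seed(seed, {
    p <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
           G = gc_bias / 2, T = (1 - gc_bias) / 2)
    draw <- function(n) {
      b <- sample(DNA_BASES, 3 * n, replace = TRUE, prob = p)
      apply(matrix(b, ncol = 3), 1, paste, collapse = "")
    }
    codons <- draw(length)
    repeat {
      stops <- which(codons %in% STOP_CODONS)
      if (length(stops) == 0) break
      codons[stops] <- draw(length(stops))
    }
    gene_model(gene_id, codons, is_dee_gene = is_dee_gene)
  })
}

# All possible SNVs of a gene as a data frame (codon_index + .snv_table cols)
.gene_possible_snvs <- function(gene) {
  idx_list <- split(seq_len(nrow(.snv_table)), .snv_table$codon)
  rows <- idx_list[gene$codons]
  counts <- lengths(rows)
  df <- .snv_table[unlist(rows, use.names = FALSE), , drop = FALSE]
  df$codon_index <- rep(seq_along(gene$codons), counts)
  rownames(df) <- NULL
  df
}

#' Generate population variants for one gene
#'
#' Each possible single-nucleotide substitution is observed independently
#' with probability `density / 9`; inside depletion regions the missense
#' observation probability is multiplied by `multiplier` while synonymous
#' observation is unaffected -- the signature of purifying selection against
#' missense change. Variants carry an `alt_codon` column so distinct
#' nucleotide changes remain distinct observations.
#'
#' @param gene A `GeneModel`.
#' @param density Expected observed variants per codon (out of 9 possible).
#' @param regions Data frame with `start`, `end` codon indices of depleted
#'   regions (optional).
#' @param multiplier Missense observation multiplier inside regions.
#' @param seed Integer seed.
#' @return A `VariantSet` labelled `"population"`.
#' @export
generate_population_variants <- function(gene, density = 4.5, regions = NULL,
                                         multiplier = 0.2, seed = NULL) {
  .with_seed(seed, {
    snvs <- .gene_possible_snvs(gene)
    p <- rep(density / 9, nrow(snvs))
    if (!is.null(regions) && nrow(regions) > 0) {
      in_region <- rep(FALSE, gene$length)
      for (k in seq_len(nrow(regions))) {
        in_region[regions$start[k]:regions$end[k]] <- TRUE
      }
      dep <- in_region[snvs$codon_index] & snvs$consequence == "missense"
      p[dep] <- p[dep] * multiplier
    }
    obs <- stats::runif(nrow(snvs)) < p
    df <- snvs[obs, , drop = FALSE]
    out <- data.frame(gene_id = gene$gene_id, codon_index = df$codon_index,
                      ref_aa = df$ref_aa, alt_aa = df$alt_aa,
                      consequence = df$consequence, cohort = "population",
                      alt_codon = df$alt_codon, stringsAsFactors = FALSE)
    variant_set(out, label = "population",
                provenance = sprintf("synthetic; density=%g multiplier=%g",
                                     density, multiplier))
  })
}

#' Generate case and control cohorts over a gene panel
#'
#' Case variants are drawn without replacement from the unique possible
#' missense substitutions (amino-acid level) with probability proportional
#' to `case_enrichment` inside planted depletion regions; control cohorts
#' are drawn uniformly. Cohort sizes are honoured exactly.
#'
#' @param genes Named list of `GeneModel`s.
#' @param regions Named list (by gene id) of region data frames
#'   (`start`, `end`).
#' @param spec A `SyntheticCohortSpec`.
#' @param seed Integer seed.
#' @return A list of `VariantSet`s: `case`, `control1`, `control2`.
#' @export
generate_cohorts <- function(genes, regions, spec, seed = NULL) {
  .with_seed(seed, {
    pool <- do.call(rbind, lapply(genes, function(g) {
      snvs <- .gene_possible_snvs(g)
      snvs <- snvs[snvs$consequence == "missense", , drop = FALSE]
      key <- paste(snvs$codon_index, snvs$ref_aa, snvs$alt_aa)
      snvs <- snvs[!duplicated(key), , drop = FALSE]
      in_region <- rep(FALSE, g$length)
      rg <- regions[[g$gene_id]]
      if (!is.null(rg) && nrow(rg) > 0) {
        for (k in seq_len(nrow(rg))) in_region[rg$start[k]:rg$end[k]] <- TRUE
      }
      data.frame(gene_id = g$gene_id, codon_index = snvs$codon_index,
                 ref_aa = snvs$ref_aa, alt_aa = snvs$alt_aa,
                 in_region = in_region[snvs$codon_index],
                 stringsAsFactors = FALSE)
    }))
    rownames(pool) <- NULL
    sizes <- c(spec$n_case, spec$n_controls)
    if (any(sizes > nrow(pool))) {
      stop("requested cohort size exceeds the ", nrow(pool),
           " possible unique missense variants", call. = FALSE)
    }
    draw <- function(n, weights, label) {
      idx <- sample.int(nrow(pool), n, replace = FALSE, prob = weights)
      df <- pool[idx, c("gene_id", "codon_index", "ref_aa", "alt_aa")]
      df$consequence <- "missense"
      df$cohort <- label
      variant_set(df, label = label,
                  provenance = "synthetic cohort; MPC-style pre-filters assumed upstream")
    }
    w_case <- ifelse(pool$in_region, spec$case_enrichment, 1)
    list(case = draw(spec$n_case, w_case, "case"),
         control1 = draw(spec$n_controls[1], NULL, "control1"),
         control2 = draw(spec$n_controls[2], NULL, "control2"))
  })
}

# 2D rotation of a direction vector about the z axis
.rot_z <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2], v[3])
}

#' Generate a synthetic protein structure for a gene
#'
#' Topologies: `"extended"` places residues on a straight line with fixed
#' spacing (so spatial neighbourhoods coincide with sequence windows);
#' `"helix"` builds an ideal alpha-helix (radius 2.3 A, rise 1.5 A per
#' residue, 100 degrees per turn step); `"folded"` starts from the extended
#' chain and bends the segment between each requested contact pair onto a
#' circular arc so the pair ends up at the stated distance, bringing
#' sequence-distant codons into one spatial neighbourhood. The emitted true
#' mapping is the identity.
#'
#' @param gene A `GeneModel`.
#' @param topology `"extended"`, `"helix"` or `"folded"`.
#' @param spacing Consecutive-residue spacing in Angstrom (default 3.8, the
#'   canonical CA-CA distance).
#' @param contact_pairs For `"folded"`: list of `c(i, j, distance)` triples
#'   on disjoint segments. Infeasible requests (distance not in
#'   `(0, (j - i) * spacing)`, or overlapping segments) are errors.
#' @param source_kind Reported structure provenance class.
#' @param seed Unused for the deterministic topologies; accepted for
#'   interface uniformity.
#' @return A list with `structure` (a `StructureModel`) and `mapping` (the
#'   identity `SeqStructMap`).
#' @export
generate_structure <- function(gene, topology = c("extended", "helix",
                                                  "folded"),
                               spacing = 3.8, contact_pairs = NULL,
                               source_kind = "experimental", seed = NULL) {
  topology <- match.arg(topology)
  L <- gene$length
  coords <- matrix(0, nrow = L, ncol = 3)
  if (topology == "extended") {
    coords[, 1] <- (seq_len(L) - 1L) * spacing
  } else if (topology == "helix") {
    r <- 2.3; rise <- 1.5; step <- 100 * pi / 180
    i <- seq_len(L) - 1L
    coords[, 1] <- r * cos(i * step)
    coords[, 2] <- r * sin(i * step)
    coords[, 3] <- i * rise
  } else {
    if (is.null(contact_pairs) || length(contact_pairs) == 0) {
      stop("folded topology requires contact_pairs", call. = FALSE)
    }
    cp <- do.call(rbind, lapply(contact_pairs, function(x) x))
    cp <- cp[order(cp[, 1]), , drop = FALSE]
    if (any(cp[, 1] >= cp[, 2]) || any(cp[, 1] < 1) || any(cp[, 2] > L)) {
      stop("contact pairs must satisfy 1 <= i < j <= L", call. = FALSE)
    }
    if (nrow(cp) > 1 && any(cp[-1, 1] <= cp[-nrow(cp), 2])) {
      stop("contact pair segments overlap; infeasible", call. = FALSE)
    }
    pos <- c(0, 0, 0)
    dir <- c(1, 0, 0)
    coords[1, ] <- pos
    turn_until <- rep(0, L)  # per-step turn angle applied before step to k
    for (r in seq_len(nrow(cp))) {
      i <- cp[r, 1]; j <- cp[r, 2]; d <- cp[r, 3]
      n <- j - i
      if (d <= 0 || d >= n * spacing) {
        stop("contact distance ", d, " infeasible for segment of ", n,
             " steps", call. = FALSE)
      }
      chord <- function(theta) spacing * sin(n * theta / 2) / sin(theta / 2)
      theta <- stats::uniroot(function(t) chord(t) - d,
                              lower = 1e-9, upper = 2 * pi / n - 1e-9,
                              tol = 1e-12)$root
      turn_until[(i + 1):j] <- theta
    }
    for (k in 2:L) {
      if (turn_until[k] != 0) dir <- .rot_z(dir, turn_until[k])
      pos <- pos + spacing * dir
      coords[k, ] <- pos
    }
  }
  aa <- strsplit(gene$protein_seq, "")[[1]]
  residues <- data.frame(residue_id = as.character(seq_len(L)),
                         amino_acid = aa, x = coords[, 1], y = coords[, 2],
                         z = coords[, 3], has_rep = TRUE,
                         stringsAsFactors = FALSE)
  sm <- structure_model(paste0(gene$gene_id, "_", topology), residues,
                        source_kind = source_kind)
  mapping <- structure(list(
    gene_id = gene$gene_id, structure_id = sm$structure_id,
    source_kind = source_kind,
    pairs = data.frame(codon_index = seq_len(L),
                       residue_id = as.character(seq_len(L)),
                       match = TRUE, stringsAsFactors = FALSE),
    match_fraction = 1
  ), class = "SeqStructMap")
  list(structure = sm, mapping = mapping)
}

#' Generate a multiple sequence alignment with planted conserved blocks
#'
#' The gene's protein sequence is the (ungapped) reference row; each other
#' sequence substitutes residues at `substitution_rate` per position,
#' reduced by `conserved_multiplier` inside conserved blocks. With
#' probability `gap_rate` a column is gapped across all sequences,
#' emulating unalignable stretches.
#'
#' @param gene A `GeneModel`.
#' @param conserved_blocks List of `c(start, end)` codon ranges.
#' @param n_sequences Alignment depth (>= 2, including the reference).
#' @param substitution_rate Per-position substitution probability outside
#'   blocks.
#' @param gap_rate Probability a column is gapped.
#' @param conserved_multiplier Substitution-rate multiplier inside blocks.
#' @param seed Integer seed.
#' @return A list with `matrix` (sequences x columns) and `ids`.
#' @export
generate_alignment <- function(gene, conserved_blocks = list(),
                               n_sequences = 30L, substitution_rate = 0.4,
                               gap_rate = 0.02, conserved_multiplier = 0.05,
                               seed = NULL) {
  stopifnot(n_sequences >= 2)
  .with_seed(seed, {
    L <- gene$length
    ref <- strsplit(gene$protein_seq, "")[[1]]
    rate <- rep(substitution_rate, L)
    for (b in conserved_blocks) rate[b[1]:b[2]] <- substitution_rate *
      conserved_multiplier
    m <- matrix(rep(ref, each = n_sequences), nrow = n_sequences)
    bg <- BLOSUM62_BACKGROUND
    for (s in 2:n_sequences) {
      mut <- stats::runif(L) < rate
      if (any(mut)) {
        m[s, mut] <- vapply(which(mut), function(i) {
          sample(AA_ALPHABET, 1, prob = bg)
        }, character(1))
      }
    }
    gap_cols <- stats::runif(L) < gap_rate
    m[, gap_cols] <- "-"
    rownames(m) <- c(gene$gene_id, paste0("homolog", seq_len(n_sequences - 1)))
    list(matrix = m, ids = rownames(m))
  })
}

#' Generate a complete synthetic study
#'
#' One RNG stream drives the whole study: genes (lengths uniform over the
#' spec's range, one planted depletion region per gene at random position),
#' per-gene population variation, and the three cohorts.
#'
#' @param spec A `SyntheticCohortSpec`.
#' @param seed Integer seed.
#' @return A list with `genes` (named list), `regions` (named list of data
#'   frames), `population` (named list of `VariantSet`s per gene), `cohorts`
#'   (list case/control1/control2), `spec`, `seed`.
#' @export
generate_study <- function(spec = synthetic_cohort_spec(), seed = 1L) {
  .with_seed(seed, {
    genes <- list()
    regions <- list()
    population <- list()
    dee_flags <- seq_len(spec$n_genes) <= spec$n_dee_genes
    for (g in seq_len(spec$n_genes)) {
      L <- sample(spec$gene_length_range[1]:spec$gene_length_range[2], 1)
      id <- sprintf("geneS%02d", g)
      gene <- generate_gene(L, gc_bias = spec$gc_bias, gene_id = id,
                            is_dee_gene = dee_flags[g])
      reg_len <- max(1L, round(spec$depletion_coverage * L))
      start <- sample.int(L - reg_len + 1L, 1)
      reg <- data.frame(start = start, end = start + reg_len - 1L)
      genes[[id]] <- gene
      regions[[id]] <- reg
      population[[id]] <- generate_population_variants(
        gene, density = spec$population_density, regions = reg,
        multiplier = spec$depletion_multiplier
      )
    }
    cohorts <- generate_cohorts(genes, regions, spec)
    list(genes = genes, regions = regions, population = population,
         cohorts = cohorts, spec = spec, seed = seed)
  })
}
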
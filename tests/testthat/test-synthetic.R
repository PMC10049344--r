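test_that("gene generation is seed-deterministic, stop-free and translation-consistent", {
  g1 <- generate_gene(100, seed = 81)
  g2 <- generate_gene(100, seed = 81)
  expect_identical(g1$codons, g2$codons)
  expect_equal(g1$length, 100)
  expect_equal(nchar(g1$protein_seq), 100)
  many <- unlist(lapply(1:50, function(s) generate_gene(40, seed = s)$codons))
  expect_false(any(many %in% spatialMTR:::STOP_CODONS))
  for (i in c(1, 50, 100)) {
    expect_identical(substr(g1$protein_seq, i, i),
                     oracle_translate(g1$codons[i]))
  }
  expect_error(generate_gene(5), ">= 10")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_gene(50, seed = 9))
  invisible(generate_study(synthetic_cohort_spec(
    n_genes = 2, gene_length_range = c(50L, 60L), n_case = 10L,
    n_controls = c(10L, 10L)), seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("population variants track possibility ratios and respect depletion multipliers", {
  g <- generate_gene(800, seed = 82, gene_id = "gBig")
  pv <- generate_population_variants(g, density = 4.5, seed = 83)
  poss <- spatialMTR:::.possibility_counts(g$codons)
  poss_ratio <- sum(poss$n_missense) /
    (sum(poss$n_missense) + sum(poss$n_synonymous))
  obs_ratio <- sum(pv$consequence == "missense") /
    sum(pv$consequence %in% c("missense", "synonymous"))
  expect_lt(abs(obs_ratio - poss_ratio), 0.05 * poss_ratio)

  reg <- data.frame(start = 200, end = 400)
  pv0 <- generate_population_variants(g, density = 4.5, regions = reg,
                                      multiplier = 1e-9, seed = 84)
  in_reg <- pv0$codon_index >= 200 & pv0$codon_index <= 400
  expect_equal(sum(in_reg & pv0$consequence == "missense"), 0)
  expect_gt(sum(in_reg & pv0$consequence == "synonymous"), 0)

  expect_identical(
    as.data.frame(generate_population_variants(g, density = 2, seed = 85)),
    as.data.frame(generate_population_variants(g, density = 2, seed = 85)))
})

test_that("cohort sizes are honoured exactly and enrichment follows the closed form", {
  spec <- synthetic_cohort_spec(n_genes = 8, gene_length_range = c(300L, 400L),
                                depletion_coverage = 0.25,
                                case_enrichment = 3,
                                n_case = 276L, n_controls = c(454L, 762L))
  study <- generate_study(spec, seed = 86)
  expect_equal(nrow(study$cohorts$case), 276)
  expect_equal(nrow(study$cohorts$control1), 454)
  expect_equal(nrow(study$cohorts$control2), 762)
  expect_true(all(study$cohorts$case$consequence == "missense"))

  # expected in-region fraction: 3 * 25 / (3 * 25 + 75) = 50%
  frac_in_region <- function(vs, regions) {
    inside <- mapply(function(gid, pos) {
      rg <- regions[[gid]]
      any(pos >= rg$start & pos <= rg$end)
    }, vs$gene_id, vs$codon_index)
    mean(inside)
  }
  cases <- vapply(1:20, function(s) {
    st <- generate_study(spec, seed = s)
    frac_in_region(st$cohorts$case, st$regions)
  }, numeric(1))
  expect_lt(abs(mean(cases) - 0.50), 0.04)

  # null enrichment: case occupancy matches the control occupancy
  spec_null <- synthetic_cohort_spec(n_genes = 8,
                                     gene_length_range = c(300L, 400L),
                                     case_enrichment = 1,
                                     n_case = 276L, n_controls = c(454L, 762L))
  nulls <- vapply(1:20, function(s) {
    st <- generate_study(spec_null, seed = s + 100)
    frac_in_region(st$cohorts$case, st$regions) -
      frac_in_region(st$cohorts$control1, st$regions)
  }, numeric(1))
  expect_lt(abs(mean(nulls)), 0.04)

  expect_error(generate_cohorts(
    study$genes[1], study$regions[1],
    synthetic_cohort_spec(n_genes = 1, n_case = 10000L,
                          n_controls = c(5L, 5L))), "exceeds")
})

test_that("extended topology spaces residues exactly and folded contacts hit their distances", {
  g <- generate_gene(100, seed = 87, gene_id = "gGeo")
  ext <- generate_structure(g, "extended")$structure
  r <- ext$residues
  d <- function(st, i, j) {
    rr <- st$residues
    sqrt((rr$x[i] - rr$x[j])^2 + (rr$y[i] - rr$y[j])^2 +
           (rr$z[i] - rr$z[j])^2)
  }
  expect_equal(d(ext, 1, 2), 3.8)
  expect_equal(d(ext, 10, 30), 20 * 3.8, tolerance = 1e-9)

  fold <- generate_structure(g, "folded",
                             contact_pairs = list(c(12, 83, 5)))$structure
  expect_equal(d(fold, 12, 83), 5, tolerance = 1e-6)
  # consecutive spacing is preserved through the fold
  steps <- vapply(1:99, function(i) d(fold, i, i + 1), numeric(1))
  expect_equal(steps, rep(3.8, 99), tolerance = 1e-9)

  expect_error(generate_structure(g, "folded",
                                  contact_pairs = list(c(10, 12, 50))),
               "infeasible")
  expect_error(generate_structure(g, "folded",
                                  contact_pairs = list(c(10, 40, 5),
                                                       c(30, 60, 5))),
               "overlap")
  # emitted true mapping is the identity
  gen <- generate_structure(g, "extended")
  expect_equal(gen$mapping$pairs$codon_index,
               as.integer(gen$mapping$pairs$residue_id))
  expect_equal(gen$mapping$match_fraction, 1)
  # and the alignment-based mapper recovers it
  m <- map_sequence_to_structure(g, gen$structure)
  expect_equal(m$pairs, gen$mapping$pairs)
})

test_that("alignment generator honours substitution and gap extremes", {
  g <- generate_gene(50, seed = 88, gene_id = "gA")
  identical_aln <- generate_alignment(g, substitution_rate = 0,
                                      gap_rate = 0, seed = 89)
  expect_true(all(apply(identical_aln$matrix, 2,
                        function(col) length(unique(col)) == 1)))
  gappy <- generate_alignment(g, gap_rate = 1, seed = 90)
  expect_true(all(gappy$matrix == "-"))
  ct <- windowed_conservation(gappy$matrix[, 1:10, drop = FALSE], window = 2)
  expect_true(all(ct$gap_flag))
  expect_identical(generate_alignment(g, seed = 91)$matrix,
                   generate_alignment(g, seed = 91)$matrix)
})

test_that("full studies are pure functions of spec and seed", {
  spec <- synthetic_cohort_spec(n_genes = 3, gene_length_range = c(80L, 120L),
                                n_case = 30L, n_controls = c(40L, 50L))
  s1 <- generate_study(spec, seed = 92)
  s2 <- generate_study(spec, seed = 92)
  expect_identical(lapply(s1$genes, `[[`, "codons"),
                   lapply(s2$genes, `[[`, "codons"))
  expect_identical(as.data.frame(s1$cohorts$case),
                   as.data.frame(s2$cohorts$case))
  expect_identical(s1$regions, s2$regions)
  s3 <- generate_study(spec, seed = 93)
  expect_false(identical(as.data.frame(s1$cohorts$case),
                         as.data.frame(s3$cohorts$case)))
})
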
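# A radius strictly between 10 and 11 backbone steps (3.8 A each) makes the
# spatial neighbourhood of an extended chain exactly the 21-codon sequence
# window; 39 A sits safely inside (38 A itself is a floating-point knife
# edge).
RADIUS_21_EQUIV <- 39

test_that("on an extended chain the spatial score equals the 21-codon sequence score exactly", {
  g <- generate_gene(150, seed = 31, gene_id = "gE")
  pv <- generate_population_variants(g, density = 4, seed = 32)
  st <- generate_structure(g, "extended")
  m3 <- compute_mtr3d(g, pv, st$mapping, st$structure,
                      radius = RADIUS_21_EQUIV)
  m21 <- compute_mtr(g, pv, window_spec(21))
  expect_identical(m3$score, m21$score)
})

test_that("a folded contact makes spatial depletion visible where the sequence window is blind", {
  g <- generate_gene(100, seed = 33, gene_id = "gF")
  # depletion planted only at 80..85; contact brings 12 close to 83
  reg <- data.frame(start = 80, end = 85)
  pv <- generate_population_variants(g, density = 6, regions = reg,
                                     multiplier = 0.05, seed = 34)
  st <- generate_structure(g, "folded",
                           contact_pairs = list(c(12, 83, 5)))
  m3 <- compute_mtr3d(g, pv, st$mapping, st$structure, radius = 8)
  m21 <- compute_mtr(g, pv, window_spec(21))
  expect_lt(m3$score[12], m21$score[12])
})

test_that("radius zero degenerates to per-codon ratios, missing without observations", {
  g <- generate_gene(60, seed = 35, gene_id = "gZ")
  pv <- generate_population_variants(g, density = 2, seed = 36)
  st <- generate_structure(g, "extended")
  m0 <- compute_mtr3d(g, pv, st$mapping, st$structure, radius = 0)
  obs <- spatialMTR:::.observed_per_codon(pv, g)
  for (i in seq_len(g$length)) {
    om <- obs$obs_mis[i]; os <- obs$obs_syn[i]
    if (om + os == 0) {
      expect_true(is.na(m0$score[i]))
    } else {
      ep <- expected_missense_proportion(g, i)
      expect_equal(m0$score[i], (om / (om + os)) / ep)
    }
  }
})

test_that("an empty mapping yields an all-missing track with a warning", {
  g <- generate_gene(40, seed = 37, gene_id = "gQ")
  pv <- generate_population_variants(g, density = 3, seed = 38)
  st <- generate_structure(g, "extended")
  empty_map <- st$mapping
  empty_map$pairs <- empty_map$pairs[0, ]
  expect_warning(tr <- compute_mtr3d(g, pv, empty_map, st$structure), "no mapped")
  expect_true(all(is.na(tr$score)))
})

# shared feature fixture: a study-sized feature table with a separable label
make_feature_fixture <- function(seed = 41, n_genes = 4) {
  spec <- synthetic_cohort_spec(n_genes = n_genes,
                                gene_length_range = c(150L, 250L),
                                n_case = 40L, n_controls = c(50L, 60L),
                                n_dee_genes = 2L)
  study <- generate_study(spec, seed = seed)
  rows <- do.call(rbind, lapply(study$genes, function(g) {
    pv <- study$population[[g$gene_id]]
    st <- generate_structure(g, "helix")
    mtrx_feature_table(
      g,
      compute_mtr(g, pv, window_spec(41)),
      compute_mtr(g, pv, window_spec(21)),
      compute_mtr3d(g, pv, st$mapping, st$structure, radius = 8),
      compute_rsa(st$structure),
      st$mapping)
  }))
  rownames(rows) <- NULL
  rows
}

test_that("the consensus combiner separates the noise-free labelling with high held-out accuracy", {
  rows <- mtrx_synthetic_labels(make_feature_fixture())
  expect_gt(sum(rows$label == "deleterious", na.rm = TRUE), 20)
  st <- mtrx_self_test(rows, seed = 20230307L)
  expect_gte(st$accuracy, 0.95)
  expect_gte(st$auc, 0.95)
})

test_that("shuffled labels give chance-level held-out AUC", {
  rows <- mtrx_synthetic_labels(make_feature_fixture())
  keep <- !is.na(rows$label)
  rows <- rows[keep, ]
  set.seed(99)
  rows$label <- sample(rows$label)
  st <- mtrx_self_test(rows, seed = 20230307L)
  expect_lt(abs(st$auc - 0.5), 0.1)
})

test_that("consensus scores are probabilities, bit-identical under a fixed seed, missing where features are", {
  rows <- mtrx_synthetic_labels(make_feature_fixture())
  m1 <- train_mtrx(rows, seed = 20230307L)
  m2 <- train_mtrx(rows, seed = 20230307L)
  s1 <- score_mtrx(m1, rows)
  s2 <- score_mtrx(m2, rows)
  expect_identical(s1, s2)
  ok <- !is.na(s1)
  expect_true(all(s1[ok] >= 0 & s1[ok] <= 1))
  incomplete <- !stats::complete.cases(rows[, spatialMTR:::MTRX_FEATURES])
  expect_true(all(is.na(s1[incomplete])))
  allmiss <- rows[1, ]
  allmiss[, spatialMTR:::MTRX_FEATURES] <- NA_real_
  expect_true(is.na(score_mtrx(m1, allmiss)))
  expect_error(score_mtrx(m1, rows[, c("mtr_v1", "rsa")]), "absent")
})

test_that("training demands two classes and the listed features", {
  rows <- mtrx_synthetic_labels(make_feature_fixture())
  one_class <- rows[rows$label == "benign" & !is.na(rows$label), ]
  expect_error(train_mtrx(one_class), "two classes")
  expect_error(train_mtrx(rows[, c("mtr_v1", "label")]), "lack column")
})

test_that("every feature earns positive importance on a monotone multivariate signal", {
  rows <- make_feature_fixture(seed = 47, n_genes = 6)
  complete <- stats::complete.cases(rows[, spatialMTR:::MTRX_FEATURES])
  rows <- rows[complete, ]
  set.seed(7)
  z <- function(x) as.numeric(scale(x))
  logit <- -1.5 * z(rows$mtr_v1) - 1.5 * z(rows$mtr_v2) -
    1.5 * z(rows$mtr3d) - 1.5 * z(rows$rsa) +
    stats::rnorm(nrow(rows), 0, 0.3)
  rows$label <- ifelse(stats::runif(nrow(rows)) < stats::plogis(logit),
                       "deleterious", "benign")
  m <- train_mtrx(rows, seed = 20230307L)
  imp <- randomForest::importance(m$forest, type = 1)
  expect_true(all(imp[spatialMTR:::MTRX_FEATURES, 1] > 0))
})

test_that("case variants score lower spatial tolerance and higher consensus than controls", {
  spec <- synthetic_cohort_spec(n_genes = 6, gene_length_range = c(200L, 300L),
                                n_case = 120L, n_controls = c(150L, 150L),
                                case_enrichment = 5)
  study <- generate_study(spec, seed = 53)
  mtr3d_tracks <- list(); mtrx_tracks <- list()
  rows_all <- list()
  for (id in names(study$genes)) {
    g <- study$genes[[id]]
    pv <- study$population[[id]]
    st <- generate_structure(g, "helix")
    m3 <- compute_mtr3d(g, pv, st$mapping, st$structure, radius = 8)
    rows_all[[id]] <- mtrx_feature_table(
      g, compute_mtr(g, pv, window_spec(41)),
      compute_mtr(g, pv, window_spec(21)), m3,
      compute_rsa(st$structure), st$mapping)
    mtr3d_tracks[[id]] <- m3
  }
  rows <- do.call(rbind, rows_all)
  model <- train_mtrx(mtrx_synthetic_labels(rows), seed = 20230307L)
  sc <- score_mtrx(model, rows)
  for (id in names(study$genes)) {
    L <- study$genes[[id]]$length
    vals <- rep(NA_real_, L)
    sel <- rows$gene_id == id
    vals[rows$codon_index[sel]] <- sc[sel]
    mtrx_tracks[[id]] <- spatialMTR:::.new_track(id, "MTRX", vals)
  }
  case_m3 <- score_variants(mtr3d_tracks, study$cohorts$case)
  ctrl_m3 <- score_variants(mtr3d_tracks, study$cohorts$control1)
  expect_lt(mean(case_m3, na.rm = TRUE), mean(ctrl_m3, na.rm = TRUE))
  case_mx <- score_variants(mtrx_tracks, study$cohorts$case)
  ctrl_mx <- score_variants(mtrx_tracks, study$cohorts$control1)
  expect_gt(mean(case_mx, na.rm = TRUE), mean(ctrl_mx, na.rm = TRUE))
})
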
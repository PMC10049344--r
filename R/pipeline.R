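# End-to-end analysis: score -> map -> classify -> compare, over a
# synthetic study (or user-supplied inputs plugged into the same
# functions), with per-stage counts and a machine-readable report.

#' Analysis configuration
#'
#' Thresholds default to the published exome-wide values (sequence
#' tolerance ratio < 0.78 = exome-wide top 25 percent most intolerant,
#' spatial ratio < 0.75 intolerant and < 0.5 strongly intolerant, consensus
#' score > 0.75 deleterious). On synthetic data the pooled 25th-percentile
#' cutoff computed from the data itself is reported alongside, since a
#' synthetic exome yields its own percentile.
#'
#' @param spec A `SyntheticCohortSpec` describing the study inputs.
#' @param thresholds Named list: `mtr`, `mtr3d`, `mtr3d_strong`, `mtrx`.
#' @param windows Sequence window sizes (odd), default `c(41, 21)`.
#' @param radius Spatial neighbourhood radius in Angstrom.
#' @param percentile Pooled percentile used for the data-derived cutoff.
#' @param structure_coverage Fraction of genes given a structure (emulating
#'   partial structure availability).
#' @param test Group-test kind (`"ranksum"` or `"signedrank"`).
#' @param seed Integer seed for the whole analysis.
#' @return An `AnalysisConfig` list.
#' @export
analysis_config <- function(spec = synthetic_cohort_spec(),
                            thresholds = list(mtr = 0.78, mtr3d = 0.75,
                                              mtr3d_strong = 0.5,
                                              mtrx = 0.75),
                            windows = c(41L, 21L), radius = 8,
                            percentile = 25, structure_coverage = 0.6,
                            test = "ranksum", seed = 1L) {
  stopifnot(all(unlist(thresholds) > 0), all(windows %% 2L == 1L),
            radius >= 0)
  structure(list(spec = spec, thresholds = thresholds,
                 windows = as.integer(windows), radius = radius,
                 percentile = percentile,
                 structure_coverage = structure_coverage, test = test,
                 seed = as.integer(seed)),
            class = "AnalysisConfig")
}

# cheap stable fingerprint of the configuration for report stamping
.config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 251)) %%
            .Machine$integer.max)
}

#' Run the full analysis and assemble a report
#'
#' Generates the synthetic study, computes all intolerance tracks (sequence
#' windows, spatial score on generated structures, consensus score,
#' conservation), classifies each cohort at every configured threshold and
#' at the data-derived pooled percentile cutoff, runs the rank-based group
#' tests for every score, computes pairwise predictor correlations (all
#' genes and the disease-panel subset) and the conservation-versus-MTR
#' correlation, and returns everything as a nested report list with
#' per-stage counts.
#'
#' @param config An `AnalysisConfig`.
#' @return An `AnalysisReport` list; see `write_report_json()` to serialise.
#' @export
run_analysis <- function(config = analysis_config()) {
  study <- generate_study(config$spec, seed = config$seed)
  genes <- study$genes
  gene_ids <- names(genes)
  log <- list()

  # --- sequence-window tolerance tracks ------------------------------------
  mtr_tracks <- list()
  for (w in config$windows) {
    mtr_tracks[[paste0("MTR_", w)]] <- lapply(genes, function(g) {
      compute_mtr(g, study$population[[g$gene_id]], window_spec(w))
    })
  }
  v1_name <- paste0("MTR_", config$windows[1])
  v2_name <- paste0("MTR_", config$windows[2])

  # --- structures, spatial score, solvent accessibility --------------------
  n_struct <- max(1L, round(config$structure_coverage * length(genes)))
  struct_ids <- gene_ids[seq_len(n_struct)]
  .with_seed(config$seed + 1L, {
    structures <- lapply(genes[struct_ids], function(g) {
      generate_structure(g, topology = "helix")
    })
  })
  mtr3d_tracks <- lapply(gene_ids, function(id) {
    if (!id %in% struct_ids) {
      return(.new_track(id, "MTR3D", rep(NA_real_, genes[[id]]$length)))
    }
    st <- structures[[id]]
    compute_mtr3d(genes[[id]], study$population[[id]], st$mapping,
                  st$structure, radius = config$radius)
  })
  names(mtr3d_tracks) <- gene_ids
  rsa_tables <- lapply(structures, function(st) compute_rsa(st$structure))

  # --- conservation --------------------------------------------------------
  .with_seed(config$seed + 2L, {
    cons_tracks <- lapply(genes, function(g) {
      aln <- generate_alignment(
        g, conserved_blocks = list(c(study$regions[[g$gene_id]]$start,
                                     study$regions[[g$gene_id]]$end)))
      conservation_track(g, aln)
    })
  })

  # --- consensus combiner --------------------------------------------------
  feature_rows <- do.call(rbind, lapply(struct_ids, function(id) {
    mtrx_feature_table(genes[[id]], mtr_tracks[[v1_name]][[id]],
                       mtr_tracks[[v2_name]][[id]], mtr3d_tracks[[id]],
                       rsa_tables[[id]], structures[[id]]$mapping)
  }))
  labelled <- mtrx_synthetic_labels(feature_rows)
  self_test <- mtrx_self_test(labelled, seed = config$seed + 3L)
  mtrx_scores_all <- score_mtrx(self_test$model, feature_rows)
  mtrx_tracks <- lapply(gene_ids, function(id) {
    L <- genes[[id]]$length
    vals <- rep(NA_real_, L)
    sel <- feature_rows$gene_id == id
    if (any(sel)) vals[feature_rows$codon_index[sel]] <- mtrx_scores_all[sel]
    .new_track(id, "MTRX", vals)
  })
  names(mtrx_tracks) <- gene_ids

  # --- pooled data-derived cutoffs -----------------------------------------
  pooled_cutoffs <- list()
  for (nm in names(mtr_tracks)) {
    pooled_cutoffs[[nm]] <- percentile_threshold(mtr_tracks[[nm]],
                                                 config$percentile)
  }
  pooled_cutoffs$MTR3D <- percentile_threshold(mtr3d_tracks,
                                               config$percentile)

  # --- score the cohorts ---------------------------------------------------
  all_tracks <- c(mtr_tracks,
                  list(MTR3D = mtr3d_tracks, MTRX = mtrx_tracks,
                       conservation = cons_tracks))
  cohort_scores <- lapply(study$cohorts, function(vs) {
    out <- lapply(all_tracks, function(trks) score_variants(trks, vs))
    as.data.frame(out, check.names = FALSE)
  })
  log$n_variants <- vapply(study$cohorts, nrow, integer(1))
  log$n_scored <- lapply(cohort_scores, function(df) {
    vapply(df, function(x) sum(!is.na(x)), integer(1))
  })

  # --- enrichment at every configured threshold ----------------------------
  frac_block <- function(score_col, threshold, direction) {
    lapply(names(cohort_scores), function(grp) {
      fraction_intolerant(cohort_scores[[grp]][[score_col]], threshold,
                          direction = direction, group = grp)
    }) |> stats::setNames(names(cohort_scores))
  }
  enrichment <- list(
    mtr = frac_block(v2_name, config$thresholds$mtr, "below"),
    mtr_pooled = frac_block(v2_name, pooled_cutoffs[[v2_name]], "below"),
    mtr3d = frac_block("MTR3D", config$thresholds$mtr3d, "below"),
    mtr3d_strong = frac_block("MTR3D", config$thresholds$mtr3d_strong,
                              "below"),
    mtrx = frac_block("MTRX", config$thresholds$mtrx, "above")
  )

  # --- rank-based group comparisons for every score ------------------------
  invert <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  names(invert) <- c(v1_name, v2_name, "MTR3D", "MTRX", "conservation")
  comparisons <- list()
  for (sc in names(invert)) {
    pooled_vals <- unlist(lapply(cohort_scores, function(df) df[[sc]]),
                          use.names = FALSE)
    if (all(is.na(pooled_vals))) next
    rk <- rank_scores(pooled_vals, invert = invert[[sc]])
    grp <- rep(names(cohort_scores),
               vapply(cohort_scores, nrow, integer(1)))
    for (ctrl in c("control1", "control2")) {
      case_r <- rk[grp == "case"]
      ctrl_r <- rk[grp == ctrl]
      if (sum(!is.na(case_r)) == 0 || sum(!is.na(ctrl_r)) == 0) next
      comparisons[[paste(sc, "case_vs", ctrl, sep = "_")]] <-
        compare_groups(case_r, ctrl_r, test = config$test, score_name = sc)
    }
  }

  # --- pairwise predictor correlations (all genes / panel subset) ----------
  case_table <- cohort_scores$case
  dee_genes <- gene_ids[vapply(genes, function(g) g$is_dee_gene, logical(1))]
  case_in_dee <- study$cohorts$case$gene_id %in% dee_genes
  correlations <- list(
    all_genes = tryCatch(pairwise_correlations(case_table),
                         error = function(e) NULL),
    dee_genes = tryCatch(
      pairwise_correlations(case_table[case_in_dee, , drop = FALSE]),
      error = function(e) NULL)
  )

  # --- conservation vs tolerance ratio, per position -----------------------
  cons_vs_mtr <- function(ids) {
    a <- unlist(lapply(ids, function(id) cons_tracks[[id]]$score))
    b <- unlist(lapply(ids, function(id) mtr_tracks[[v2_name]][[id]]$score))
    tryCatch(correlate_tracks(a, b, method = "pearson"),
             error = function(e) list(r = NA_real_, p = NA_real_, n = 0))
  }
  conservation_mtr <- list(all_genes = cons_vs_mtr(gene_ids),
                           dee_genes = cons_vs_mtr(dee_genes))

  report <- list(
    config_hash = .config_hash(config),
    seed = config$seed,
    thresholds = config$thresholds,
    pooled_cutoffs = pooled_cutoffs,
    counts = log,
    enrichment = enrichment,
    comparisons = comparisons,
    correlations = correlations,
    conservation_mtr = conservation_mtr,
    mtrx_self_test = self_test[c("accuracy", "auc", "n_train", "n_test")],
    mtrx_provenance = sprintf(
      "trained on synthetic labels (deleterious iff %s < 0.5), seed %d, %d rows",
      v2_name, config$seed + 3L, self_test$n_train),
    lollipop = lollipop_export(study$cohorts)
  )
  structure(list(report = report, study = study, tracks = all_tracks,
                 config = config),
            class = "AnalysisReport")
}

#' Serialise a report as JSON
#'
#' Deterministic given the analysis seed: rerunning the same configuration
#' yields a byte-identical file.
#'
#' @param analysis An `AnalysisReport` from `run_analysis()` (or its
#'   `$report` element).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(analysis, path) {
  rep <- if (inherits(analysis, "AnalysisReport")) analysis$report else analysis
  strip <- function(x) {
    if (inherits(x, c("EnrichmentResult", "GroupComparison"))) {
      return(unclass(x))
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  json <- jsonlite::toJSON(strip(rep), auto_unbox = TRUE, digits = 10,
                           na = "null", dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}

#' Human-readable enrichment summary table
#'
#' @param analysis An `AnalysisReport`.
#' @return A data frame: one row per (threshold block, cohort).
#' @export
report_enrichment_table <- function(analysis) {
  rep <- analysis$report
  rows <- list()
  for (blk in names(rep$enrichment)) {
    for (grp in names(rep$enrichment[[blk]])) {
      e <- rep$enrichment[[blk]][[grp]]
      rows[[length(rows) + 1L]] <- data.frame(
        block = blk, group = grp, n_scored = e$n_scored,
        n_intolerant = e$n_intolerant, fraction = e$fraction,
        threshold = e$threshold, direction = e$direction,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
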
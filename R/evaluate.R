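# Study-level evaluation helpers: recovery of planted intolerant regions,
# cohort fraction-intolerant comparison and the rank-based case/control
# test. These are the building blocks of the multi-seed calibration
# experiments as well as of the full report.

#' Recover planted depletion regions from MTR classification
#'
#' Computes the sliding-window tolerance ratio for every gene of a synthetic
#' study, classifies codons as intolerant below the pooled q-th percentile,
#' and scores the classification against the planted regions.
#'
#' @param study A study from `generate_study()`.
#' @param window Window size in codons (default 21).
#' @param q Pooled percentile used as the intolerance cutoff (default 25).
#' @return A list with `precision`, `recall`, `cutoff` and the per-gene
#'   `tracks`.
#' @export
region_recovery <- function(study, window = 21L, q = 25) {
  spec <- window_spec(window)
  tracks <- lapply(study$genes, function(g) {
    compute_mtr(g, study$population[[g$gene_id]], spec)
  })
  cutoff <- percentile_threshold(tracks, q)
  tp <- fp <- fn <- 0L
  for (id in names(study$genes)) {
    L <- study$genes[[id]]$length
    truth <- rep(FALSE, L)
    rg <- study$regions[[id]]
    for (k in seq_len(nrow(rg))) truth[rg$start[k]:rg$end[k]] <- TRUE
    sc <- tracks[[id]]$score
    pred <- !is.na(sc) & sc < cutoff
    tp <- tp + sum(pred & truth)
    fp <- fp + sum(pred & !truth)
    fn <- fn + sum(!pred & truth)
  }
  list(precision = tp / (tp + fp), recall = tp / (tp + fn),
       cutoff = cutoff, tracks = tracks)
}

#' Cohort fraction-intolerant comparison and rank test
#'
#' Scores each cohort's variants with the study's tolerance tracks,
#' classifies them against `cutoff` (default: the pooled q-th percentile)
#' and runs the two-sample rank test of case against each control on
#' percentile rank scores (tolerance ratios inverted so higher rank = more
#' damaging).
#'
#' @param study A study from `generate_study()`.
#' @param tracks Optional precomputed named track list (as from
#'   `region_recovery()$tracks`); computed if missing.
#' @param window Window size used when computing tracks here.
#' @param q Pooled percentile for the cutoff.
#' @param cutoff Explicit cutoff overriding `q`.
#' @return A list with `fractions` (named list of `EnrichmentResult` for
#'   case/control1/control2), `tests` (named list of `GroupComparison` of
#'   case vs each control) and `cutoff`.
#' @export
cohort_enrichment <- function(study, tracks = NULL, window = 21L, q = 25,
                              cutoff = NULL) {
  if (is.null(tracks)) {
    spec <- window_spec(window)
    tracks <- lapply(study$genes, function(g) {
      compute_mtr(g, study$population[[g$gene_id]], spec)
    })
  }
  if (is.null(cutoff)) cutoff <- percentile_threshold(tracks, q)
  scores <- lapply(study$cohorts, function(vs) score_variants(tracks, vs))
  fractions <- lapply(names(scores), function(nm) {
    fraction_intolerant(scores[[nm]], cutoff, direction = "below", group = nm)
  })
  names(fractions) <- names(scores)
  pooled <- unlist(scores, use.names = FALSE)
  ranks <- rank_scores(pooled, invert = TRUE)
  grp <- rep(names(scores), vapply(scores, length, integer(1)))
  tests <- lapply(c("control1", "control2"), function(ctrl) {
    compare_groups(ranks[grp == "case"], ranks[grp == ctrl],
                   score_name = "MTR_rank")
  })
  names(tests) <- c("control1", "control2")
  list(fractions = fractions, tests = tests, cutoff = cutoff)
}
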
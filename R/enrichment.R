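# Case/control enrichment statistics: percentile rank scores, threshold
# classification with rounded-percent reporting, rank-based group tests and
# pairwise predictor correlation matrices.

#' Convert raw predictor values to percentile rank scores
#'
#' Each non-missing value is mapped to its percentile rank in `[0, 1]` over
#' all scored positions (average ranks for ties, then min -> 0, max -> 1).
#' Rank scores are oriented so that higher = more likely damaging; set
#' `invert = TRUE` for predictors where low raw values are damaging (MTR,
#' SIFT, FATHMM and kin).
#'
#' @param values Numeric vector (missing allowed).
#' @param invert Negate values before ranking.
#' @return Numeric vector of rank scores; `NA` preserved. A column of
#'   entirely tied values maps to 0.5.
#' @export
rank_scores <- function(values, invert = FALSE) {
  ok <- !is.na(values)
  if (!any(ok)) stop("no non-missing values to rank", call. = FALSE)
  v <- values[ok]
  if (invert) v <- -v
  out <- rep(NA_real_, length(values))
  if (length(v) == 1 || max(v) == min(v)) {
    out[ok] <- 0.5
    return(out)
  }
  r <- rank(v, ties.method = "average")
  out[ok] <- (r - 1) / (length(v) - 1)
  out
}

# round half away from zero, as in printed results percentages
.round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Fraction of scores beyond an intolerance threshold
#'
#' Counts non-missing scores strictly beyond `threshold` in the damaging
#' direction, reporting the count and the percentage rounded
#' half-away-from-zero to an integer, as results tables print it.
#'
#' @param scores Numeric vector of scores for one group.
#' @param threshold Classification cutoff.
#' @param direction `"below"` (intolerance scores such as MTR; default) or
#'   `"above"` (scores oriented towards 1 = damaging, such as MTRX).
#' @param group Group label carried into the result.
#' @return An `EnrichmentResult`: list with `group`, `n_scored`,
#'   `n_intolerant`, `fraction` (integer percent, `NA` and flagged when no
#'   scores), `threshold`, `direction`.
#' @export
fraction_intolerant <- function(scores, threshold,
                                direction = c("below", "above"),
                                group = "group") {
  direction <- match.arg(direction)
  s <- scores[!is.na(scores)]
  n_scored <- length(s)
  n_intol <- if (direction == "below") sum(s < threshold) else sum(s > threshold)
  fraction <- if (n_scored > 0) {
    as.integer(.round_half_up(100 * n_intol / n_scored))
  } else {
    NA_integer_
  }
  structure(list(group = group, n_scored = n_scored, n_intolerant = n_intol,
                 fraction = fraction, threshold = threshold,
                 direction = direction, flagged = n_scored == 0),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("<EnrichmentResult %s: %d of %d (%s%%) %s %.3g>\n", x$group,
              x$n_intolerant, x$n_scored,
              ifelse(is.na(x$fraction), "-", x$fraction),
              ifelse(x$direction == "below", "<", ">"), x$threshold))
  invisible(x)
}

#' Rank-based comparison of case and control score distributions
#'
#' Default is the two-sample Wilcoxon rank-sum (Mann-Whitney) test: the
#' compared cohorts are independent samples of unequal size, for which the
#' signed-rank test is undefined; a paired signed-rank option is available
#' for genuinely paired designs.
#'
#' @param case,control Numeric score vectors (missing values removed).
#' @param test `"ranksum"` (default) or `"signedrank"` (requires equal-length
#'   paired vectors).
#' @param alternative Passed to [stats::wilcox.test()]; default two-sided.
#' @param score_name Label carried into the result.
#' @return A `GroupComparison`: list with `score_name`, `n_case`,
#'   `n_control`, `statistic`, `p`, `test`, `alternative`.
#' @export
compare_groups <- function(case, control, test = c("ranksum", "signedrank"),
                           alternative = "two.sided", score_name = "score") {
  test <- match.arg(test)
  case <- case[!is.na(case)]
  control <- control[!is.na(control)]
  if (length(case) == 0 || length(control) == 0) {
    stop("a group is empty after missing-value removal", call. = FALSE)
  }
  wt <- if (test == "ranksum") {
    suppressWarnings(stats::wilcox.test(case, control,
                                        alternative = alternative))
  } else {
    if (length(case) != length(control)) {
      stop("signed-rank test requires paired, equal-length groups",
           call. = FALSE)
    }
    suppressWarnings(stats::wilcox.test(case, control, paired = TRUE,
                                        alternative = alternative))
  }
  structure(list(score_name = score_name, n_case = length(case),
                 n_control = length(control),
                 statistic = unname(wt$statistic), p = wt$p.value,
                 test = test, alternative = alternative),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("<GroupComparison %s (%s): n=%d vs %d, W=%.1f, p=%.3g>\n",
              x$score_name, x$test, x$n_case, x$n_control, x$statistic, x$p))
  invisible(x)
}

#' Pairwise correlation matrix of predictor columns
#'
#' Pairwise-complete correlations between predictor columns of a score
#' table, with per-cell sample sizes. Columns with fewer than 3 complete
#' pairs against every other column are excluded with a warning.
#'
#' @param table Data frame whose numeric columns are predictor scores (any
#'   non-numeric columns such as keys are ignored).
#' @param method Correlation method (default `"spearman"`).
#' @return A list with `r` (symmetric matrix, unit diagonal) and `n` (matrix
#'   of pairwise-complete counts).
#' @export
pairwise_correlations <- function(table, method = "spearman") {
  num <- table[, vapply(table, is.numeric, logical(1)), drop = FALSE]
  if (ncol(num) < 2) stop("need at least 2 predictor columns", call. = FALSE)
  m <- as.matrix(num)
  n_mat <- crossprod(!is.na(m))
  usable <- vapply(seq_len(ncol(m)), function(j) {
    any(n_mat[j, -j] >= 3)
  }, logical(1))
  if (any(!usable)) {
    warning("excluding column(s) with <3 complete pairs: ",
            paste(colnames(m)[!usable], collapse = ", "))
    m <- m[, usable, drop = FALSE]
    n_mat <- n_mat[usable, usable, drop = FALSE]
  }
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                   method = method))
  diag(r) <- 1
  list(r = r, n = n_mat)
}

#' Lollipop-plot data export
#'
#' Per-gene, per-position variant counts by cohort, serialisable to JSON for
#' external plotting of variant location diagrams.
#'
#' @param sets List of `VariantSet`s.
#' @return A data frame with `gene`, `position`, `cohort`, `count`.
#' @export
lollipop_export <- function(sets) {
  rows <- lapply(sets, function(s) {
    df <- as.data.frame(s)
    if (nrow(df) == 0) return(NULL)
    agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                            by = list(gene = df$gene_id,
                                      position = df$codon_index,
                                      cohort = rep(attr(s, "label"),
                                                   nrow(df))),
                            FUN = sum)
    agg
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), position = integer(),
                      cohort = character(), count = integer())
  }
  out[order(out$gene, out$position, out$cohort), , drop = FALSE]
}
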
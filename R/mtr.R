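# Sliding-window Missense Tolerance Ratio (MTR). At each focal codon i the
# score is the observed missense proportion among observed missense +
# synonymous variants in a window of codons centred on i, divided by the
# proportion expected from the possible single-nucleotide substitutions of
# the window's codons. Values near 1 indicate tolerance; values below 1
# indicate depletion of missense variation (intolerance).

#' Window specification for sequence-window scores
#'
#' @param size Odd window size in codons. The published score variants use 41
#'   (v1) and 21 (v2).
#' @param truncation How windows behave at gene ends; `"clip"` (the default
#'   and only rule) clips the window to `[1, L]`, giving asymmetric windows
#'   near the termini rather than dropping terminal codons.
#' @return A `WindowSpec` list.
#' @export
window_spec <- function(size = 31L, truncation = "clip") {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) {
    stop("window size must be an odd positive integer", call. = FALSE)
  }
  truncation <- match.arg(truncation, "clip")
  structure(list(size = size, truncation = truncation), class = "WindowSpec")
}

.new_track <- function(gene_id, score_name, values, obs_mis = NA_real_,
                       obs_syn = NA_real_, exp_prop = NA_real_) {
  df <- data.frame(gene_id = gene_id, position = seq_along(values),
                   score = as.numeric(values), obs_mis = obs_mis,
                   obs_syn = obs_syn, exp_prop = exp_prop,
                   stringsAsFactors = FALSE)
  structure(df, score_name = score_name,
            class = c("IntoleranceTrack", "data.frame"))
}

#' @export
print.IntoleranceTrack <- function(x, ...) {
  cat(sprintf("<IntoleranceTrack %s / %s: %d positions, %d scored>\n",
              x$gene_id[1], attr(x, "score_name"), nrow(x),
              sum(!is.na(x$score))))
  invisible(x)
}

#' Expected missense proportion of a codon window
#'
#' The proportion of possible single-nucleotide substitutions in the window
#' that are missense, among missense + synonymous possibilities. Nonsense
#' possibilities are excluded from the denominator.
#'
#' @param gene A `GeneModel`.
#' @param window Integer vector of codon indices (need not be contiguous; the
#'   spatial score passes neighbourhood codon sets through here).
#' @return A proportion in (0, 1].
#' @export
expected_missense_proportion <- function(gene, window) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  if (any(window < 1L | window > gene$length)) {
    stop("window outside gene bounds", call. = FALSE)
  }
  cnt <- .possibility_counts(gene$codons[window])
  mis <- sum(cnt$n_missense)
  syn <- sum(cnt$n_synonymous)
  stopifnot(mis + syn > 0)
  mis / (mis + syn)
}

# Per-codon observed counts of distinct missense / synonymous variant keys.
.observed_per_codon <- function(variants, gene) {
  df <- as.data.frame(variants)
  df <- df[df$gene_id == gene$gene_id &
             df$consequence %in% c("missense", "synonymous"), , drop = FALSE]
  df <- df[!duplicated(.variant_key(df)), , drop = FALSE]
  om <- tabulate(df$codon_index[df$consequence == "missense"], gene$length)
  os <- tabulate(df$codon_index[df$consequence == "synonymous"], gene$length)
  list(obs_mis = om, obs_syn = os)
}

#' Observed variant counts in a codon window
#'
#' Counts distinct missense and synonymous variants of a gene whose codon
#' index falls in the window. Uniqueness is by variant key, so duplicated
#' records never inflate the counts.
#'
#' @param variants A `VariantSet` (restricted to `gene` internally).
#' @param gene A `GeneModel`.
#' @param window Integer vector of codon indices.
#' @return A list with `obs_missense` and `obs_synonymous` counts.
#' @export
observed_window_counts <- function(variants, gene, window) {
  obs <- .observed_per_codon(variants, gene)
  list(obs_missense = sum(obs$obs_mis[window]),
       obs_synonymous = sum(obs$obs_syn[window]))
}

# Clipped-window running sum: sum of v over [i-h, i+h] intersected [1, L].
.window_sum <- function(v, h) {
  cs <- cumsum(v)
  L <- length(v)
  hi <- pmin(seq_len(L) + h, L)
  lo <- pmax(seq_len(L) - h, 1L)
  cs[hi] - c(0, cs)[lo]
}

#' Compute the sliding-window Missense Tolerance Ratio
#'
#' @param gene A `GeneModel`.
#' @param population_variants A `VariantSet` of standing variation (missense
#'   and synonymous records are used; others are ignored).
#' @param spec A `WindowSpec`; `window_spec(41)` and `window_spec(21)` give
#'   the v1 and v2 score variants.
#' @param score_name Track name; defaults to `MTR_<size>`.
#' @return An `IntoleranceTrack` with one value per codon. Positions whose
#'   window contains no observed missense or synonymous variant are missing
#'   (`NA`): the ratio is undefined there, not 0 or 1.
#' @export
compute_mtr <- function(gene, population_variants, spec = window_spec(31L),
                        score_name = NULL) {
  L <- gene$length
  if (spec$size > 2L * L - 1L) {
    stop("window size ", spec$size, " too large for gene of length ", L,
         call. = FALSE)
  }
  h <- (spec$size - 1L) %/% 2L
  poss <- .possibility_counts(gene$codons)
  obs <- .observed_per_codon(population_variants, gene)

  om <- .window_sum(obs$obs_mis, h)
  os <- .window_sum(obs$obs_syn, h)
  em <- .window_sum(poss$n_missense, h)
  es <- .window_sum(poss$n_synonymous, h)

  exp_prop <- em / (em + es)
  score <- ifelse(om + os > 0, (om / (om + os)) / exp_prop, NA_real_)
  if (is.null(score_name)) score_name <- paste0("MTR_", spec$size)
  .new_track(gene$gene_id, score_name, score, obs_mis = om, obs_syn = os,
             exp_prop = exp_prop)
}

#' Pooled percentile cutoff for intolerance classification
#'
#' Pools the non-missing values of one or more tracks and returns the q-th
#' percentile under the lower-interpolation convention (the order statistic
#' at index `floor((n-1) * q/100) + 1`). Classification as intolerant uses a
#' strict `score < cutoff` rule, matching a "top q% most intolerant" reading.
#'
#' @param tracks An `IntoleranceTrack`, or a list of them, or a numeric
#'   vector of scores.
#' @param q Percentile in `[0, 100]`.
#' @return The score cutoff (a single numeric).
#' @export
percentile_threshold <- function(tracks, q = 25) {
  vals <- pool_track_values(tracks)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no non-missing score values", call. = FALSE)
  if (q < 0 || q > 100) stop("q must be in [0, 100]", call. = FALSE)
  vals <- sort(vals)
  idx <- floor((length(vals) - 1) * q / 100) + 1
  vals[idx]
}

#' Pool score values from tracks
#'
#' @param tracks An `IntoleranceTrack`, a list of tracks, or a numeric vector.
#' @return Numeric vector of scores (missing values retained).
#' @export
pool_track_values <- function(tracks) {
  if (is.numeric(tracks)) return(as.numeric(tracks))
  if (inherits(tracks, "IntoleranceTrack")) return(tracks$score)
  if (is.list(tracks)) {
    return(unlist(lapply(tracks, pool_track_values), use.names = FALSE))
  }
  stop("cannot pool scores from object of class ", class(tracks)[1],
       call. = FALSE)
}

#' Look up track scores at variant positions
#'
#' @param tracks Named list of `IntoleranceTrack`s (names are gene ids), or a
#'   single track.
#' @param variants A `VariantSet`.
#' @return Numeric vector, one score per variant (`NA` where the position is
#'   unscored or the gene has no track).
#' @export
score_variants <- function(tracks, variants) {
  if (inherits(tracks, "IntoleranceTrack")) {
    tracks <- stats::setNames(list(tracks), tracks$gene_id[1])
  }
  vapply(seq_len(nrow(variants)), function(i) {
    tr <- tracks[[variants$gene_id[i]]]
    if (is.null(tr)) return(NA_real_)
    pos <- variants$codon_index[i]
    if (pos < 1 || pos > nrow(tr)) return(NA_real_)
    tr$score[pos]
  }, numeric(1))
}

#' Write an intolerance track as TSV
#'
#' Columns: gene, position, score, obs_mis, obs_syn, exp_prop.
#'
#' @param track An `IntoleranceTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# score: ", attr(track, "score_name")), con)
  utils::write.table(as.data.frame(track), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export intolerant intervals in BED-like form
#'
#' Merges runs of consecutive codons classified intolerant (strictly below
#' `cutoff`) into 0-based half-open intervals, one row per run.
#'
#' @param track An `IntoleranceTrack`.
#' @param cutoff Intolerance cutoff (strict `<`).
#' @return A data frame with `gene`, `start` (0-based), `end` (exclusive),
#'   `name`.
#' @export
track_to_bed <- function(track, cutoff) {
  flag <- !is.na(track$score) & track$score < cutoff
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(gene = track$gene_id[1],
             start = starts[keep] - 1L, end = ends[keep],
             name = paste0(attr(track, "score_name"), "_lt_", cutoff),
             stringsAsFactors = FALSE)
}
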
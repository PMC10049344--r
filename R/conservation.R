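# Jensen-Shannon-divergence conservation from a multiple sequence
# alignment: per-column divergence of the (pseudocounted) residue
# distribution from a background distribution, with window smoothing and a
# gap threshold. Log base 2 bounds the divergence by 1, so scores live in
# the unit interval with higher values more conserved.

# Background amino-acid frequencies: the marginal distribution underlying
# the BLOSUM62 matrix, the conventional default for divergence-based
# conservation; normalised to sum exactly 1.
BLOSUM62_BACKGROUND <- local({
  f <- c(A = 0.078, R = 0.051, N = 0.041, D = 0.052, C = 0.024, Q = 0.034,
         E = 0.059, G = 0.083, H = 0.025, I = 0.062, L = 0.092, K = 0.056,
         M = 0.024, F = 0.044, P = 0.043, S = 0.059, T = 0.055, W = 0.014,
         Y = 0.034, V = 0.072)
  f / sum(f)
})

.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence conservation of one alignment column
#'
#' `JSD(p, q) = H((p+q)/2) - (H(p) + H(q))/2` with `p` the column's
#' pseudocounted amino-acid distribution and `q` a background distribution,
#' entropies in bits. With log base 2 the value is bounded by 1, giving a
#' `[0, 1]` conservation score (higher = more diverged from background = more
#' conserved under a conserved column's concentrated distribution).
#'
#' @param letters Character vector of single-letter amino acids and `"-"`
#'   gaps (one per aligned sequence).
#' @param background Named background distribution over the 20 amino acids
#'   (default BLOSUM62 marginals); `"uniform"` is also accepted.
#' @param pseudocount Pseudocount added per amino acid (default 1/50).
#' @return The divergence score, or `NA` for an all-gap column.
#' @export
column_jsd <- function(letters, background = BLOSUM62_BACKGROUND,
                       pseudocount = 1 / 50) {
  if (identical(background, "uniform")) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  letters <- letters[letters != "-" & !is.na(letters)]
  if (length(letters) == 0) return(NA_real_)
  bad <- !letters %in% AA_ALPHABET
  if (any(bad)) {
    stop("unknown letter(s) in column: ",
         paste(unique(letters[bad]), collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(letters, levels = AA_ALPHABET))
  p <- (as.numeric(counts) + pseudocount) /
    (sum(counts) + 20 * pseudocount)
  q <- as.numeric(background[AA_ALPHABET])
  m <- (p + q) / 2
  .entropy2(m) - (.entropy2(p) + .entropy2(q)) / 2
}

#' Windowed conservation track from a multiple sequence alignment
#'
#' Per-column divergence scores smoothed with flanking columns:
#' `score_i = (1 - lambda) * jsd_i + lambda * mean(jsd over the window's
#' flanking columns, excluding i)`. Columns whose gap fraction exceeds
#' `gap_threshold` are missing and flagged -- conservation cannot be
#' measured confidently through gaps.
#'
#' @param alignment A character matrix (sequences x columns) of single
#'   letters and `"-"`, or the list returned by `read_alignment_fasta()`.
#' @param window Number of flanking columns on each side used for smoothing
#'   (default 3).
#' @param lambda Smoothing weight in `[0, 1]` (default 0.5); 0 disables
#'   smoothing.
#' @param gap_threshold Maximum tolerated gap fraction per column
#'   (default 0.3).
#' @param background Background distribution passed to `column_jsd()`.
#' @return A `ConservationTrack` data frame with `position`, `score`,
#'   `raw_jsd`, `gap_fraction`, `gap_flag`.
#' @export
windowed_conservation <- function(alignment, window = 3, lambda = 0.5,
                                  gap_threshold = 0.3,
                                  background = BLOSUM62_BACKGROUND) {
  if (is.list(alignment) && !is.matrix(alignment)) {
    alignment <- alignment$matrix
  }
  stopifnot(is.matrix(alignment))
  L <- ncol(alignment)
  if (window >= L) stop("window must be smaller than alignment length",
                        call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  gap_fraction <- colMeans(alignment == "-")
  jsd <- vapply(seq_len(L), function(i) {
    column_jsd(alignment[, i], background = background)
  }, numeric(1))
  gap_flag <- gap_fraction > gap_threshold | is.na(jsd)
  jsd[gap_flag] <- NA_real_
  score <- vapply(seq_len(L), function(i) {
    if (is.na(jsd[i])) return(NA_real_)
    if (lambda == 0) return(jsd[i])
    flank <- setdiff(max(1, i - window):min(L, i + window), i)
    flank_vals <- jsd[flank]
    flank_vals <- flank_vals[!is.na(flank_vals)]
    if (length(flank_vals) == 0) return(jsd[i])
    (1 - lambda) * jsd[i] + lambda * mean(flank_vals)
  }, numeric(1))
  out <- data.frame(position = seq_len(L), score = score, raw_jsd = jsd,
                    gap_fraction = gap_fraction, gap_flag = gap_flag)
  structure(out, score_name = "conservation",
            class = c("ConservationTrack", "data.frame"))
}

#' Conservation track as an IntoleranceTrack for a gene
#'
#' Convenience wrapper: computes `windowed_conservation()` and re-houses the
#' scores in the shared per-codon track container (alignment columns are
#' taken to correspond 1:1 to gene codon positions, with the gene as the
#' alignment's ungapped reference row).
#'
#' @param gene A `GeneModel`.
#' @param alignment Alignment matrix whose column count equals the gene
#'   length.
#' @param ... Passed to `windowed_conservation()`.
#' @return An `IntoleranceTrack` named `conservation`.
#' @export
conservation_track <- function(gene, alignment, ...) {
  if (is.list(alignment) && !is.matrix(alignment)) {
    alignment <- alignment$matrix
  }
  if (ncol(alignment) != gene$length) {
    stop("alignment has ", ncol(alignment), " columns but gene ",
         gene$gene_id, " has ", gene$length, " codons", call. = FALSE)
  }
  ct <- windowed_conservation(alignment, ...)
  .new_track(gene$gene_id, "conservation", ct$score)
}

#' Correlate two per-position tracks
#'
#' Correlation over jointly non-missing positions only.
#'
#' @param a,b `IntoleranceTrack`s (or numeric vectors) of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r`, `p`, `n`. Zero-variance input yields an `NA` correlation
#'   with a warning.
#' @export
correlate_tracks <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  av <- pool_track_values(a)
  bv <- pool_track_values(b)
  stopifnot(length(av) == length(bv))
  ok <- !is.na(av) & !is.na(bv)
  n <- sum(ok)
  if (n < 3) stop("fewer than 3 jointly non-missing positions", call. = FALSE)
  if (stats::sd(av[ok]) == 0 || stats::sd(bv[ok]) == 0) {
    warning("zero-variance input; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(stats::cor.test(av[ok], bv[ok], method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Read an aligned FASTA file
#'
#' Records must be equal length (an alignment, not raw sequences).
#'
#' @param path Path to an aligned FASTA file.
#' @return A list with `matrix` (sequences x columns character matrix) and
#'   `ids`.
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1) {
    stop("records in ", path, " have unequal lengths; not an alignment",
         call. = FALSE)
  }
  m <- do.call(rbind, strsplit(as.character(ss), ""))
  rownames(m) <- names(ss)
  list(matrix = m, ids = names(ss))
}

#' Write an alignment as FASTA
#'
#' @param alignment Alignment matrix or list from `read_alignment_fasta()`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  if (is.list(alignment) && !is.matrix(alignment)) {
    alignment <- alignment$matrix
  }
  ids <- rownames(alignment)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(alignment)))
  lines <- character(0)
  for (i in seq_len(nrow(alignment))) {
    lines <- c(lines, paste0(">", ids[i]),
               paste(alignment[i, ], collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}
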
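# Precomputed single-nucleotide substitution tables over the standard genetic
# code. All downstream possibility counts (the expected side of every
# tolerance ratio) are lookups into these tables.

DNA_BASES <- c("A", "C", "G", "T")

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @importFrom Biostrings GENETIC_CODE
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  data.frame(codon = names(gc), aa = unname(gc), stringsAsFactors = FALSE)
})

STOP_CODONS <- .codon_table$codon[.codon_table$aa == "*"]
SENSE_CODONS <- .codon_table$codon[.codon_table$aa != "*"]

.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(aa)
}

# Every (sense codon, base position, alternate base) triple with its outcome:
# 61 codons x 9 substitutions = 549 rows.
.snv_table <- local({
  rows <- vector("list", length(SENSE_CODONS) * 9L)
  k <- 0L
  for (codon in SENSE_CODONS) {
    ref_aa <- .translate_codon(codon)
    bases <- strsplit(codon, "", fixed = TRUE)[[1]]
    for (pos in 1:3) {
      for (alt in setdiff(DNA_BASES, bases[pos])) {
        alt_bases <- bases
        alt_bases[pos] <- alt
        alt_codon <- paste(alt_bases, collapse = "")
        alt_aa <- .translate_codon(alt_codon)
        consequence <- if (alt_aa == "*") {
          "nonsense"
        } else if (alt_aa == ref_aa) {
          "synonymous"
        } else {
          "missense"
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          codon = codon, base_position = pos, alt_base = alt,
          alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
          consequence = consequence, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
})

# Per-codon counts of the 9 possible SNVs by consequence class.
.codon_snv_counts <- local({
  tab <- table(.snv_table$codon, .snv_table$consequence)
  out <- data.frame(
    codon = rownames(tab),
    n_missense = as.integer(tab[, "missense"]),
    n_synonymous = as.integer(tab[, "synonymous"]),
    n_nonsense = as.integer(tab[, "nonsense"]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$codon
  out
})

.check_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      !all(strsplit(codon, "", fixed = TRUE)[[1]] %in% DNA_BASES)) {
    stop("codon must be a single uppercase ACGT triplet, got: ",
         deparse(codon), call. = FALSE)
  }
  if (codon %in% STOP_CODONS) {
    stop("codon ", codon, " is a stop codon, not a sense codon", call. = FALSE)
  }
  invisible(codon)
}

#' Classify a single-nucleotide substitution within a codon
#'
#' Applies the standard genetic code to the codon obtained by replacing the
#' base at `base_position` with `alt_base`, and classifies the amino-acid
#' consequence as missense, synonymous or nonsense.
#'
#' @param codon A sense codon (uppercase ACGT triplet).
#' @param base_position Position of the substituted base within the codon
#'   (1, 2 or 3).
#' @param alt_base The alternate base; must differ from the reference base at
#'   `base_position`.
#'
#' @return A list with elements `consequence` (one of `"missense"`,
#'   `"synonymous"`, `"nonsense"`), `ref_aa`, `alt_aa` (single-letter amino
#'   acids; `alt_aa` is `"*"` for nonsense) and `alt_codon`.
#' @examples
#' classify_substitution("GCT", 3, "A")  # synonymous (Ala)
#' classify_substitution("TGG", 3, "A")  # nonsense (TGA)
#' @export
classify_substitution <- function(codon, base_position, alt_base) {
  .check_codon(codon)
  if (!base_position %in% 1:3) {
    stop("base_position must be 1, 2 or 3", call. = FALSE)
  }
  if (!is.character(alt_base) || length(alt_base) != 1L ||
      !alt_base %in% DNA_BASES) {
    stop("alt_base must be one of A, C, G, T", call. = FALSE)
  }
  ref_base <- substr(codon, base_position, base_position)
  if (alt_base == ref_base) {
    stop("alt_base equals the reference base at position ", base_position,
         call. = FALSE)
  }
  hit <- .snv_table[.snv_table$codon == codon &
                      .snv_table$base_position == base_position &
                      .snv_table$alt_base == alt_base, ]
  list(consequence = hit$consequence, ref_aa = hit$ref_aa,
       alt_aa = hit$alt_aa, alt_codon = hit$alt_codon)
}

#' Count the possible single-nucleotide substitutions of a codon by class
#'
#' Enumerates all 9 single-nucleotide substitutions of a sense codon and
#' counts how many are missense, synonymous and nonsense. These counts are
#' the expected-side denominator of the tolerance ratios.
#'
#' @param codon A sense codon (uppercase ACGT triplet).
#' @return A list with integer elements `n_missense`, `n_synonymous`,
#'   `n_nonsense`; the three always sum to 9.
#' @examples
#' enumerate_codon_snvs("GCT")  # 6 missense, 3 synonymous, 0 nonsense
#' @export
enumerate_codon_snvs <- function(codon) {
  .check_codon(codon)
  row <- .codon_snv_counts[codon, ]
  list(n_missense = row$n_missense, n_synonymous = row$n_synonymous,
       n_nonsense = row$n_nonsense)
}

# Vectorised possibility counts for a codon vector (internal fast path).
.possibility_counts <- function(codons) {
  idx <- match(codons, .codon_snv_counts$codon)
  if (anyNA(idx)) {
    stop("non-sense codon(s) in gene model: ",
         paste(unique(codons[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  list(n_missense = .codon_snv_counts$n_missense[idx],
       n_synonymous = .codon_snv_counts$n_synonymous[idx])
}
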
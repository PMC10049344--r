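# Domain types: GeneModel (codon-indexed coordinate frame), VariantSet
# (unique amino-acid-level substitutions with cohort labels), and the
# variant-set filters used to build mutually exclusive case/control sets.

#' Construct a gene model
#'
#' A gene model is the coordinate frame for every intolerance track: an
#' ordered codon sequence with its translation. Codon index `i` (1-based)
#' indexes all per-position scores.
#'
#' @param gene_id Gene identifier.
#' @param codons Character vector of uppercase ACGT triplets (sense codons
#'   only; the terminal stop is not part of the model).
#' @param transcript_id Transcript identifier; the analysis assumes one
#'   transcript per gene.
#' @param is_dee_gene Whether the gene belongs to the configured disease gene
#'   list (e.g. an epileptic-encephalopathy panel).
#'
#' @return An object of class `GeneModel` with fields `gene_id`,
#'   `transcript_id`, `codons`, `protein_seq`, `length`, `is_dee_gene`.
#' @export
gene_model <- function(gene_id, codons, transcript_id = paste0(gene_id, "-t1"),
                       is_dee_gene = FALSE) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.character(codons), length(codons) >= 1L)
  bad <- !codons %in% .codon_table$codon
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codons[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(codons %in% STOP_CODONS)) {
    stop("internal stop codon in gene ", gene_id, call. = FALSE)
  }
  protein <- paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, codons = codons,
         protein_seq = protein, length = length(codons),
         is_dee_gene = isTRUE(is_dee_gene)),
    class = "GeneModel"
  )
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("<GeneModel %s (%s): %d codons%s>\n", x$gene_id,
              x$transcript_id, x$length,
              if (x$is_dee_gene) ", disease panel" else ""))
  invisible(x)
}

# Variant uniqueness key. Amino-acid-level by default; population variant
# sets carry an alt_codon column so that distinct nucleotide changes with the
# same amino-acid outcome (synonymous changes in particular) remain distinct
# observations, as in the underlying tolerance-ratio calculation.
.variant_key <- function(df) {
  key <- paste(df$gene_id, df$codon_index, df$ref_aa, df$alt_aa, sep = "|")
  if ("alt_codon" %in% names(df)) {
    key <- paste(key, df$alt_codon, sep = "|")
  }
  key
}

.empty_variants <- function(alt_codon = FALSE) {
  df <- data.frame(gene_id = character(), codon_index = integer(),
                   ref_aa = character(), alt_aa = character(),
                   consequence = character(), cohort = character(),
                   stringsAsFactors = FALSE)
  if (alt_codon) df$alt_codon <- character()
  df
}

#' Construct a variant set
#'
#' A variant set is a data frame of amino-acid-level substitutions, unique by
#' variant key, carrying a label and free-text provenance. Required columns:
#' `gene_id`, `codon_index`, `ref_aa`, `alt_aa`, `consequence`. Optional:
#' `cohort`, `clinvar_significance`, `alt_codon` (nucleotide-level key
#' extension used for population variation).
#'
#' @param variants Data frame of variants.
#' @param label Set label (e.g. `"case"`, `"population"`).
#' @param provenance Free-text notes recording upstream filters.
#' @param genes Optional named list of `GeneModel`s; when given, variants are
#'   validated against them: out-of-range positions and reference amino acids
#'   disagreeing with the gene model are rejected (dropped with a message),
#'   mirroring a transcript-mismatch check.
#' @return A `VariantSet`: the data frame with attributes `label`,
#'   `provenance` and `n_dropped`.
#' @export
variant_set <- function(variants, label = "unlabelled", provenance = "",
                        genes = NULL) {
  req <- c("gene_id", "codon_index", "ref_aa", "alt_aa", "consequence")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0) {
    stop("missing variant columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  variants$codon_index <- as.integer(variants$codon_index)
  n_dropped <- 0L
  if (!is.null(genes) && nrow(variants) > 0) {
    keep <- rep(TRUE, nrow(variants))
    for (i in seq_len(nrow(variants))) {
      g <- genes[[variants$gene_id[i]]]
      if (is.null(g)) next
      pos <- variants$codon_index[i]
      if (pos < 1L || pos > g$length ||
          substr(g$protein_seq, pos, pos) != variants$ref_aa[i]) {
        keep[i] <- FALSE
      }
    }
    n_dropped <- sum(!keep)
    if (n_dropped > 0) {
      message(n_dropped,
              " variant(s) rejected: position out of range or reference ",
              "amino acid disagrees with the gene model")
      variants <- variants[keep, , drop = FALSE]
    }
  }
  dup <- duplicated(.variant_key(variants))
  variants <- variants[!dup, , drop = FALSE]
  rownames(variants) <- NULL
  structure(variants, label = label, provenance = provenance,
            n_dropped = n_dropped, class = c("VariantSet", "data.frame"))
}

#' @export
print.VariantSet <- function(x, ...) {
  cat(sprintf("<VariantSet '%s': %d variants>\n", attr(x, "label"), nrow(x)))
  if (nzchar(attr(x, "provenance"))) {
    cat("  provenance:", attr(x, "provenance"), "\n")
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

.as_vs <- function(df, label, provenance = "") {
  rownames(df) <- NULL
  structure(df, label = label, provenance = provenance, n_dropped = 0L,
            class = c("VariantSet", "data.frame"))
}

#' Filter a variant set on clinical significance
#'
#' Keeps only missense records whose significance is benign, likely benign,
#' pathogenic or likely pathogenic; unknown and conflicting records are
#' removed, and records missing the significance field are dropped with a
#' logged count.
#'
#' @param records A `VariantSet` with a `clinvar_significance` column.
#' @return A filtered `VariantSet`; the numbers removed are appended to its
#'   provenance.
#' @export
filter_significance <- function(records) {
  if (nrow(records) == 0) return(records)
  if (!"clinvar_significance" %in% names(records)) {
    stop("records carry no clinvar_significance column", call. = FALSE)
  }
  sig <- records$clinvar_significance
  n_missing <- sum(is.na(sig) | !nzchar(trimws(ifelse(is.na(sig), "", sig))))
  if (n_missing > 0) {
    message(n_missing, " record(s) missing a significance label were dropped")
  }
  keep_sig <- c("benign", "likely_benign", "pathogenic", "likely_pathogenic")
  keep <- !is.na(sig) & sig %in% keep_sig & records$consequence == "missense"
  out <- records[keep, , drop = FALSE]
  prov <- paste0(attr(records, "provenance"),
                 "; significance filter: kept ", nrow(out), " of ",
                 nrow(records), " (", n_missing, " missing significance)")
  .as_vs(as.data.frame(out), attr(records, "label"), prov)
}

#' Set difference of two variant sets
#'
#' Returns the variants of `a` whose key does not occur in `b`; used to make
#' case and control sets mutually exclusive.
#'
#' @param a,b `VariantSet`s sharing the key convention.
#' @return A `VariantSet` containing `a \\ b`.
#' @export
subtract_sets <- function(a, b) {
  keep <- !.variant_key(a) %in% .variant_key(b)
  prov <- paste0(attr(a, "provenance"), "; subtracted ", sum(!keep),
                 " variant(s) present in '", attr(b, "label"), "'")
  .as_vs(as.data.frame(a)[keep, , drop = FALSE], attr(a, "label"), prov)
}

#' Restrict a variant set to a gene list, with a per-gene tally
#'
#' @param set A `VariantSet`.
#' @param genes Character vector of gene ids.
#' @return A list with `set` (the restricted `VariantSet`) and `tally` (a
#'   named integer vector over genes with at least one variant, summing to
#'   the size of the restricted set).
#' @export
subset_to_genes <- function(set, genes) {
  keep <- set$gene_id %in% genes
  out <- .as_vs(as.data.frame(set)[keep, , drop = FALSE],
                attr(set, "label"),
                paste0(attr(set, "provenance"), "; restricted to ",
                       length(genes), " gene(s)"))
  tally <- table(out$gene_id)
  tally <- stats::setNames(as.integer(tally), names(tally))
  tally <- tally[sort(names(tally))]
  list(set = out, tally = tally)
}

#' Read a variant table from TSV
#'
#' Expects at least the columns `gene`, `protein_position`, `ref_aa`,
#' `alt_aa`; optional `consequence`, `cohort`, `clinvar_significance` and
#' predictor score columns are carried through. Rows whose ref/alt amino
#' acids are not single letters (multi-residue or indel records) are dropped
#' with a logged count, since the analysis is missense-only. Lines starting
#' with `#` are treated as a provenance header.
#'
#' @param path Path to a tab-separated file.
#' @param label Label for the resulting set.
#' @param genes Optional named list of `GeneModel`s for validation.
#' @return A `VariantSet`.
#' @export
read_variant_tsv <- function(path, label = basename(path), genes = NULL) {
  header <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0 || !startsWith(line, "#")) break
    header <- c(header, sub("^#\\s?", "", line))
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "protein_position", "ref_aa", "alt_aa")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("variant table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  single <- nchar(df$ref_aa) == 1L & nchar(df$alt_aa) == 1L &
    df$ref_aa %in% AA_ALPHABET & df$alt_aa %in% c(AA_ALPHABET, "*")
  if (any(!single)) {
    message(sum(!single), " non single-residue record(s) dropped from ", path)
    df <- df[single, , drop = FALSE]
  }
  names(df)[names(df) == "gene"] <- "gene_id"
  names(df)[names(df) == "protein_position"] <- "codon_index"
  if (!"consequence" %in% names(df)) {
    df$consequence <- ifelse(df$alt_aa == "*", "nonsense",
                             ifelse(df$alt_aa == df$ref_aa,
                                    "synonymous", "missense"))
  }
  if (!"cohort" %in% names(df)) df$cohort <- label
  variant_set(df, label = label,
              provenance = paste(header, collapse = " | "), genes = genes)
}

#' Write a variant set as TSV with a provenance header
#'
#' @param set A `VariantSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(set, path) {
  df <- as.data.frame(set)
  names(df)[names(df) == "gene_id"] <- "gene"
  names(df)[names(df) == "codon_index"] <- "protein_position"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# label: ", attr(set, "label")),
               paste0("# provenance: ", attr(set, "provenance")),
               paste0("# n_variants: ", nrow(df))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
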
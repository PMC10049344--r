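# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: translation goes through seqinr, window counting
# is a per-window recount, neighbourhoods are an all-pairs distance filter,
# and divergence is a direct two-term entropy computation.

oracle_translate <- function(codon) {
  toupper(seqinr::translate(strsplit(tolower(codon), "")[[1]]))
}

# naive per-window MTR recomputation straight from the definitions
oracle_mtr <- function(gene, variants, size) {
  h <- (size - 1) %/% 2
  L <- gene$length
  df <- as.data.frame(variants)
  df <- df[df$gene_id == gene$gene_id, , drop = FALSE]
  key_cols <- intersect(c("gene_id", "codon_index", "ref_aa", "alt_aa",
                          "alt_codon"), names(df))
  df <- df[!duplicated(do.call(paste, df[key_cols])), , drop = FALSE]
  sapply(seq_len(L), function(i) {
    win <- max(1, i - h):min(L, i + h)
    om <- sum(df$consequence == "missense" & df$codon_index %in% win)
    os <- sum(df$consequence == "synonymous" & df$codon_index %in% win)
    em <- 0; es <- 0
    for (j in win) {
      cnt <- enumerate_codon_snvs(gene$codons[j])
      em <- em + cnt$n_missense
      es <- es + cnt$n_synonymous
    }
    if (om + os == 0) return(NA_real_)
    (om / (om + os)) / (em / (em + es))
  })
}

oracle_neighbors <- function(structure, focal, radius) {
  res <- structure$residues[structure$residues$has_rep, , drop = FALSE]
  i <- match(as.character(focal), res$residue_id)
  d <- sqrt((res$x - res$x[i])^2 + (res$y - res$y[i])^2 +
              (res$z - res$z[i])^2)
  res$residue_id[d <= radius]
}

# two-term entropy JSD on explicit distributions, log base 2
oracle_jsd <- function(p, q) {
  H <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  H((p + q) / 2) - (H(p) + H(q)) / 2
}

# pseudocounted column distribution matching the documented convention
oracle_column_dist <- function(letters, pseudocount = 1 / 50) {
  letters <- letters[letters != "-"]
  counts <- table(factor(letters, levels = spatialMTR:::AA_ALPHABET))
  (as.numeric(counts) + pseudocount) / (sum(counts) + 20 * pseudocount)
}

# small helper: gene from an explicit codon string
gene_from_codons <- function(codon_string, id = "toy") {
  codons <- substring(codon_string, seq(1, nchar(codon_string), 3),
                      seq(3, nchar(codon_string), 3))
  gene_model(id, codons)
}

toy_variants <- function(df, label = "toy") {
  if (!"consequence" %in% names(df)) {
    df$consequence <- ifelse(df$ref_aa == df$alt_aa, "synonymous", "missense")
  }
  if (!"cohort" %in% names(df)) df$cohort <- rep(label, nrow(df))
  variant_set(df, label = label)
}
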
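# Spatial Missense Tolerance Ratio (MTR3D): the observed/expected missense
# ratio of compute_mtr, but with the window replaced by the set of codons
# whose mapped residues fall within a distance radius of the focal residue
# in the protein structure.

#' Compute the spatial Missense Tolerance Ratio over a structure
#'
#' For each codon with a mapped residue, the score is the observed missense
#' proportion among observed missense + synonymous variants at the codons
#' mapped into the focal residue's spatial neighbourhood, divided by the
#' proportion expected from those codons' possible substitutions. Codons
#' without a mapped residue are missing: a valid spatial score exists only
#' where the sequence-to-structure mapping succeeds. Unmapped neighbourhood
#' residues contribute nothing to either sum, keeping numerator and
#' denominator consistent.
#'
#' @param gene A `GeneModel`.
#' @param population_variants A `VariantSet` of standing variation.
#' @param map A `SeqStructMap` for this gene and structure.
#' @param structure The mapped `StructureModel`.
#' @param radius Spatial radius in Angstrom (default 8).
#' @return An `IntoleranceTrack` named `MTR3D`.
#' @export
compute_mtr3d <- function(gene, population_variants, map, structure,
                          radius = 8) {
  L <- gene$length
  score <- rep(NA_real_, L)
  om_out <- rep(NA_real_, L)
  os_out <- rep(NA_real_, L)
  ep_out <- rep(NA_real_, L)
  pairs <- map$pairs
  if (nrow(pairs) == 0) {
    warning("no mapped codons for gene ", gene$gene_id, "; all-missing track")
    return(.new_track(gene$gene_id, "MTR3D", score))
  }
  res <- structure$residues
  res_idx <- match(pairs$residue_id, res$residue_id)
  usable <- res$has_rep[res_idx]
  poss <- .possibility_counts(gene$codons)
  obs <- .observed_per_codon(population_variants, gene)
  coords <- cbind(res$x[res_idx], res$y[res_idx], res$z[res_idx])
  r2 <- radius^2
  for (k in which(usable)) {
    d2 <- (coords[, 1] - coords[k, 1])^2 + (coords[, 2] - coords[k, 2])^2 +
      (coords[, 3] - coords[k, 3])^2
    nb_codons <- pairs$codon_index[usable & !is.na(d2) & d2 <= r2]
    om <- sum(obs$obs_mis[nb_codons])
    os <- sum(obs$obs_syn[nb_codons])
    em <- sum(poss$n_missense[nb_codons])
    es <- sum(poss$n_synonymous[nb_codons])
    i <- pairs$codon_index[k]
    ep_out[i] <- em / (em + es)
    om_out[i] <- om
    os_out[i] <- os
    if (om + os > 0) score[i] <- (om / (om + os)) / ep_out[i]
  }
  .new_track(gene$gene_id, "MTR3D", score, obs_mis = om_out, obs_syn = os_out,
             exp_prop = ep_out)
}
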
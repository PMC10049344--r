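# Protein structure ingestion and geometry: residue-level models read from
# PDB files, sequence<->structure residue mapping by alignment, spatial
# neighbourhoods on representative-atom distances, and Shrake-Rupley
# relative solvent accessibility.

# Van der Waals radii (Angstrom) by element symbol; fallback 1.70.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                P = 1.80, SE = 1.90)

# Theoretical maximal accessible surface areas (Angstrom^2) per residue,
# Tien-style values, used to normalise residue SASA into relative solvent
# accessibility.
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
             G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
             P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)

.element_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Construct a structure model
#'
#' @param structure_id Identifier (e.g. PDB id or model name).
#' @param residues Data frame with columns `residue_id` (author numbering as
#'   a string, insertion codes included), `amino_acid` (single letter),
#'   `x`, `y`, `z` (representative-atom coordinates, Angstrom) and optional
#'   `has_rep` (whether the representative atom is present; defaults TRUE).
#' @param source_kind `"experimental"` or `"homology"`.
#' @param atoms Optional data frame of all atoms (`residue_id`, `element`,
#'   `x`, `y`, `z`, `radius`); required for solvent accessibility. When
#'   omitted, each residue contributes its representative atom.
#' @return A `StructureModel`.
#' @export
structure_model <- function(structure_id, residues,
                            source_kind = c("experimental", "homology"),
                            atoms = NULL) {
  source_kind <- match.arg(source_kind)
  residues$residue_id <- as.character(residues$residue_id)
  if (anyDuplicated(residues$residue_id)) {
    stop("duplicate residue identifiers in ", structure_id, call. = FALSE)
  }
  if (!"has_rep" %in% names(residues)) residues$has_rep <- TRUE
  coords <- as.matrix(residues[, c("x", "y", "z")])
  if (any(!is.finite(coords[residues$has_rep, ]))) {
    stop("non-finite representative coordinates in ", structure_id,
         call. = FALSE)
  }
  if (is.null(atoms)) {
    atoms <- data.frame(residue_id = residues$residue_id[residues$has_rep],
                        element = "C",
                        x = residues$x[residues$has_rep],
                        y = residues$y[residues$has_rep],
                        z = residues$z[residues$has_rep],
                        radius = 1.70, stringsAsFactors = FALSE)
  }
  rownames(residues) <- NULL
  structure(list(structure_id = structure_id, source_kind = source_kind,
                 residues = residues, atoms = atoms),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("<StructureModel %s (%s): %d residues, %d with rep atom>\n",
              x$structure_id, x$source_kind, nrow(x$residues),
              sum(x$residues$has_rep)))
  invisible(x)
}

#' Read a protein chain from a PDB file
#'
#' Parses ATOM records of one chain into a `StructureModel`. The first model
#' of multi-model files is used; for alternate locations the
#' highest-occupancy conformer of each atom is kept. Residues lacking the
#' representative atom are retained but flagged (`has_rep = FALSE`) and take
#' no part in spatial neighbourhoods. Insertion codes yield distinct residue
#' identities (e.g. `"52"` and `"52A"`).
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; default the first protein chain.
#' @param rep_atom Representative atom name (default `"CA"`).
#' @param source_kind `"experimental"` (default) or `"homology"`.
#' @return A `StructureModel`.
#' @export
read_structure <- function(path, chain = NULL, rep_atom = "CA",
                           source_kind = c("experimental", "homology")) {
  source_kind <- match.arg(source_kind)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  at <- at[!is.na(aa1) & aa1 != "X", , drop = FALSE]
  if (nrow(at) == 0) stop("no protein chain in ", path, call. = FALSE)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms for chain ", chain, call. = FALSE)

  ins <- ifelse(is.na(at$insert) | at$insert == " ", "", at$insert)
  at$residue_id <- paste0(at$resno, ins)
  # highest-occupancy conformer per (residue, atom name)
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(at$residue_id, at$elety, -occ)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$residue_id, at$elety)), , drop = FALSE]

  # stable residue order: by residue number then insertion code
  ins2 <- ifelse(is.na(at$insert) | at$insert == " ", "", at$insert)
  res_ids <- unique(at$residue_id[order(at$resno, ins2)])
  rep_at <- at[at$elety == rep_atom, , drop = FALSE]
  rep_idx <- match(res_ids, rep_at$residue_id)
  aa <- suppressWarnings(bio3d::aa321(at$resid[match(res_ids, at$residue_id)]))
  residues <- data.frame(
    residue_id = res_ids, amino_acid = aa,
    x = rep_at$x[rep_idx], y = rep_at$y[rep_idx], z = rep_at$z[rep_idx],
    has_rep = !is.na(rep_idx), stringsAsFactors = FALSE
  )
  residues$x[!residues$has_rep] <- NA_real_
  residues$y[!residues$has_rep] <- NA_real_
  residues$z[!residues$has_rep] <- NA_real_
  element <- ifelse(nzchar(trimws(at$elesy)), trimws(at$elesy),
                    substr(trimws(at$elety), 1, 1))
  atoms <- data.frame(residue_id = at$residue_id, element = element,
                      x = at$x, y = at$y, z = at$z,
                      radius = .element_radius(element),
                      stringsAsFactors = FALSE)
  structure_model(sub("\\.pdb$", "", basename(path)), residues,
                  source_kind = source_kind, atoms = atoms)
}

#' Write a structure model as a (representative-atom) PDB file
#'
#' Emits one CA ATOM record per residue with a representative atom, in
#' standard fixed-column PDB format. Used by the synthetic-structure
#' generator for byte-reproducible fixtures.
#'
#' @param structure A `StructureModel`.
#' @param path Output path.
#' @param chain Chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path, chain = "A") {
  res <- structure$residues[structure$residues$has_rep, , drop = FALSE]
  aa3 <- bio3d::aa123(res$amino_acid)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(res)), aa3, chain, as.integer(res$residue_id),
    res$x, res$y, res$z, 1.00, 0.00
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Identity-flavoured substitution matrix for sequence->structure mapping.
.identity_submat <- function(match = 2, mismatch = -1) {
  letters <- c(AA_ALPHABET, "X")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m["X", ] <- mismatch
  m[, "X"] <- mismatch
  m
}

#' Map gene protein positions to structure residue numbers
#'
#' Aligns the gene's protein sequence to the structure's residue sequence
#' (affine-gap alignment, identity scoring, end gaps on the gene side free so
#' partial structures map to the region they cover) and records the aligned,
#' non-gap position pairs. `match_fraction` is the proportion of paired
#' positions whose amino acids agree -- the structure-selection criterion.
#'
#' @param gene A `GeneModel`.
#' @param structure A `StructureModel`.
#' @return A `SeqStructMap`: list with `gene_id`, `structure_id`,
#'   `source_kind`, `pairs` (data frame of `codon_index`, `residue_id`,
#'   `match`) and `match_fraction`.
#' @export
map_sequence_to_structure <- function(gene, structure) {
  struct_seq <- paste(ifelse(is.na(structure$residues$amino_acid), "X",
                             structure$residues$amino_acid), collapse = "")
  empty <- function() {
    list(gene_id = gene$gene_id, structure_id = structure$structure_id,
         source_kind = structure$source_kind,
         pairs = data.frame(codon_index = integer(), residue_id = character(),
                            match = logical(), stringsAsFactors = FALSE),
         match_fraction = 0)
  }
  if (nchar(struct_seq) == 0) return(structure(empty(), class = "SeqStructMap"))
  aln <- Biostrings::pairwiseAlignment(
    pattern = gene$protein_seq, subject = struct_seq, type = "local-global",
    substitutionMatrix = .identity_submat(), gapOpening = 10, gapExtension = 0.5
  )
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ip <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  is_ <- Biostrings::start(Biostrings::subject(aln)) - 1L
  codon_index <- integer(0); struct_idx <- integer(0)
  for (k in seq_along(p)) {
    if (p[k] != "-") ip <- ip + 1L
    if (s[k] != "-") is_ <- is_ + 1L
    if (p[k] != "-" && s[k] != "-") {
      codon_index <- c(codon_index, ip)
      struct_idx <- c(struct_idx, is_)
    }
  }
  if (length(codon_index) == 0) return(structure(empty(), class = "SeqStructMap"))
  pairs <- data.frame(
    codon_index = codon_index,
    residue_id = structure$residues$residue_id[struct_idx],
    match = substring(gene$protein_seq, codon_index, codon_index) ==
      structure$residues$amino_acid[struct_idx],
    stringsAsFactors = FALSE
  )
  out <- list(gene_id = gene$gene_id, structure_id = structure$structure_id,
              source_kind = structure$source_kind, pairs = pairs,
              match_fraction = mean(pairs$match))
  structure(out, class = "SeqStructMap")
}

#' @export
print.SeqStructMap <- function(x, ...) {
  cat(sprintf(
    "<SeqStructMap %s -> %s (%s): %d pairs, match_fraction %.3f>\n",
    x$gene_id, x$structure_id, x$source_kind, nrow(x$pairs),
    x$match_fraction))
  invisible(x)
}

#' Select the best structure mapping
#'
#' Experimental structures are preferred over homology models; within the
#' preferred class the mapping with the highest proportion of matching
#' sequence/structure positions wins. Ties break by larger pair count, then
#' lexicographic structure id, so selection is deterministic. When `position`
#' is given, only mappings covering that codon are candidates, allowing
#' different partial structures to serve different variants.
#'
#' @param maps List of `SeqStructMap`s.
#' @param position Optional codon index a candidate must cover.
#' @return The selected `SeqStructMap`, or `NULL` if no candidate covers
#'   `position`.
#' @export
select_structure <- function(maps, position = NULL) {
  stopifnot(length(maps) >= 1)
  if (!is.null(position)) {
    maps <- Filter(function(m) position %in% m$pairs$codon_index, maps)
    if (length(maps) == 0) return(NULL)
  }
  kind <- vapply(maps, function(m) m$source_kind, character(1))
  if (any(kind == "experimental")) maps <- maps[kind == "experimental"]
  mf <- vapply(maps, function(m) m$match_fraction, numeric(1))
  np <- vapply(maps, function(m) nrow(m$pairs), numeric(1))
  id <- vapply(maps, function(m) m$structure_id, character(1))
  ord <- order(-mf, -np, id)
  maps[[ord[1]]]
}

#' Spatial neighbourhood of a residue
#'
#' All residues whose representative atoms lie within `radius` Angstrom
#' (Euclidean, inclusive) of the focal residue's representative atom; the
#' focal residue is always a member. This is the spatial window of the 3D
#' tolerance ratio.
#'
#' @param structure A `StructureModel`.
#' @param focal Focal `residue_id` (coerced to character).
#' @param radius Radius in Angstrom.
#' @return A `SpatialNeighborhood`: list with `focal`, `members` (residue
#'   ids) and `radius`.
#' @export
spatial_neighbors <- function(structure, focal, radius) {
  focal <- as.character(focal)
  res <- structure$residues
  i <- match(focal, res$residue_id)
  if (is.na(i)) stop("unknown residue ", focal, call. = FALSE)
  if (!res$has_rep[i]) {
    stop("focal residue ", focal, " has no representative atom", call. = FALSE)
  }
  usable <- res$has_rep
  d2 <- (res$x - res$x[i])^2 + (res$y - res$y[i])^2 + (res$z - res$z[i])^2
  members <- res$residue_id[usable & !is.na(d2) & d2 <= radius^2]
  structure(list(focal = focal, members = members, radius = radius),
            class = "SpatialNeighborhood")
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue relative solvent accessibility (Shrake-Rupley)
#'
#' Computes solvent-accessible surface area with the Shrake-Rupley rolling
#' sphere method (default 960 test points per atom, probe radius 1.4
#' Angstrom) over the structure's atoms, sums per residue, and divides by
#' the amino acid's theoretical maximal accessible area (`MAX_ASA`). Values
#' are >= 0 and can slightly exceed 1 for highly exposed residues.
#'
#' @param structure A `StructureModel` with populated atoms.
#' @param n_points Sphere test points per atom.
#' @param probe Probe radius in Angstrom.
#' @return A data frame with `residue_id`, `amino_acid`, `sasa` (Angstrom^2)
#'   and `rsa`.
#' @export
compute_rsa <- function(structure, n_points = 960, probe = 1.4) {
  at <- structure$atoms
  if (is.null(at) || nrow(at) == 0) stop("structure has no atoms", call. = FALSE)
  pts <- .sphere_points(n_points)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rr <- at$radius + probe
  n <- nrow(at)
  asa <- numeric(n)
  # pairwise neighbour lists: atoms whose expanded spheres intersect
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rr + rr[i])^2 & seq_len(n) != i)
    surf <- sweep(pts * rr[i], 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
        (surf[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj2 > rr[j]^2
      if (!any(accessible)) break
    }
    asa[i] <- 4 * pi * rr[i]^2 * mean(accessible)
  }
  res <- structure$residues
  sasa <- vapply(res$residue_id,
                 function(id) sum(asa[at$residue_id == id]), numeric(1))
  rsa <- sasa / unname(MAX_ASA[res$amino_acid])
  data.frame(residue_id = res$residue_id, amino_acid = res$amino_acid,
             sasa = unname(sasa), rsa = unname(rsa), stringsAsFactors = FALSE)
}
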
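test_that("generator-written PDB round-trips through the structure reader", {
  g <- generate_gene(30, seed = 9, gene_id = "gP")
  st <- generate_structure(g, "helix")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st$structure, path)
  back <- read_structure(path)
  expect_equal(nrow(back$residues), 30)
  expect_equal(back$residues$residue_id, as.character(1:30))
  expect_equal(back$residues$amino_acid,
               strsplit(g$protein_seq, "")[[1]])
  expect_equal(back$residues$x, st$structure$residues$x, tolerance = 1e-3)
  expect_true(all(back$residues$has_rep))
})

test_that("residues lacking the representative atom are flagged and excluded", {
  g <- generate_gene(30, seed = 9, gene_id = "gP")
  st <- generate_structure(g, "extended")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st$structure, path)
  lines <- readLines(path)
  # residue 10 keeps a side-chain atom but loses its CA
  hit <- grepl("^ATOM", lines) &
    suppressWarnings(as.integer(substr(lines, 23, 26))) == 10
  lines[hit] <- sub(" CA ", " CB ", lines[hit])
  writeLines(lines, path)
  back <- read_structure(path)
  expect_equal(sum(back$residues$has_rep), 29)
  expect_error(spatial_neighbors(back, "10", 5), "no representative atom")
  nb <- spatial_neighbors(back, "9", 4)
  expect_false("10" %in% nb$members)
})

test_that("insertion codes yield distinct residue identities", {
  lines <- c(
    "ATOM      1  CA  ALA A  52      0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A  52A     3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  VAL A  53      7.600   0.000   0.000  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  back <- read_structure(path)
  expect_equal(back$residues$residue_id, c("52", "52A", "53"))
  expect_equal(back$residues$amino_acid, c("A", "G", "V"))
})

test_that("altloc conformers collapse to the highest occupancy", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  back <- read_structure(path)
  expect_equal(nrow(back$residues), 2)
  expect_equal(back$residues$x[1], 9.0)
})

test_that("sequence-to-structure mapping recovers identity, partial coverage and substitutions", {
  g <- generate_gene(100, seed = 12, gene_id = "gM")
  st <- generate_structure(g, "extended")
  m <- map_sequence_to_structure(g, st$structure)
  expect_equal(nrow(m$pairs), 100)
  expect_equal(m$pairs$codon_index, 1:100)
  expect_equal(m$match_fraction, 1.0)

  # partial structure covering positions 40..80 only
  part <- st$structure
  part$residues <- part$residues[40:80, ]
  part$structure_id <- "partial"
  mp <- map_sequence_to_structure(g, part)
  expect_equal(sort(mp$pairs$codon_index), 40:80)
  expect_equal(mp$match_fraction, 1.0)

  # two engineered substitutions over 100 aligned residues
  sub <- st$structure
  aa <- sub$residues$amino_acid
  for (i in c(25, 75)) {
    aa[i] <- setdiff(c("A", "G"), aa[i])[1]
  }
  sub$residues$amino_acid <- aa
  ms <- map_sequence_to_structure(g, sub)
  expect_equal(nrow(ms$pairs), 100)
  expect_equal(ms$match_fraction, 0.98)
})

test_that("structure selection prefers experimental, then match fraction, with deterministic ties", {
  g <- generate_gene(60, seed = 13, gene_id = "gS")
  mk_map <- function(id, kind, mf, cover) {
    structure(list(gene_id = "gS", structure_id = id, source_kind = kind,
                   pairs = data.frame(codon_index = cover,
                                      residue_id = as.character(cover),
                                      match = TRUE),
                   match_fraction = mf), class = "SeqStructMap")
  }
  exp90 <- mk_map("exp90", "experimental", 0.90, 1:60)
  hom99 <- mk_map("hom99", "homology", 0.99, 1:60)
  expect_equal(select_structure(list(exp90, hom99))$structure_id, "exp90")
  exp95 <- mk_map("exp95", "experimental", 0.95, 1:60)
  expect_equal(select_structure(list(exp90, exp95))$structure_id, "exp95")
  # tie on match fraction: larger pair count, then lexicographic id
  a <- mk_map("bbb", "experimental", 0.9, 1:50)
  b <- mk_map("aaa", "experimental", 0.9, 1:40)
  expect_equal(select_structure(list(a, b))$structure_id, "bbb")
  b2 <- mk_map("aaa", "experimental", 0.9, 1:50)
  expect_equal(select_structure(list(a, b2))$structure_id, "aaa")
  # per-variant selection: partial structures covering different regions
  left <- mk_map("left", "experimental", 0.95, 1:100)
  right <- mk_map("right", "experimental", 0.90, 150:300)
  expect_equal(select_structure(list(left, right), position = 200)$structure_id,
               "right")
  expect_null(select_structure(list(left, right), position = 120))
})

test_that("spatial neighbourhoods equal the all-pairs distance oracle and are symmetric", {
  g <- generate_gene(80, seed = 14, gene_id = "gG")
  for (topo in c("extended", "helix")) {
    st <- generate_structure(g, topo)$structure
    for (radius in c(0, 5, 8, 12)) {
      for (focal in c("1", "17", "40", "80")) {
        nb <- spatial_neighbors(st, focal, radius)
        expect_setequal(nb$members, oracle_neighbors(st, focal, radius))
        expect_true(focal %in% nb$members)
      }
    }
    # symmetry: j in N(i, r) <=> i in N(j, r)
    for (i in c("3", "25")) {
      for (j in spatial_neighbors(st, i, 8)$members) {
        expect_true(i %in% spatial_neighbors(st, j, 8)$members)
      }
    }
  }
  st <- generate_structure(g, "extended")$structure
  expect_equal(spatial_neighbors(st, "40", 0)$members, "40")
  # radius between 2 and 3 backbone steps captures exactly +/-2 neighbours
  expect_setequal(spatial_neighbors(st, "40", 2.5 * 3.8)$members,
                  as.character(38:42))
})

test_that("isolated-sphere SASA matches the closed form within quadrature error", {
  res <- data.frame(residue_id = "1", amino_acid = "A", x = 0, y = 0, z = 0)
  atoms <- data.frame(residue_id = "1", element = "C", x = 0, y = 0, z = 0,
                      radius = 1.7)
  st <- structure_model("sphere", res, atoms = atoms)
  out <- compute_rsa(st)
  expect_equal(out$sasa, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  expect_error(compute_rsa(structure_model("none", res,
                                           atoms = atoms[0, ])), "no atoms")
})

test_that("an isolated residue has RSA near 1 and buried residues score below surface ones", {
  res <- data.frame(residue_id = "1", amino_acid = "A", x = 0, y = 0, z = 0)
  st <- structure_model("iso", res)
  out <- compute_rsa(st)
  expect_lt(abs(out$rsa - 1), 0.15)

  # buried-core packing: centre atom enclosed by an icosahedral-ish shell
  shell <- spatialMTR:::.sphere_points(12) * 4.0
  res2 <- data.frame(residue_id = as.character(1:13), amino_acid = "A",
                     x = c(0, shell[, 1]), y = c(0, shell[, 2]),
                     z = c(0, shell[, 3]))
  st2 <- structure_model("core", res2)
  out2 <- compute_rsa(st2)
  expect_lt(out2$rsa[1], min(out2$rsa[-1]))
})

test_that("ideal helix geometry places i,i+3 closer than i,i+2 with canonical backbone spacing", {
  g <- generate_gene(30, seed = 15, gene_id = "gH")
  st <- generate_structure(g, "helix")$structure
  d <- function(i, j) {
    r <- st$residues
    sqrt((r$x[i] - r$x[j])^2 + (r$y[i] - r$y[j])^2 + (r$z[i] - r$z[j])^2)
  }
  expect_equal(d(5, 6), 3.8, tolerance = 0.1)
  expect_lt(d(5, 8), d(5, 7))   # the helical turn brings i+3 back around
  expect_gt(d(5, 9), d(5, 8))
})
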
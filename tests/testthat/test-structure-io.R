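test_that("a minimal PDB text parses into the expected hierarchy", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.458   2.000   3.000  1.00 10.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m), 2)
  expect_equal(unique(m$chain), "A")
  expect_equal(unique(m$res_seq), 1L)
  expect_equal(m$atom_name, c("N", "CA"))
  expect_equal(m$x, c(1, 2.458))
  expect_true(all(m$is_heavy))
})

test_that("a minimal mmCIF atom_site loop parses", {
  f <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_test", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 5 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.500 2.000 3.000 1.00 10.00 ? 5 ALA A CA 1",
    "#"), f)
  m <- read_structure(f)
  expect_equal(nrow(m), 2)
  expect_equal(m$res_seq, c(5L, 5L))   # author numbering is authoritative
  expect_equal(m$x, c(1, 2.5))
})

test_that("read-write-read round trip preserves atoms and coordinates", {
  p <- toy12()
  f <- tempfile(fileext = ".pdb")
  write_structure(p, f)
  p2 <- read_structure(f)
  expect_equal(nrow(p2), nrow(p))
  expect_equal(p2$atom_name, p$atom_name)
  expect_equal(p2$res_seq, p$res_seq)
  expect_lt(max(abs(cbind(p$x, p$y, p$z) - cbind(p2$x, p2$y, p2$z))), 1e-3 + 1e-9)
  # second round trip is exact (coordinates already quantized)
  f2 <- tempfile(fileext = ".pdb")
  write_structure(p2, f2)
  p3 <- read_structure(f2)
  expect_equal(p3$x, p2$x)
})

test_that("non-finite coordinates are rejected on write", {
  p <- toy12()
  p$x[1] <- NaN
  expect_error(write_structure(p, tempfile()), "non-finite")
})

test_that("alt-locs collapse to the highest-occupancy conformer", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CB AALA A   1       0.000   1.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BALA A   1       1.000   1.000   0.000  0.50 10.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m), 2)
  expect_equal(m$x[m$atom_name == "CA"], 1)    # occupancy 0.6 wins
  expect_equal(m$x[m$atom_name == "CB"], 0)    # tie: first alt id wins
})

test_that("selection is stable, idempotent and counts ranges correctly", {
  long <- make_toy_protein(200, seed = 5)
  sel <- select_atoms(long, chain = "A", res_range = c(31, 155))
  expect_equal(length(unique(sel$res_seq)), 125)
  expect_identical(select_atoms(sel, chain = "A", res_range = c(31, 155)), sel)
  # absent chain gives an empty result, not an error
  expect_equal(nrow(select_atoms(long, chain = "Z")), 0)
  # selections never reorder
  ca <- select_atoms(long, atom_names = "CA")
  expect_true(!is.unsorted(ca$res_seq))
})

test_that("heavy-only selection excludes hydrogens", {
  m <- mk_atoms("A", c(1, 1), "ALA", c("CA", "HA"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(select_atoms(m, heavy_only = TRUE)$atom_name, "CA")
})

test_that("waters/het groups are retained and flagged", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "HETATM    2  O   HOH A 101       5.000   0.000   0.000  1.00 10.00           O",
    "END"), f)
  m <- read_structure(f)
  expect_equal(m$is_het, c(FALSE, TRUE))
  expect_equal(nrow(select_atoms(m, drop_het = TRUE)), 1)
})

test_that("multi-copy models get distinct chain ids and a 62-chain cap", {
  cs <- standin1()
  t1 <- extract_dimer_transform(cs$dimer1, "A", "B")
  t2 <- extract_dimer_transform(cs$dimer2, "A", "B")
  lat <- build_lattice(build_zigzag(cs$monomer, t1, t2, n_copies = 8),
                       default_row_shift(build_zigzag(cs$monomer, t1, t2, 4)),
                       n_rows = 2)
  ex <- expand_lattice(lat)
  expect_equal(length(unique(ex$chain)), 16)
  # chain extraction then reassembly preserves the atom count
  parts <- lapply(unique(ex$chain), function(ch) select_atoms(ex, chain = ch))
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(ex))
  big <- dplyr::bind_rows(lapply(1:63, function(i) {
    m <- mk_atoms("A", 1, "ALA", "CA", c(i, 0, 0)); m$chain <- paste0("c", i); m
  }))
  expect_error(write_structure(as_structure(big), tempfile()), "62")
})
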
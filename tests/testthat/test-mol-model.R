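test_that("XYZ reading covers the minimal molecule and the charge column", {
  lig <- water_ligand()
  tf <- tempfile(fileext = ".xyz")
  write_xyz(lig, tf)
  got <- read_xyz(tf)
  expect_equal(nrow(got$atoms), 3)
  expect_equal(nrow(got$bonds), 2)              # two O-H bonds
  expect_equal(got$atoms$charge, c(-0.8, 0.4, 0.4), tolerance = 1e-6)

  # a plain 4-column file reads with zero charges and a warning
  writeLines(c("3", "", "O 0 0 0", "H 0.96 0 0", "H -0.24 0.93 0"), tf)
  expect_warning(got2 <- read_xyz(tf), "charge")
  expect_true(all(got2$atoms$charge == 0))
})

test_that("XYZ round trip preserves coordinates to 1e-6 A", {
  lig <- make_toy_complex("Ru", 4, 2, seed = 3)
  tf <- tempfile(fileext = ".xyz")
  write_xyz(lig, tf)
  got <- read_xyz(tf)
  expect_equal(got$atoms$element, lig$atoms$element)
  expect_lt(max(abs(coords(got) - coords(lig))), 1e-6)
  expect_equal(got$atoms$charge, lig$atoms$charge, tolerance = 1e-5)
})

test_that("malformed XYZ input is rejected with useful errors", {
  tf <- tempfile(fileext = ".xyz")
  writeLines(c("not-a-number", "", "O 0 0 0"), tf)
  expect_error(read_xyz(tf), "header")
  writeLines(c("5", "", "O 0 0 0", "H 1 0 0"), tf)
  expect_error(read_xyz(tf), "5 atoms")
  writeLines(c("2", "", "O 0 0 0", "Qq 1 0 0"), tf)
  expect_error(read_xyz(tf), "Qq")
})

test_that("PDB reading filters waters and resolves alternate locations", {
  p <- write_tiny_pdb(n_res = 3, waters = 2, cofactor = TRUE)
  rec <- read_pdb(p)
  expect_s3_class(rec, "mc_receptor")
  expect_equal(nrow(rec$atoms), 12)             # 3 residues x 4 atoms
  rec2 <- read_pdb(p, keep_nonresidues = TRUE)
  expect_equal(nrow(rec2$atoms), 16)            # + 4 cofactor atoms, waters still gone
  expect_true("HEM" %in% rec2$atoms$resid)
  expect_false(any(rec2$atoms$resid %in% c("HOH", "WAT")))

  p2 <- write_tiny_pdb(altloc = TRUE)
  rec3 <- read_pdb(p2)
  cb <- rec3$atoms[rec3$atoms$atom_name == "CB", ]
  expect_equal(nrow(cb), 1)                     # highest occupancy kept
  expect_equal(cb$x, 3.8 + 1.2, tolerance = 1e-3)
})

test_that("multi-model PDB needs an explicit model and empty files error", {
  p <- write_tiny_pdb(models = 3)
  expect_error(read_pdb(p), "model")
  rec <- read_pdb(p, model = 2)
  expect_equal(nrow(rec$atoms), 12)
  p3 <- tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH W 100      20.000  20.000  20.000  1.00  0.00           O",
               "END"), p3)
  expect_error(read_pdb(p3), "no receptor atoms")
})

test_that("PDBQT writing emits the torsion tree and inverts through read_pdbqt", {
  rigid <- make_toy_complex("Ru", 5, 0, seed = 1)
  tq <- tempfile(fileext = ".pdbqt")
  write_pdbqt(rigid, tq)
  lines <- readLines(tq)
  expect_equal(sum(grepl("^ROOT", lines)), 1)
  expect_equal(sum(grepl("^BRANCH", lines)), 0)
  expect_true("TORSDOF 0" %in% lines)

  flex <- make_toy_complex("Ru", 5, 3, seed = 1)
  write_pdbqt(flex, tq)
  lines <- readLines(tq)
  expect_equal(sum(grepl("^BRANCH ", lines)), 3)
  expect_true("TORSDOF 3" %in% lines)

  got <- read_pdbqt(tq)
  expect_equal(nrow(got$atoms), nrow(flex$atoms))
  expect_equal(n_torsions(got), 3)
  # same atoms up to the tree-traversal permutation; charges to 3 decimals
  expect_equal(sort(got$atoms$element), sort(flex$atoms$element))
  expect_equal(sort(got$atoms$charge), sort(round(flex$atoms$charge, 3)),
               tolerance = 1e-9)
  expect_equal(sort(coords(got)[, 1]), sort(coords(flex)[, 1]), tolerance = 1e-3)
})

test_that("untyped atoms cannot be written to PDBQT", {
  lig <- water_ligand()
  expect_error(write_pdbqt(lig, tempfile()), "untyped|assign_types")
})

test_that("bond perception is symmetric, self-free, and uses the dative factor", {
  lig <- make_toy_complex("Ru", 6, 0, seed = 2)
  b <- lig$bonds
  expect_true(all(b[, 1] < b[, 2]))
  expect_equal(nrow(b), nrow(unique(b)))
  # all six ligators bonded to the metal through the 1.25 dative factor
  mi <- lig$metal_index
  expect_equal(sum(b[, 1] == mi | b[, 2] == mi), 6)
})
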
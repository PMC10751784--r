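test_that("toy complexes honour geometry, torsion count, and determinism", {
  oct <- make_toy_complex("Ru", 6, 0, seed = 1)
  expect_equal(detect_sphere(oct)$coordination_number, 6)
  expect_equal(n_torsions(oct), 0)
  cn5 <- make_toy_complex("Ru", 5, 3, seed = 2)
  expect_equal(n_torsions(cn5), 3)
  expect_identical(make_toy_complex("Os", 4, 1, seed = 9)$atoms,
                   make_toy_complex("Os", 4, 1, seed = 9)$atoms)
  expect_false(identical(make_toy_complex("Ru", 5, 0, seed = 1)$atoms$x,
                         make_toy_complex("Ru", 5, 0, seed = 2)$atoms$x))
  expect_error(make_toy_complex("Ru", 7), "coordination_number")
  # stated formal charge is honoured
  ch <- make_toy_complex("Ru", 5, 0, seed = 1, formal_charge = 2)
  expect_equal(sum(ch$atoms$charge), 2, tolerance = 1e-9)
})

test_that("the CN=5 vacancy is axial and receives the dummy", {
  lig <- make_toy_complex("Ru", 5, 0, seed = 1, jitter = 0)
  l2 <- place_dummy(lig)
  v <- coords(l2)[l2$dummy_index, ] - coords(l2)[l2$metal_index, ]
  expect_equal(v / sqrt(sum(v^2)), c(0, 0, 1), tolerance = 1e-6)
})

test_that("pockets plant a pose that beats random poses", {
  pk <- make_pocket(pocket_spec(), seed = 6, check_n = 0)
  expect_equal(pose_rmsd(pk$reference, pk$reference), 0)
  ctx_e <- function(xyz) intermolecular_energy(pk$ligand, pk$receptor,
                                               pk$params, pose_coords = xyz)$total
  expect_equal(ctx_e(pk$reference), pk$planted_energy, tolerance = 1e-9)
  set.seed(7)
  rand <- replicate(100, ctx_e(apply_genome(pk$ligand, randomize_genome(pk$ligand, pk$box))))
  expect_true(all(rand > pk$planted_energy))
})

test_that("the vacancy acceptor sits at the metal pair's optimal distance", {
  pk <- make_pocket(pocket_spec(), seed = 1, check_n = 0)
  xyz <- coords(pk$ligand)
  m <- xyz[pk$ligand$metal_index, ]
  acc <- as.numeric(pk$receptor$atoms[1, c("x", "y", "z")])
  rmin <- get_pair(pk$params, "Ru", pk$spec$acceptor_type)$rmin
  # the reference pose is relaxed, so compare against the planted geometry
  expect_equal(sqrt(sum((acc - m)^2)), rmin, tolerance = 1e-9)
})

test_that("generated fixtures round-trip through the readers", {
  fp <- make_fit_problem(n_pairs = 2, seed = 3)
  dir <- tempfile("fixtures")
  mf <- write_fixture_files(fp$pairs, dir)
  man <- read.delim(mf)
  expect_equal(nrow(man), 2)
  for (k in seq_len(nrow(man))) {
    lig <- read_xyz(man$ligand[k])
    expect_equal(nrow(lig$atoms), nrow(fp$pairs[[k]]$ligand$atoms))
    expect_lt(max(abs(coords(lig) - coords(fp$pairs[[k]]$ligand))), 1e-6)
    rec <- read_pdbqt(man$receptor[k], as = "receptor")
    expect_equal(rec$atoms$ad_type, fp$pairs[[k]]$receptor$atoms$ad_type)
    ref <- read_xyz(man$reference[k])
    expect_lt(max(abs(coords(ref) - fp$pairs[[k]]$reference)), 1e-3)
  }
})

test_that("fit problems place their optimum at the true parameters", {
  fp <- make_fit_problem(true_eps = c(HD = 5.6, "NA" = 2, OA = 1, SA = 0.2),
                         seed = 1)
  objective <- function(eps) {
    mean(unlist(lapply(fp$pairs, function(pair) {
      params <- set_metal_eps(default_params(fp$metal), eps)
      res <- mock_dock(pair$ligand, pair$receptor, params, pair$box, seed = 17)
      vapply(res$poses, function(po) {
        pose_rmsd(po$coords, pair$reference,
                  elements = pair$ligand$atoms$element,
                  dummy_index = pair$ligand$dummy_index)
      }, 0)
    })))
  }
  at_true <- objective(fp$true_eps)
  lo <- fp$true_eps; lo[] <- 0.05
  hi <- fp$true_eps; hi[] <- 6.95
  expect_lte(at_true, objective(lo))
  expect_lte(at_true, objective(hi))
  # deterministic from seed
  fp2 <- make_fit_problem(true_eps = c(HD = 5.6, "NA" = 2, OA = 1, SA = 0.2),
                          seed = 1)
  expect_equal(fp$pairs[[1]]$reference, fp2$pairs[[1]]$reference)
})

test_that("the mock docking function honours the docking contract shape", {
  fp <- make_fit_problem(n_pairs = 1, seed = 2)
  pair <- fp$pairs[[1]]
  params <- set_metal_eps(default_params("Ru"), fp$true_eps)
  res <- mock_dock(pair$ligand, pair$receptor, params, pair$box, seed = 5)
  expect_s3_class(res, "dock_result")
  expect_equal(dim(res$poses[[1]]$coords), dim(coords(pair$ligand)))
  # returned energy matches a recomputation at the returned coordinates
  expect_equal(res$poses[[1]]$energy,
               intermolecular_energy(pair$ligand, pair$receptor, params,
                                     pose_coords = res$poses[[1]]$coords)$total,
               tolerance = 1e-9)
})
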
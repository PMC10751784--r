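test_that("both LJ forms reach -eps at rmin and vanish at long range", {
  expect_equal(lj_energy(2.25, 1.7, 2.25, c(12, 6)), -1.7, tolerance = 1e-12)
  expect_equal(lj_energy(2.25, 1.7, 2.25, c(12, 10)), -1.7, tolerance = 1e-12)
  # closed-form tail magnitudes at 10 rmin: 2e-6 eps (12,6), 6e-10 eps (12,10)
  expect_lt(abs(lj_energy(22.5, 1.7, 2.25, c(12, 6))), 2.1e-6 * 1.7)
  expect_lt(abs(lj_energy(22.5, 1.7, 2.25, c(12, 10))), 1e-6 * 1.7)
  # (12,6) zero crossing at rmin * 2^(-1/6)
  expect_equal(lj_energy(2.25 * 2^(-1 / 6), 3, 2.25, c(12, 6)), 0, tolerance = 1e-9)
  expect_error(lj_energy(-1, 1, 2), "r must")
  expect_error(lj_energy(2, 1, 2, c(12, 8)), "exponents")
})

test_that("default parameters carry the fixed metal geometry and depths", {
  p <- default_params("Ru")
  expect_equal(get_pair(p, "Ru", "HD")$rmin, 1.00)
  expect_equal(get_pair(p, "Ru", "NA")$rmin, 2.20)
  expect_equal(get_pair(p, "Ru", "OA")$rmin, 2.25)
  expect_equal(get_pair(p, "Ru", "SA")$rmin, 2.30)
  expect_equal(get_pair(p, "Ru", "Ru")$eps, 0.010)
  expect_equal(get_pair(p, "Ru", "HD")$exponents, c(12L, 6L))
  expect_equal(get_pair(p, "Ru", "OA")$exponents, c(12L, 10L))
})

test_that("parameter files override pair by pair and are validated", {
  mo <- load_params(system.file("extdata", "mo_example_params.txt", package = "mcdock"),
                    defaults = default_params("Mo"))
  expect_equal(get_pair(mo, "Mo", "HD")$eps, 5.62)
  expect_equal(get_pair(mo, "Mo", "SA")$eps, 0.17)
  expect_equal(get_pair(mo, "Mo", "OA")$eps, 2.0)    # untouched default

  tf <- tempfile()
  writeLines("Ru OA -1.0 2.25 12-10", tf)
  expect_error(load_params(tf), "line 1")
  writeLines("Ru OA 1.0 2.25 12-8", tf)
  expect_error(load_params(tf), "12-6 or 12-10")
  expect_error(get_pair(default_params(), "Ru", "Zz"), "Ru-Zz|Zz")
})

test_that("the angular hydrogen-bond weight follows cos^2 with a 90-degree gate", {
  m <- c(0, 0, 0); d <- c(0, 0, 1)
  expect_equal(hbond_weight(m, d, c(0, 0, 3)), 1)
  expect_equal(hbond_weight(m, d, c(3, 0, 0)), 0)
  expect_equal(hbond_weight(m, d, c(0, 3, 3) / sqrt(2)), 0.5, tolerance = 1e-12)
  expect_equal(hbond_weight(m, d, c(0, 0, -2)), 0)
})

test_that("screened Coulomb term has the right sign, zero, and decay", {
  expect_equal(electrostatic_energy(0, 1, 3), 0)
  expect_gt(electrostatic_energy(1, 1, 3), 0)
  expect_lt(electrostatic_energy(1, -1, 3), 0)
  expect_gt(abs(electrostatic_energy(1, 1, 3)), abs(electrostatic_energy(1, 1, 6)))
  expect_error(electrostatic_energy(1, 1, 0), "r must")
})

test_that("a single metal-acceptor contact reduces to -eps", {
  lig <- new_ligand(data.frame(element = c("Ru", "N", "DD"),
                               x = c(0, -2.1, 0), y = 0, z = c(0, 0, 2),
                               charge = 0))
  lig <- assign_types(lig)
  rec <- structure(list(atoms = data.frame(
    element = "O", x = 0, y = 0, z = 2.25, charge = 0, ad_type = "OA")),
    class = "mc_receptor")
  p <- default_params("Ru")
  # neutralize the spectator nitrogen so only the metal-OA term remains
  p$pairs[[mcdock:::.pair_key("NA", "OA")]]$eps <- 0
  e <- intermolecular_energy(lig, rec, p)
  expect_equal(e$total, -get_pair(p, "Ru", "OA")$eps, tolerance = 1e-6)
  expect_equal(e$total, e$vdw + e$hbond_metal + e$electrostatic, tolerance = 1e-9)
})

test_that("a ligand far outside the cutoffs scores zero", {
  pk <- make_pocket(pocket_spec(), seed = 1, check_n = 0)
  far <- coords(pk$ligand) + 60
  e <- intermolecular_energy(pk$ligand, pk$receptor, pk$params, pose_coords = far)
  expect_lt(abs(e$total), 1e-6)
})

test_that("the energy kernel matches a brute-force R double loop", {
  pk <- make_pocket(pocket_spec(n_torsions = 0), seed = 2, check_n = 0)
  set.seed(11)
  for (k in 1:5) {
    g <- randomize_genome(pk$ligand, pk$box)
    lxyz <- apply_genome(pk$ligand, g)
    got <- intermolecular_energy(pk$ligand, pk$receptor, pk$params,
                                 lj_cutoff = 1e6, elec_cutoff = 1e6,
                                 pose_coords = lxyz)$total
    want <- oracle_energy(pk$ligand, pk$receptor, pk$params, lxyz)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("energy is invariant under joint rigid motion", {
  pk <- make_pocket(pocket_spec(), seed = 3, check_n = 0)
  e0 <- intermolecular_energy(pk$ligand, pk$receptor, pk$params)$total
  set.seed(21)
  R <- mcdock:::random_rotation(); tr <- rnorm(3)
  move <- function(x) sweep(x %*% t(R), 2, tr, "+")
  lig2 <- set_coords(pk$ligand, move(coords(pk$ligand)))
  rec2 <- pk$receptor
  rec2$atoms[, c("x", "y", "z")] <- move(coords(pk$receptor))
  expect_equal(intermolecular_energy(lig2, rec2, pk$params)$total, e0,
               tolerance = 1e-9)
})

test_that("removing the dummy can only deepen metal-acceptor terms", {
  pk <- make_pocket(pocket_spec(), seed = 4, check_n = 0)
  with_d <- intermolecular_energy(pk$ligand, pk$receptor, pk$params)
  no_dummy <- pk$ligand
  no_dummy$atoms <- no_dummy$atoms[-no_dummy$dummy_index, ]
  no_dummy$bonds <- perceive_bonds(no_dummy)
  no_dummy$dummy_index <- NA_integer_
  without <- intermolecular_energy(no_dummy, pk$receptor, pk$params,
                                   pose_coords = coords(no_dummy))
  expect_lte(without$hbond_metal, with_d$hbond_metal + 1e-9)
})

test_that("each pair's scanned minimum is -eps at rmin", {
  p <- default_params("Ru")
  for (key in c("Ru|SA", "HD|OA", "C|C")) {
    rec <- p$pairs[[key]]
    r <- seq(0.7 * rec$rmin, 3 * rec$rmin, length.out = 20000)
    e <- lj_energy(r, rec$eps, rec$rmin, rec$exponents)
    expect_equal(min(e), -rec$eps, tolerance = 1e-6)
    expect_equal(r[which.min(e)], rec$rmin, tolerance = 1e-3)
  }
})
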
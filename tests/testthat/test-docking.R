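test_that("random genomes are reproducible, box-uniform, and sized to the ligand", {
  lig <- make_toy_complex("Ru", 5, 2, seed = 1)
  box <- docking_box(c(1, -2, 3), 10)
  set.seed(99); g1 <- randomize_genome(lig, box)
  set.seed(99); g2 <- randomize_genome(lig, box)
  expect_identical(g1, g2)
  expect_length(g1, 7 + 2)
  expect_equal(sqrt(sum(g1[4:7]^2)), 1, tolerance = 1e-9)

  rigid <- make_toy_complex("Ru", 5, 0, seed = 1)
  expect_length(randomize_genome(rigid, box), 7)

  set.seed(5)
  draws <- t(replicate(10000, randomize_genome(rigid, box)[1:3]))
  se <- apply(draws, 2, sd) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - box$center) < 3 * se))
  expect_true(all(draws >= rep(box$center - 5, each = nrow(draws))))
})

test_that("Solis-Wets local search never goes uphill and solves a quadratic", {
  quad <- function(g) sum((g - c(1, 2, 3, 0.5, 0.5, 0.5, 0.5, -1))^2)
  # fitness at a genome-like vector (quaternion block renormalized)
  set.seed(3)
  g0 <- rnorm(8)
  res <- local_search(g0, function(g) sum((g[c(1:3, 8)] - c(1, 2, 3, -1))^2),
                      max_iter = 400, rho = 0.5)
  expect_lte(res$fitness, sum((g0[c(1:3, 8)] - c(1, 2, 3, -1))^2))
  expect_lt(res$fitness, 1e-3)
  expect_equal(res$genome[c(1:3, 8)], c(1, 2, 3, -1), tolerance = 0.05)
})

test_that("ga_dock is reproducible and self-consistent", {
  pk <- make_pocket(pocket_spec(), seed = 2, check_n = 0)
  cfg <- ga_config(pop_size = 20, generations = 15, polish_iter = 200)
  r1 <- ga_dock(pk$ligand, pk$receptor, pk$params, pk$box, n_runs = 2,
                config = cfg, seed = 5)
  r2 <- ga_dock(pk$ligand, pk$receptor, pk$params, pk$box, n_runs = 2,
                config = cfg, seed = 5)
  expect_equal(r1$poses[[1]]$coords, r2$poses[[1]]$coords)
  expect_equal(vapply(r1$poses, `[[`, 0, "energy"),
               vapply(r2$poses, `[[`, 0, "energy"))
  # energies sorted ascending and equal to a recomputation from coordinates
  e <- vapply(r1$poses, `[[`, 0, "energy")
  expect_false(is.unsorted(e))
  for (po in r1$poses) {
    expect_equal(po$energy,
                 intermolecular_energy(pk$ligand, pk$receptor, pk$params,
                                       pose_coords = po$coords)$total,
                 tolerance = 1e-6)
    expect_equal(po$coords, apply_genome(pk$ligand, po$genome), tolerance = 1e-12)
  }
})

test_that("per-generation best fitness never increases (elitism)", {
  pk <- make_pocket(pocket_spec(), seed = 1, check_n = 0)
  r <- ga_dock(pk$ligand, pk$receptor, pk$params, pk$box, n_runs = 1,
               config = ga_config(pop_size = 16, generations = 25,
                                  polish_iter = 50), seed = 3)
  for (trace in r$traces) {
    expect_true(all(diff(trace) <= 1e-9))
  }
})

test_that("translating receptor and box together translates the poses", {
  pk <- make_pocket(pocket_spec(), seed = 3, check_n = 0)
  cfg <- ga_config(pop_size = 16, generations = 10, polish_iter = 100)
  r1 <- ga_dock(pk$ligand, pk$receptor, pk$params, pk$box, n_runs = 1,
                config = cfg, seed = 11)
  d <- c(5, -3, 2)
  rec2 <- pk$receptor
  rec2$atoms[, c("x", "y", "z")] <- sweep(coords(pk$receptor), 2, d, "+")
  box2 <- docking_box(pk$box$center + d, pk$box$size)
  r2 <- ga_dock(pk$ligand, rec2, pk$params, box2, n_runs = 1,
                config = cfg, seed = 11)
  expect_equal(r2$poses[[1]]$energy, r1$poses[[1]]$energy, tolerance = 1e-6)
  expect_equal(r2$poses[[1]]$coords, sweep(r1$poses[[1]]$coords, 2, d, "+"),
               tolerance = 1e-6)
})

test_that("degenerate GA configurations are rejected", {
  pk <- make_pocket(pocket_spec(), seed = 1, check_n = 0)
  expect_error(ga_dock(pk$ligand, pk$receptor, pk$params, pk$box,
                       config = ga_config(pop_size = 3)), "at least 4")
})
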
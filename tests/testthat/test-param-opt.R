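test_that("epsilon proposals are uniform on [0, 7] and reproducible", {
  set.seed(31)
  x <- propose_epsilon(1e5)
  expect_true(all(x >= 0 & x <= 7))
  expect_equal(mean(x), 3.5, tolerance = 0.05)
  set.seed(31); a <- propose_epsilon(10)
  set.seed(31); b <- propose_epsilon(10)
  expect_identical(a, b)
})

# A deterministic toy docking function whose pose offset depends linearly
# on the trial well depths: fast, exactly reproducible, and with a unique
# objective minimum at eps = (3, 1, 4, 2).
toy_dock_fn <- local({
  target <- c(HD = 3, "NA" = 1, OA = 4, SA = 2)
  function(ligand, receptor, params, box, seed) {
    eps <- vapply(c("HD", "NA", "OA", "SA"), function(t)
      get_pair(params, params$metal, t)$eps, 0)
    off <- sum(abs(eps - target)) / 4
    pose <- sweep(coords(ligand), 2, c(off, 0, 0), "+")
    structure(list(poses = list(list(coords = pose, energy = -1))),
              class = "dock_result")
  }
})

test_that("greedy optimization is monotone, reproducible, and recovers the toy optimum", {
  lig <- make_toy_complex("Ru", 5, 0, seed = 1)
  lig <- place_dummy(lig)
  pair <- list(ligand = lig, receptor = NULL, reference = coords(lig),
               box = docking_box(c(0, 0, 0), 8))
  fit <- mc_optimize(list(pair), toy_dock_fn, samples_per_param = 40, seed = 2)
  acc <- fit$history$rmsd[fit$history$accepted]
  expect_true(all(diff(acc) <= 1e-12))
  expect_lte(fit$rmsd_best, fit$rmsd_init)
  expect_true(all(abs(coef(fit) - c(3, 1, 4, 2)) < 0.5))
  expect_true(all(fit$history$proposed >= 0 & fit$history$proposed <= 7))

  fit2 <- mc_optimize(list(pair), toy_dock_fn, samples_per_param = 40, seed = 2)
  expect_identical(fit$history, fit2$history)
  expect_identical(coef(fit), coef(fit2))
})

test_that("zero samples returns the initial state and empty sets error", {
  lig <- place_dummy(make_toy_complex("Ru", 5, 0, seed = 1))
  pair <- list(ligand = lig, receptor = NULL, reference = coords(lig),
               box = docking_box(c(0, 0, 0), 8))
  fit <- mc_optimize(list(pair), toy_dock_fn, samples_per_param = 0, seed = 1)
  expect_equal(unname(coef(fit)), rep(2, 4))
  expect_equal(nrow(fit$history), 0)
  expect_error(mc_optimize(list(), toy_dock_fn), "empty")
})

test_that("the Metropolis mode can accept uphill moves but tracks the best", {
  lig <- place_dummy(make_toy_complex("Ru", 5, 0, seed = 1))
  pair <- list(ligand = lig, receptor = NULL, reference = coords(lig),
               box = docking_box(c(0, 0, 0), 8))
  fit <- mc_optimize(list(pair), toy_dock_fn, samples_per_param = 30, seed = 3,
                     acceptance = "metropolis", temperature = 0.5)
  expect_gt(sum(fit$history$accepted), 0)
  expect_lte(fit$rmsd_best, fit$rmsd_init)
})

test_that("recovery error shrinks with more samples per parameter", {
  fp <- make_fit_problem(true_eps = c(HD = 5.6, "NA" = 2, OA = 1, SA = 0.2),
                         seed = 1)
  errs <- vapply(c(10, 100), function(ns) {
    fit <- mc_optimize(fp$pairs, mock_dock, samples_per_param = ns, seed = 51)
    median(abs(coef(fit) - fp$true_eps))
  }, 0)
  expect_lt(errs[2], errs[1])
})

test_that("fitted parameters round-trip through the parameter-table format", {
  lig <- place_dummy(make_toy_complex("Ru", 5, 0, seed = 1))
  pair <- list(ligand = lig, receptor = NULL, reference = coords(lig),
               box = docking_box(c(0, 0, 0), 8))
  fit <- mc_optimize(list(pair), toy_dock_fn, samples_per_param = 10, seed = 4)
  tf <- tempfile()
  write_fit_params(fit, tf)
  p <- load_params(tf, defaults = default_params("Ru"))
  for (t in c("HD", "NA", "OA", "SA")) {
    expect_equal(get_pair(p, "Ru", t)$eps, unname(round(coef(fit)[t], 4)))
  }
})
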
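# Genetic-algorithm pose search over rigid translation, orientation and
# torsions within a user box, with Solis-Wets local refinement.
#
# A genome is a numeric vector c(tx, ty, tz, qw, qx, qy, qz, torsions...):
# the root atom is placed at (tx, ty, tz), the whole ligand is rotated
# about the root by the unit quaternion, and each torsion angle (radians)
# rotates its distal subtree about its bond axis.

#' Define a docking box
#'
#' @param center 3-vector, Angstrom.
#' @param size edge lengths, 3-vector or scalar, Angstrom (default 20).
#' @return a `docking_box`.
#' @export
docking_box <- function(center, size = 20) {
  center <- as.numeric(center)
  size <- rep_len(as.numeric(size), 3L)
  stopifnot(length(center) == 3, all(size > 0))
  structure(list(center = center, size = size), class = "docking_box")
}

#' Draw a random genome
#'
#' Translation uniform in the box, orientation uniform on the rotation
#' group (normalized 4-normal-deviate quaternion), torsions uniform in
#' [-pi, pi). Uses R's RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param ligand `mc_ligand` with a torsion tree.
#' @param box a `docking_box`.
#' @return numeric genome vector.
#' @export
randomize_genome <- function(ligand, box) {
  k <- n_torsions(ligand)
  tr <- box$center + (stats::runif(3) - 0.5) * box$size
  q <- random_quat()
  tors <- if (k) stats::runif(k, -pi, pi) else numeric(0)
  c(tr, q, tors)
}

#' Ligand coordinates for a genome
#'
#' @param ligand `mc_ligand` with a torsion tree (defines the input
#'   conformer and rotatable bonds).
#' @param genome numeric vector (translation, quaternion, torsions).
#' @return n x 3 coordinate matrix.
#' @export
apply_genome <- function(ligand, genome) {
  tt <- ligand$torsion_tree
  if (is.null(tt)) stop("ligand has no torsion tree")
  .apply_genome_xyz(coords(ligand), tt, genome)
}

# Internal fast path: conformer coordinates already extracted as a matrix.
.apply_genome_xyz <- function(xyz, tt, genome) {
  k <- length(tt$torsions)
  if (length(genome) != 7 + k) stop("genome length must be 7 + n_torsions")
  bonds <- if (k) do.call(rbind, lapply(tt$torsions, `[[`, "bond")) else
    matrix(integer(0), ncol = 2)
  storage.mode(bonds) <- "integer"
  moving <- lapply(tt$torsions, function(t) {
    as.integer(if (is.null(t$moving_sans_pivot))
      setdiff(t$moving, t$bond[2]) else t$moving_sans_pivot)
  })
  .apply_genome_cpp(xyz, bonds, moving, tt$root, genome)
}

# Quadratic out-of-box penalty on the root atom (keeps the fitness
# landscape informative instead of hard-rejecting).
.box_penalty <- function(tr, box, weight = 50) {
  exc <- pmax(abs(tr - box$center) - box$size / 2, 0)
  weight * sum(exc^2)
}

# Fitness = intermolecular energy + box penalty.
.genome_fitness <- function(ctx, xyz0, tt, box, genome, rep_cap = 0) {
  .context_total(ctx, .apply_genome_xyz(xyz0, tt, genome), rep_cap) +
    .box_penalty(genome[1:3], box)
}

#' Solis-Wets local search
#'
#' Stochastic hill descent on the genome: a Gaussian step (and its
#' negation) is tried each iteration; the step size expands after
#' successes and contracts after failures. The returned genome never has a
#' higher fitness than the input.
#'
#' @param genome start genome.
#' @param fitness_fn function(genome) -> scalar to minimize.
#' @param max_iter iterations (default 30).
#' @param rho initial step scale (default 0.3).
#' @param lb,ub optional per-gene bounds (used to keep quaternion genes
#'   sane); the quaternion block is renormalized each step.
#' @return list(genome, fitness).
#' @export
local_search <- function(genome, fitness_fn, max_iter = 30, rho = 0.3,
                         lb = NULL, ub = NULL) {
  g <- .normalize_quat_block(genome)
  f <- fitness_fn(g)
  succ <- 0; fail <- 0
  bias <- numeric(length(g))
  for (it in seq_len(max_iter)) {
    step <- stats::rnorm(length(g), 0, rho) + bias
    for (cand_step in list(step, -step)) {
      cand <- .normalize_quat_block(g + cand_step)
      fc <- fitness_fn(cand)
      if (fc < f) {
        g <- cand; f <- fc
        bias <- 0.4 * bias + 0.2 * cand_step
        succ <- succ + 1; fail <- 0
        break
      } else if (identical(cand_step, -step)) {
        fail <- fail + 1; succ <- 0; bias <- 0.5 * bias
      }
    }
    if (succ >= 4) { rho <- rho * 2; succ <- 0 }
    if (fail >= 4) { rho <- rho / 2; fail <- 0 }
    if (rho < 1e-4) break
  }
  list(genome = g, fitness = f)
}

.normalize_quat_block <- function(g) {
  q <- g[4:7]
  nq <- sqrt(sum(q * q))
  if (nq < 1e-12) q <- c(1, 0, 0, 0) else q <- q / nq
  g[4:7] <- q
  g
}

# Default GA configuration (desk scale). AutoDock-like presets are
# available via ga_config(preset = "autodock").
#' GA configuration
#' @param pop_size population size (default 50).
#' @param generations number of generations (default 100).
#' @param p_crossover two-point crossover probability (default 0.8).
#' @param p_mutation per-individual mutation probability (default 0.2).
#' @param sigma_translation,sigma_rotation,sigma_torsion Gaussian mutation
#'   scales: Angstrom, radians, radians (defaults 0.2 A, 5 degrees).
#' @param elitism elite count carried over unchanged (default 1).
#' @param ls_fraction fraction of the population refined by Solis-Wets
#'   local search each generation (default 0.1).
#' @param ls_iter local-search iterations (default 20).
#' @param soft_cap cap on the per-pair Lennard-Jones repulsion during the
#'   evolutionary search, kcal/mol (default 0.5; 0 disables). The pair
#'   potential is flattened inside the radius where its repulsion reaches
#'   the cap, which smears the narrow hydrogen-bond wells into wide
#'   funnels the population can find; every returned pose is re-refined
#'   and scored with the exact potential.
#' @param polish_iter iteration budget of the final exact-potential polish
#'   of each run's best genome (default 1500).
#' @param preset "desk" (the defaults) or "autodock" (population 150,
#'   heavier search).
#' @return list of settings.
#' @export
ga_config <- function(pop_size = 50, generations = 100, p_crossover = 0.8,
                      p_mutation = 0.2, sigma_translation = 0.2,
                      sigma_rotation = 5 * pi / 180,
                      sigma_torsion = 5 * pi / 180, elitism = 1,
                      ls_fraction = 0.1, ls_iter = 20, soft_cap = 0.5,
                      polish_iter = 1500, preset = "desk") {
  cfg <- list(pop_size = pop_size, generations = generations,
              p_crossover = p_crossover, p_mutation = p_mutation,
              sigma_translation = sigma_translation,
              sigma_rotation = sigma_rotation, sigma_torsion = sigma_torsion,
              elitism = elitism, ls_fraction = ls_fraction, ls_iter = ls_iter,
              soft_cap = soft_cap, polish_iter = polish_iter)
  if (preset == "autodock") {
    cfg$pop_size <- 150; cfg$generations <- 270
  }
  cfg
}

#' Genetic-algorithm docking
#'
#' `n_runs` independent GA runs, each from a freshly randomized population;
#' the best genome of each run becomes one pose, and poses are returned
#' sorted by energy. Fully reproducible for a given seed.
#'
#' @param ligand typed, charged `mc_ligand` with a torsion tree (place the
#'   vacancy dummy first if wanted).
#' @param receptor typed, charged `mc_receptor`.
#' @param params an `lj_params`.
#' @param box a `docking_box`.
#' @param n_runs number of runs / poses (default 10).
#' @param config GA settings from [ga_config()].
#' @param seed integer seed.
#' @return a `dock_result`: list of poses (`coords`, `energy`, `genome`),
#'   plus the inputs and per-run best-energy traces.
#' @export
ga_dock <- function(ligand, receptor, params, box, n_runs = 10,
                    config = ga_config(), seed = 1) {
  if (config$pop_size < 4) stop("population must be at least 4")
  ctx <- make_energy_context(ligand, receptor, params)
  xyz0 <- coords(ligand)
  tt <- ligand$torsion_tree
  fitness_fn <- function(g) .genome_fitness(ctx, xyz0, tt, box, g,
                                            rep_cap = config$soft_cap)
  exact_fn <- function(g) .genome_fitness(ctx, xyz0, tt, box, g)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  poses <- vector("list", n_runs)
  traces <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    set.seed((seed * 1000L + run) %% .Machine$integer.max)
    res <- .ga_run(ligand, box, fitness_fn, config)
    # final polish: step the repulsion back in, then minimize the exact
    # potential from the soft optimum. Optimization runs over an offset
    # from the current genome so the search is translation-invariant.
    g_cur <- res$genome
    step <- function(fn, maxit, reltol) {
      off_fn <- function(dg) fn(.normalize_quat_block(g_cur + dg))
      pol <- stats::optim(numeric(length(g_cur)), off_fn, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = reltol))
      list(g = .normalize_quat_block(g_cur + pol$par), value = pol$value)
    }
    mid_fn <- function(g) .genome_fitness(ctx, xyz0, tt, box, g, rep_cap = 20)
    p1 <- step(mid_fn, config$polish_iter %/% 2, 1e-9)
    if (is.finite(p1$value)) g_cur <- p1$g
    f_prev <- Inf
    for (rs in 1:3) {  # fresh-simplex restarts until converged
      p2 <- step(exact_fn, config$polish_iter, 1e-11)
      g_cur <- p2$g
      if (f_prev - p2$value < 1e-6) break
      f_prev <- p2$value
    }
    if (p2$value <= exact_fn(res$genome)) res$genome <- g_cur
    en <- context_energy(ctx, apply_genome(ligand, res$genome))$total
    poses[[run]] <- list(coords = apply_genome(ligand, res$genome),
                         energy = en, genome = res$genome, run = run)
    traces[[run]] <- res$trace
  }
  ord <- order(vapply(poses, `[[`, 0, "energy"))
  structure(list(poses = poses[ord], traces = traces,
                 ligand = ligand, receptor = receptor, box = box,
                 seed = seed, config = config),
            class = "dock_result")
}

.ga_run <- function(ligand, box, fitness_fn, cfg) {
  k <- n_torsions(ligand)
  pop <- lapply(seq_len(cfg$pop_size), function(i) randomize_genome(ligand, box))
  fit <- vapply(pop, fitness_fn, 0)
  if (!any(is.finite(fit))) stop("no finite-energy individual after initialization; try a larger box")
  trace <- numeric(cfg$generations)
  sig <- c(rep(cfg$sigma_translation, 3), rep(cfg$sigma_rotation / 2, 4),
           rep(cfg$sigma_torsion, k))
  for (gen in seq_len(cfg$generations)) {
    ord <- order(fit)
    pop <- pop[ord]; fit <- fit[ord]
    newpop <- pop[seq_len(cfg$elitism)]
    newfit <- fit[seq_len(cfg$elitism)]
    while (length(newpop) < cfg$pop_size) {
      p1 <- .tournament(fit); p2 <- .tournament(fit)
      child <- pop[[p1]]
      if (stats::runif(1) < cfg$p_crossover) {
        child <- .two_point_crossover(pop[[p1]], pop[[p2]])
      }
      if (stats::runif(1) < cfg$p_mutation) {
        child <- child + stats::rnorm(length(child), 0, sig)
      }
      child <- .normalize_quat_block(child)
      newpop[[length(newpop) + 1L]] <- child
    }
    pop <- newpop
    fit <- c(newfit, vapply(pop[-seq_len(cfg$elitism)], fitness_fn, 0))
    # local refinement of the current top fraction
    n_ls <- max(1L, floor(cfg$ls_fraction * cfg$pop_size))
    top <- order(fit)[seq_len(n_ls)]
    for (i in top) {
      ls <- local_search(pop[[i]], fitness_fn, max_iter = cfg$ls_iter)
      if (ls$fitness < fit[i]) { pop[[i]] <- ls$genome; fit[i] <- ls$fitness }
    }
    trace[gen] <- min(fit)
  }
  best <- which.min(fit)
  list(genome = pop[[best]], fitness = fit[best], trace = trace)
}

.tournament <- function(fit, k = 2L) {
  cand <- sample.int(length(fit), k)
  cand[which.min(fit[cand])]
}

.two_point_crossover <- function(a, b) {
  n <- length(a)
  cuts <- sort(sample.int(n + 1L, 2L) - 1L)
  if (cuts[1] == cuts[2]) return(a)
  mid <- (cuts[1] + 1L):cuts[2]
  a[mid] <- b[mid]
  a
}

#' @export
print.dock_result <- function(x, ...) {
  cat(sprintf("<dock_result> %d poses (seed %d)\n", length(x$poses), x$seed))
  e <- vapply(x$poses, `[[`, 0, "energy")
  cat(sprintf("  best %.3f kcal/mol, worst %.3f kcal/mol\n", min(e), max(e)))
  invisible(x)
}

#' @export
summary.dock_result <- function(object, reference = NULL, ...) {
  e <- vapply(object$poses, `[[`, 0, "energy")
  df <- data.frame(pose = seq_along(e), energy = e,
                   run = vapply(object$poses, `[[`, 0L, "run"))
  if (!is.null(reference)) {
    df$rmsd <- vapply(object$poses, function(p) {
      pose_rmsd(p$coords, reference, elements = object$ligand$atoms$element,
                dummy_index = object$ligand$dummy_index)
    }, 0)
  }
  df
}

#' Pose coordinate matrices of a docking result
#' @param result a `dock_result`.
#' @return list of n x 3 matrices, best energy first.
#' @export
pose_coords <- function(result) lapply(result$poses, `[[`, "coords")
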
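# Deterministic generators of toy metal complexes, typed-atom pockets with
# a planted pose, and parameter-fitting problems with a known optimum.
# Pockets are abstract shells of typed atoms, not real proteins: every
# contract they exercise depends only on atom types, charges and
# positions.

.IDEAL_GEOMETRIES <- list(
  `2` = rbind(c(0, 0, 1), c(0, 0, -1)),                                   # linear
  `3` = rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0)), # trigonal planar
  `4` = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)),          # square planar
  `5` = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, -1)), # square pyramidal, vacancy +z
  `6` = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))                                    # octahedral
)

#' Generate a toy metal complex
#'
#' Metal at the origin with a heteroleptic first sphere at ideal geometry
#' (linear, trigonal planar, square planar, square pyramidal with a +z
#' vacancy, or octahedral): amine-like N ligators carrying donor
#' hydrogens, plus one ether/oxo-like O and (from CN 4) one thioether-like
#' S, so that orientations of the complex are energetically
#' distinguishable in a pocket. An alkyl arm on the first ligator
#' supplies the requested number of rotatable bonds. Charges are chemically
#' plausible fractions summing to `formal_charge`. A tiny seeded
#' coordinate jitter distinguishes seeds.
#'
#' @param metal element symbol (default "Ru").
#' @param coordination_number 2-6.
#' @param n_torsions rotatable bonds in the arm, 0-10.
#' @param seed integer seed.
#' @param formal_charge total charge of the complex (default 0).
#' @param bond_length metal-ligator distance, Angstrom (default 2.1).
#' @param jitter coordinate noise, Angstrom (default 0.02).
#' @return a typed `mc_ligand` with its torsion tree built (no dummy).
#' @export
make_toy_complex <- function(metal = "Ru", coordination_number = 5,
                             n_torsions = 0, seed = 1, formal_charge = 0,
                             bond_length = 2.1, jitter = 0.02) {
  cn <- as.character(coordination_number)
  if (!cn %in% names(.IDEAL_GEOMETRIES)) {
    stop("coordination_number must be between 2 and 6")
  }
  if (n_torsions < 0 || n_torsions > 10) stop("n_torsions must be 0-10")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  uv <- .IDEAL_GEOMETRIES[[cn]]
  rows <- list(data.frame(element = metal, x = 0, y = 0, z = 0, charge = 0))
  add <- function(el, pos, q) {
    rows[[length(rows) + 1L]] <<- data.frame(element = el, x = pos[1],
                                             y = pos[2], z = pos[3], charge = q)
  }
  perp2 <- function(u) {
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p1 <- .unit(pracma_cross(u, ref))
    list(p1 = p1, p2 = .unit(pracma_cross(u, p1)))
  }
  lig_el <- c("N", "O", if (nrow(uv) >= 4) "S")
  lig_el <- c(lig_el, rep("N", nrow(uv) - length(lig_el)))
  lig_q <- c(N = -0.35, O = -0.40, S = -0.25)
  for (k in seq_len(nrow(uv))) {
    u <- uv[k, ]
    npos <- bond_length * u
    el_k <- lig_el[k]
    add(el_k, npos, lig_q[[el_k]])
    if (el_k != "N") next  # bare O/S ligators carry no hydrogens
    pp <- perp2(u)
    if (k == 1L && n_torsions > 0) {
      # one N-H on the side opposite the arm, then a zigzag alkyl arm:
      # n_torsions + 2 carbons give n_torsions rotatable C-C bonds (the
      # N-C bond is first-sphere rigid, the last carbon is terminal)
      add("H", npos + 1.01 * .unit(u - 1.3 * pp$p1), 0.125)
      m <- n_torsions + 2L
      w <- pp$p1   # zigzag lateral, away from the N-H side
      v <- pp$p2
      for (c in seq_len(m)) {
        cpos <- npos + (c * 1.253) * u + 0.43 * ((-1)^(c + 1)) * w
        add("C", cpos, -0.06)
        n_ch <- if (c == m) 3L else 2L
        for (h in seq_len(n_ch)) {
          hdir <- if (h == 1L) v else if (h == 2L) -v
          else .unit(u + 0.4 * ((-1)^(c + 1)) * w)
          add("H", cpos + 1.09 * hdir, 0.03)
        }
      }
    } else {
      for (s in c(1, -1)) add("H", npos + 1.01 * .unit(u + s * 1.3 * pp$p1), 0.125)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$charge[1] <- formal_charge - sum(atoms$charge[-1])
  xyz_jit <- matrix(stats::rnorm(3 * nrow(atoms), 0, jitter), ncol = 3)
  atoms$x <- atoms$x + xyz_jit[, 1]
  atoms$y <- atoms$y + xyz_jit[, 2]
  atoms$z <- atoms$z + xyz_jit[, 3]
  lig <- new_ligand(atoms)
  lig <- assign_types(lig)
  build_torsion_tree(lig)
}

#' Specify a toy pocket
#'
#' The default pocket is a cysteine-like site: a thiolate-like SA acceptor
#' faces the metal vacancy (the angular weighting through the vacancy
#' dummy also fixes the dummy direction) and a donor-hydrogen probe faces
#' the complex's unique O ligator; those two direction constraints pin
#' the orientation completely, because every other arrangement loses a
#' type-specific well. A neutral carbon cast of the planted ligand
#' surface adds dense shape complementarity: each cast atom sits at its
#' optimal pair distance from one solvent-facing ligand atom, so the
#' planted pose packs well everywhere while reoriented poses clash.
#'
#' @param metal,coordination_number,n_torsions passed to
#'   [make_toy_complex()].
#' @param acceptor_type receptor anchor type facing the metal vacancy: one
#'   of "OA", "NA", "SA", "HD" (default "SA").
#' @param box_size docking-box edge, Angstrom (default 12: the pocket
#'   extent plus clearance).
#' @param eps generating metal well depths, kcal/mol.
#' @return a `pocket_spec` list.
#' @export
pocket_spec <- function(metal = "Ru", coordination_number = 5, n_torsions = 1,
                        acceptor_type = "SA", box_size = 12,
                        eps = c(HD = 2, "NA" = 2, OA = 2, SA = 4)) {
  stopifnot(acceptor_type %in% c("OA", "NA", "SA", "HD"))
  structure(list(metal = metal, coordination_number = coordination_number,
                 n_torsions = n_torsions, acceptor_type = acceptor_type,
                 box_size = box_size, eps = eps), class = "pocket_spec")
}

.anchor_element <- c(OA = "O", "NA" = "N", SA = "S", HD = "H")

#' Generate a pocket with a planted pose
#'
#' Builds a toy complex, applies a seeded random rigid orientation, places
#' the vacancy dummy, and surrounds the planted pose with a typed-atom
#' pocket: one acceptor of `acceptor_type` exactly at the pair's rmin from
#' the metal along the vacancy axis, a donor-hydrogen probe at the O
#' ligator, and a neutral carbon cast of the ligand surface. The
#' idealized planted pose is then relaxed to its
#' local energy minimum (the returned reference), which is checked to
#' score below `check_n` random poses under the generating parameters.
#'
#' @param spec a [pocket_spec()].
#' @param seed integer seed.
#' @param check_n random poses for the generation-time optimality check
#'   (default 2000; 0 disables).
#' @return list with `ligand` (planted conformer, dummy placed),
#'   `receptor`, `reference` (planted coordinates), `box`, `params`
#'   (generating parameter set), and `planted_energy`.
#' @export
make_pocket <- function(spec = pocket_spec(), seed = 1, check_n = 2000) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  lig <- make_toy_complex(spec$metal, spec$coordination_number,
                         spec$n_torsions, seed = seed)
  set.seed(seed + 77L)
  R <- random_rotation()
  lig <- set_coords(lig, coords(lig) %*% t(R))
  lig <- place_dummy(lig)
  params <- set_metal_eps(default_params(spec$metal), spec$eps)
  xyz <- coords(lig)
  m <- lig$metal_index
  mpos <- xyz[m, ]
  vdir <- .unit(xyz[lig$dummy_index, ] - mpos)
  arec <- get_pair(params, spec$metal, spec$acceptor_type)
  racc <- list(data.frame(
    element = .anchor_element[[spec$acceptor_type]],
    x = mpos[1] + arec$rmin * vdir[1], y = mpos[2] + arec$rmin * vdir[2],
    z = mpos[3] + arec$rmin * vdir[3],
    charge = -0.5, ad_type = spec$acceptor_type))
  # type-specific orientation pin: a donor-hydrogen probe facing the
  # ligand's unique O ligator (strong HD-OA well); with the metal-axis
  # acceptor and its angular weighting this fixes the full orientation
  o_lig <- which(lig$atoms$ad_type == "OA")
  if (length(o_lig)) {
    op <- xyz[o_lig[1], ]
    hbo <- get_pair(params, "HD", "OA")
    pp <- op + hbo$rmin * .unit(op - mpos)
    if (min(sqrt(rowSums(sweep(xyz, 2, pp)^2)[-o_lig[1]])) > 2.3) {
      racc[[length(racc) + 1L]] <- data.frame(
        element = "H", x = pp[1], y = pp[2], z = pp[3],
        charge = 0.35, ad_type = "HD")
    }
  }
  # a second, weaker donor probe on the unique S ligator breaks the
  # remaining rotational pseudo-symmetry of the N ligators
  s_lig <- setdiff(which(lig$atoms$ad_type == "SA"), lig$metal_index)
  if (length(s_lig)) {
    sp <- xyz[s_lig[1], ]
    hbs <- get_pair(params, "HD", "SA")
    pp <- sp + hbs$rmin * .unit(sp - mpos)
    if (min(sqrt(rowSums(sweep(xyz, 2, pp)^2)[-s_lig[1]])) > 2.3) {
      racc[[length(racc) + 1L]] <- data.frame(
        element = "H", x = pp[1], y = pp[2], z = pp[3],
        charge = 0.30, ad_type = "HD")
    }
  }

  # neutral carbon cast: one probe atom outside each solvent-facing
  # ligand atom at the optimal pair distance -- dense shape
  # complementarity that rewards the planted pose in every direction and
  # clashes with reoriented poses
  anchors <- do.call(rbind, racc)
  placed <- as.matrix(anchors[, c("x", "y", "z")])
  centroid <- colMeans(xyz[-lig$dummy_index, , drop = FALSE])
  rm_all <- vapply(lig$atoms$ad_type, function(t2) {
    if (t2 == "DD") 0 else get_pair(params, "C", t2)$rmin
  }, 0)
  shell <- list()
  ord <- order(-sqrt(rowSums(sweep(xyz, 2, centroid)^2)))  # outermost first
  for (i in ord) {
    if (i == lig$dummy_index || i == m) next
    u <- .unit(xyz[i, ] - centroid)
    p <- xyz[i, ] + rm_all[i] * u
    d_all <- sqrt(rowSums(sweep(xyz, 2, p)^2))
    ok <- all(d_all[-i] > rm_all[-i] - 0.2) &&
      (!nrow(placed) || all(sqrt(rowSums(sweep(placed, 2, p)^2)) > 2.2))
    if (ok) {
      shell[[length(shell) + 1L]] <- p
      placed <- rbind(placed, p)
    }
  }
  shell_df <- if (length(shell)) {
    sm <- do.call(rbind, shell)
    data.frame(element = "C", x = sm[, 1], y = sm[, 2], z = sm[, 3],
               charge = 0, ad_type = "C")
  } else NULL
  ratoms <- rbind(anchors, shell_df)
  rownames(ratoms) <- NULL
  receptor <- structure(list(atoms = ratoms, source_resolution = NA_real_),
                        class = "mc_receptor")
  box <- docking_box(mpos, spec$box_size)
  ctx <- make_energy_context(lig, receptor, params)
  # relax the idealized planted pose to its local minimum; the relaxed
  # pose is the reference the pose search is expected to recover
  tt <- lig$torsion_tree
  g0 <- c(xyz[tt$root, ], 1, 0, 0, 0, rep(0, length(tt$torsions)))
  fit_fn <- function(g) .genome_fitness(ctx, xyz, tt, box, g)
  opt <- stats::optim(g0, fit_fn, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  reference <- .apply_genome_xyz(xyz, tt, opt$par)
  planted_energy <- context_energy(ctx, reference)$total
  if (check_n > 0) {
    set.seed(seed + 101L)
    for (k in seq_len(check_n)) {
      g <- randomize_genome(lig, box)
      if (context_energy(ctx, apply_genome(lig, g))$total <= planted_energy) {
        stop("pocket generation failed: a random pose scored below the planted pose")
      }
    }
  }
  list(ligand = lig, receptor = receptor, reference = reference, box = box,
       params = params, planted_energy = planted_energy, spec = spec,
       seed = seed)
}

# ---------------------------------------------------------------------------
# Parameter-fitting problems with a known optimum

#' Generate a parameter-recovery fitting problem
#'
#' `n_pairs` minimal pockets, cycling over the four metal interactions
#' (HD, NA, OA, SA). Each pocket holds the complex in a stiff neutral
#' carbon cage (a cast of the ligand surface) and places one acceptor of
#' the pair's type on the vacancy axis, displaced 0.6 Angstrom beyond the
#' pair's optimal distance. The docked position balances the
#' epsilon-dependent pull toward the acceptor against the cage walls, so
#' the pose shifts smoothly and monotonically with epsilon. Each pair's
#' reference pose is the energy minimum under `true_eps`, which makes the
#' mean-RMSD objective minimal at `true_eps` by construction.
#'
#' @param true_eps named well depths (HD, NA, OA, SA) in (0, 7) kcal/mol.
#' @param n_pairs number of training pairs (default 4, one per type).
#' @param seed integer seed.
#' @param metal element symbol (default "Ru").
#' @return list with `pairs` (training set for [mc_optimize()]), `true_eps`
#'   and `metal`.
#' @export
make_fit_problem <- function(true_eps = c(HD = 5.6, "NA" = 2, OA = 1, SA = 0.2),
                             n_pairs = 4, seed = 1, metal = "Ru") {
  stopifnot(all(c("HD", "NA", "OA", "SA") %in% names(true_eps)),
            all(true_eps > 0 & true_eps < 7))
  types <- rep(c("HD", "NA", "OA", "SA"), length.out = n_pairs)
  params_true <- set_metal_eps(default_params(metal), true_eps)
  pairs <- lapply(seq_len(n_pairs), function(k) {
    t <- types[k]
    lig <- make_toy_complex(metal, coordination_number = 5, n_torsions = 0,
                           seed = seed + k, jitter = 0.01)
    lig <- place_dummy(lig)
    xyz <- coords(lig)
    mpos <- xyz[lig$metal_index, ]
    vdir <- .unit(xyz[lig$dummy_index, ] - mpos)
    rec <- get_pair(params_true, metal, t)
    acc <- mpos + (rec$rmin + 0.6) * vdir
    ratoms <- list(data.frame(
      element = .anchor_element[[t]], x = acc[1], y = acc[2], z = acc[3],
      charge = -0.4, ad_type = t))
    # stiff neutral cage: cast probes at the optimal pair distance outside
    # each ligand atom
    rm_all <- vapply(lig$atoms$ad_type, function(t2) {
      if (t2 == "DD") 0 else get_pair(params_true, "C", t2)$rmin
    }, 0)
    centroid <- colMeans(xyz[-lig$dummy_index, , drop = FALSE])
    placed <- matrix(acc, 1, 3)
    for (i in seq_len(nrow(xyz))) {
      if (i %in% c(lig$dummy_index, lig$metal_index)) next
      u <- xyz[i, ] - centroid
      if (.vnorm(u) < 1e-6) next
      p <- xyz[i, ] + rm_all[i] * .unit(u)
      d_all <- sqrt(rowSums(sweep(xyz, 2, p)^2))
      ok <- all(d_all[-i] > rm_all[-i] - 0.2) &&
        all(sqrt(rowSums(sweep(placed, 2, p)^2)) > 2.2)
      if (ok) {
        ratoms[[length(ratoms) + 1L]] <- data.frame(
          element = "C", x = p[1], y = p[2], z = p[3], charge = 0,
          ad_type = "C")
        placed <- rbind(placed, p)
      }
    }
    ratoms <- do.call(rbind, ratoms)
    rownames(ratoms) <- NULL
    receptor <- structure(list(atoms = ratoms, source_resolution = NA_real_),
                          class = "mc_receptor")
    box <- docking_box(mpos, 8)
    # reference = minimized pose under the true parameters
    ref_res <- mock_dock(lig, receptor, params_true, box, seed = 0, jitter = 0)
    list(ligand = lig, receptor = receptor,
         reference = ref_res$poses[[1]]$coords, box = box, type = t)
  })
  list(pairs = pairs, true_eps = true_eps[c("HD", "NA", "OA", "SA")],
       metal = metal, seed = seed)
}

#' Mock-energy docking by rigid local minimization
#'
#' A fast stand-in for [ga_dock()] with the same calling convention: the
#' ligand is translated rigidly from its stored conformer position to the
#' nearest energy minimum (Nelder-Mead on the three translation degrees of
#' freedom). A tiny seeded jitter of the start point provides the
#' stochasticity the fitting audit trail records; the minimization
#' re-converges to the same basin, so results are reproducible. Intended
#' for parameter-fitting surrogates and tests, not for pose search.
#'
#' @param ligand,receptor,params,box as in [ga_dock()] (`box` unused
#'   beyond its presence in the contract).
#' @param seed integer seed for the start jitter.
#' @param jitter start-point noise, Angstrom (default 0.01).
#' @return a minimal `dock_result` with one pose.
#' @export
mock_dock <- function(ligand, receptor, params, box, seed = 1, jitter = 0.01) {
  ctx <- make_energy_context(ligand, receptor, params)
  xyz0 <- coords(ligand)
  fn <- function(d) {
    context_energy(ctx, sweep(xyz0, 2, d, "+"))$total
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed %% .Machine$integer.max)
  start <- if (jitter > 0) stats::rnorm(3, 0, jitter) else c(0, 0, 0)
  # quasi-Newton descent, then a simplex refinement for endpoint precision
  opt <- stats::optim(start, fn, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 200))
  opt <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 300))
  pose <- sweep(xyz0, 2, opt$par, "+")
  structure(list(poses = list(list(coords = pose, energy = opt$value,
                                   genome = NULL, run = 1L)),
                 ligand = ligand, receptor = receptor, box = box, seed = seed),
            class = "dock_result")
}

#' Write fixture files to a directory
#'
#' Writes the ligand (extended XYZ and PDBQT), receptor (PDBQT), reference
#' coordinates (XYZ) and a tab-separated manifest usable by the
#' command-line `fit-params` entry point.
#'
#' @param pairs list of training pairs (as from [make_fit_problem()]$pairs
#'   or a list of [make_pocket()] results).
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_fixture_files <- function(pairs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    lp <- file.path(dir, sprintf("ligand_%02d.xyz", k))
    lq <- file.path(dir, sprintf("ligand_%02d.pdbqt", k))
    rp <- file.path(dir, sprintf("receptor_%02d.pdbqt", k))
    fp <- file.path(dir, sprintf("reference_%02d.xyz", k))
    write_xyz(p$ligand, lp)
    write_pdbqt(p$ligand, lq)
    write_pdbqt(p$receptor, rp)
    ref <- p$reference
    reflig <- set_coords(p$ligand, ref)
    write_xyz(reflig, fp)
    data.frame(ligand = lp, receptor = rp, reference = fp,
               center_x = p$box$center[1], center_y = p$box$center[2],
               center_z = p$box$center[3], size_x = p$box$size[1],
               size_y = p$box$size[2], size_z = p$box$size[3])
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mf)
}
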
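# Pairwise intermolecular scoring: Lennard-Jones 12-6 / 12-10 terms with
# metal-specific parameters, screened Coulomb electrostatics, and angular
# weighting of the metal hydrogen-bond-like wells via the vacancy dummy.

COULOMB_K <- 332.06  # kcal mol^-1 A e^-2

#' Lennard-Jones pair energy
#'
#' Two functional forms, both with minimum value -epsilon at r = rmin:
#' (12,6): eps * ((rmin/r)^12 - 2 (rmin/r)^6) for generic van der Waals
#' contacts; (12,10): eps * (5 (rmin/r)^12 - 6 (rmin/r)^10), the narrower
#' hydrogen-bond-like well used for metal-NA/OA/SA and donor-acceptor
#' pairs.
#'
#' @param r distance(s), Angstrom; must be > 0.
#' @param eps well depth, kcal/mol.
#' @param rmin position of the minimum, Angstrom.
#' @param exponents integer pair, `c(12, 6)` or `c(12, 10)`.
#' @return energy in kcal/mol (vectorized over `r`).
#' @export
lj_energy <- function(r, eps, rmin, exponents = c(12, 6)) {
  if (any(r <= 0)) stop("r must be > 0")
  x <- rmin / r
  if (identical(as.integer(exponents), c(12L, 6L))) {
    eps * (x^12 - 2 * x^6)
  } else if (identical(as.integer(exponents), c(12L, 10L))) {
    eps * (5 * x^12 - 6 * x^10)
  } else {
    stop("exponents must be c(12, 6) or c(12, 10)")
  }
}

#' Screened Coulomb pair energy
#'
#' 332.06 q_i q_j / (eps(r) r) with the Mehler-Solmajer sigmoidal
#' distance-dependent dielectric.
#'
#' @param qi,qj partial charges, elementary units.
#' @param r distance(s), Angstrom; must be > 0.
#' @return energy in kcal/mol (vectorized over `r`).
#' @export
electrostatic_energy <- function(qi, qj, r) {
  if (any(r <= 0)) stop("r must be > 0")
  COULOMB_K * qi * qj / (.ms_dielectric(r) * r)
}

# Mehler-Solmajer eps(r) = A + B / (1 + k exp(-lambda B r)), eps(inf)=78.4.
.ms_dielectric <- function(r) {
  A <- -8.5525; B <- 78.4 - A; lam <- 0.003627; k <- 7.7839
  A + B / (1 + k * exp(-lam * B * r))
}

#' Angular weight of the metal hydrogen-bond term
#'
#' cos^2(theta) for theta the angle between the metal-to-dummy and
#' metal-to-acceptor directions, zero beyond 90 degrees. Multiplies only
#' the attractive well of the metal-NA/OA/SA 12-10 terms; without a dummy
#' the interaction is isotropic (weight 1).
#'
#' @param metal_pos,dummy_pos,acceptor_pos 3-vectors, Angstrom.
#' @return scalar in [0, 1].
#' @export
hbond_weight <- function(metal_pos, dummy_pos, acceptor_pos) {
  u <- .unit(dummy_pos - metal_pos)
  v <- .unit(acceptor_pos - metal_pos)
  ct <- sum(u * v)
  if (ct <= 0) 0 else ct^2
}

# ---------------------------------------------------------------------------
# Parameter sets

# AutoDock4-style self parameters: Rii (A, = rmin of the like pair) and
# epsii (kcal/mol).
.SELF_PARAMS <- list(
  C  = c(4.00, 0.150), A  = c(4.00, 0.150), N  = c(3.50, 0.160),
  "NA" = c(3.50, 0.160), OA = c(3.20, 0.200), SA = c(4.00, 0.200),
  HD = c(2.00, 0.020), H  = c(2.00, 0.020)
)
# Donor-acceptor hydrogen-bond pairs (12,10): rmin, eps.
.HB_PAIRS <- list(
  "HD|NA" = c(1.90, 5.00), "HD|OA" = c(1.90, 5.00), "HD|SA" = c(2.50, 1.00)
)
# Printed metal rmin values (A) for the four fitted interactions.
METAL_RMIN <- c(HD = 1.00, "NA" = 2.20, OA = 2.25, SA = 2.30)
METAL_METAL_EPS <- 0.010  # kcal/mol, iron-like, held fixed
.METAL_SELF_RMIN <- 1.30  # iron-like Rii for metal vdW combinations

.pair_key <- function(ti, tj) paste(sort(c(ti, tj)), collapse = "|")

#' Default Lennard-Jones parameter set
#'
#' Non-metal pairs come from AutoDock4-style self parameters combined by
#' arithmetic-mean rmin and geometric-mean eps, with 12-10 donor-acceptor
#' hydrogen-bond pairs. Metal pairs use the fixed rmin values (HD 1.00,
#' NA 2.20, OA 2.25, SA 2.30 Angstrom), exponents (12,6) for HD and (12,10)
#' for NA/OA/SA, well depths `metal_eps` (placeholder 2.0 kcal/mol until
#' fitted), and metal-metal eps fixed at 0.010 kcal/mol.
#'
#' @param metal element symbol of the metal type to parametrize (e.g. "Ru").
#' @param metal_eps named numeric, well depths for HD/NA/OA/SA in kcal/mol.
#' @return an `lj_params` object (named list of pair records).
#' @export
default_params <- function(metal = "Ru",
                           metal_eps = c(HD = 2, "NA" = 2, OA = 2, SA = 2)) {
  stopifnot(all(c("HD", "NA", "OA", "SA") %in% names(metal_eps)))
  p <- list()
  types <- names(.SELF_PARAMS)
  for (i in seq_along(types)) for (j in i:length(types)) {
    ti <- types[i]; tj <- types[j]
    key <- .pair_key(ti, tj)
    hb <- .HB_PAIRS[[key]]
    if (!is.null(hb)) {
      p[[key]] <- list(eps = hb[2], rmin = hb[1], exponents = c(12L, 10L))
    } else {
      si <- .SELF_PARAMS[[ti]]; sj <- .SELF_PARAMS[[tj]]
      p[[key]] <- list(eps = sqrt(si[2] * sj[2]), rmin = (si[1] + sj[1]) / 2,
                       exponents = c(12L, 6L))
    }
  }
  for (t in c("HD", "NA", "OA", "SA")) {
    p[[.pair_key(metal, t)]] <- list(
      eps = unname(metal_eps[t]), rmin = unname(METAL_RMIN[t]),
      exponents = if (t == "HD") c(12L, 6L) else c(12L, 10L))
  }
  # metal vdW with remaining organic types, iron-like self parameters
  for (t in c("C", "A", "N", "H")) {
    si <- .SELF_PARAMS[[t]]
    p[[.pair_key(metal, t)]] <- list(
      eps = sqrt(METAL_METAL_EPS * si[2]),
      rmin = (.METAL_SELF_RMIN + si[1]) / 2, exponents = c(12L, 6L))
  }
  p[[.pair_key(metal, metal)]] <- list(eps = METAL_METAL_EPS,
                                       rmin = .METAL_SELF_RMIN,
                                       exponents = c(12L, 6L))
  structure(list(pairs = p, metal = metal), class = "lj_params")
}

#' Load a Lennard-Jones parameter table
#'
#' Plain-text, whitespace-separated lines `TYPE_I TYPE_J EPS RMIN EXP`
#' with `EXP` one of `12-6` / `12-10` (a comma is accepted too); `#` starts
#' a comment. Lines override the defaults pair by pair.
#'
#' @param path path to the table, or NULL for pure defaults.
#' @param defaults an `lj_params` to override (default [default_params()]).
#' @return an `lj_params`.
#' @export
load_params <- function(path = NULL, defaults = default_params()) {
  p <- defaults
  if (is.null(path)) return(p)
  lines <- readLines(path)
  for (ln in seq_along(lines)) {
    s <- sub("#.*", "", lines[ln])
    s <- trimws(s)
    if (s == "") next
    tok <- strsplit(s, "\\s+")[[1]]
    if (length(tok) != 5) stop(sprintf("line %d: expected 5 fields, got %d", ln, length(tok)))
    eps <- as.numeric(tok[3]); rmin <- as.numeric(tok[4])
    if (is.na(eps) || eps < 0) stop(sprintf("line %d: invalid eps '%s'", ln, tok[3]))
    if (is.na(rmin) || rmin <= 0) stop(sprintf("line %d: invalid rmin '%s'", ln, tok[4]))
    ex <- as.integer(strsplit(tok[5], "[-,]")[[1]])
    if (length(ex) != 2 || !identical(ex[1], 12L) || !(ex[2] %in% c(6L, 10L))) {
      stop(sprintf("line %d: exponents must be 12-6 or 12-10", ln))
    }
    p$pairs[[.pair_key(tok[1], tok[2])]] <-
      list(eps = eps, rmin = rmin, exponents = ex)
  }
  p
}

#' Look up the parameters of a type pair
#' @param params an `lj_params`.
#' @param ti,tj atom types.
#' @return list with `eps`, `rmin`, `exponents`.
#' @export
get_pair <- function(params, ti, tj) {
  rec <- params$pairs[[.pair_key(ti, tj)]]
  if (is.null(rec)) stop(sprintf("no parameters for type pair %s-%s", ti, tj))
  rec
}

#' Set the four metal well depths of a parameter set
#' @param params an `lj_params`.
#' @param eps named numeric with entries HD, NA, OA, SA (kcal/mol).
#' @return the updated `lj_params`.
#' @export
set_metal_eps <- function(params, eps) {
  for (t in c("HD", "NA", "OA", "SA")) {
    if (!is.null(eps[t]) && !is.na(eps[t])) {
      key <- .pair_key(params$metal, t)
      params$pairs[[key]]$eps <- unname(eps[t])
    }
  }
  params
}

#' @export
print.lj_params <- function(x, ...) {
  cat(sprintf("<lj_params> metal %s, %d type pairs\n", x$metal, length(x$pairs)))
  for (t in c("HD", "NA", "OA", "SA")) {
    rec <- x$pairs[[.pair_key(x$metal, t)]]
    cat(sprintf("  %s-%-2s eps %6.3f kcal/mol  rmin %4.2f A  (%d,%d)\n",
                x$metal, t, rec$eps, rec$rmin, rec$exponents[1], rec$exponents[2]))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Intermolecular energy

# Precompute per-pair parameter matrices for fast pose evaluation.
# Dummy atoms carry no direct energy; they only orient the metal wells.
make_energy_context <- function(ligand, receptor, params,
                                lj_cutoff = 8, elec_cutoff = 20) {
  lt <- ligand$atoms$ad_type; rt <- receptor$atoms$ad_type
  if (any(is.na(lt)) || any(is.na(rt))) stop("untyped atoms; run assign_types")
  nl <- length(lt); nr <- length(rt)
  keep_l <- which(lt != "DD")
  eps <- rmin <- matrix(0, nl, nr)
  att10 <- matrix(FALSE, nl, nr)   # TRUE -> 12-10 form
  hb_metal <- matrix(FALSE, nl, nr)
  for (i in keep_l) for (tj in unique(rt)) {
    rec <- get_pair(params, lt[i], tj)
    cols <- which(rt == tj)
    eps[i, cols] <- rec$eps
    rmin[i, cols] <- rec$rmin
    att10[i, cols] <- rec$exponents[2] == 10L
    if (!is.na(ligand$metal_index) && i == ligand$metal_index &&
        tj %in% c("NA", "OA", "SA")) {
      hb_metal[i, cols] <- TRUE
    }
  }
  qq <- outer(ligand$atoms$charge, receptor$atoms$charge)
  qq[setdiff(seq_len(nl), keep_l), ] <- 0
  m10 <- att10 * 1L
  rep_c <- eps * (1 + 4 * m10)   # 5 eps for 12-10, eps for 12-6
  att_c <- eps * (2 + 4 * m10)   # 6 eps for 12-10, 2 eps for 12-6
  storage.mode(m10) <- "integer"
  hbi <- hb_metal * 1L
  storage.mode(hbi) <- "integer"
  list(ligand = ligand, receptor = receptor,
       rxyz = coords(receptor), eps = eps, rmin = rmin, att10 = att10,
       m10 = m10, rep_c = rep_c, att_c = att_c,
       hb_metal = hb_metal, hbi = hbi, qq = qq,
       metal = ligand$metal_index, dummy = ligand$dummy_index,
       metal0 = if (is.na(ligand$metal_index)) -1L else ligand$metal_index - 1L,
       dummy0 = if (is.na(ligand$dummy_index)) -1L else ligand$dummy_index - 1L,
       lj_cutoff = lj_cutoff, elec_cutoff = elec_cutoff)
}

# Total energy only (hot path for the pose search). rep_cap > 0 caps the
# per-pair repulsion (soft-core landscape for global search); 0 is exact.
.context_total <- function(ctx, lxyz, rep_cap = 0) {
  .pose_energy_cpp(lxyz, ctx$rxyz, ctx$rmin, ctx$rep_c, ctx$att_c, ctx$m10,
                   ctx$hbi, ctx$qq, ctx$metal0, ctx$dummy0,
                   ctx$lj_cutoff, ctx$elec_cutoff, rep_cap)[4]
}

# Energy breakdown for ligand coordinates `lxyz` under a context.
context_energy <- function(ctx, lxyz) {
  e <- .pose_energy_cpp(lxyz, ctx$rxyz, ctx$rmin, ctx$rep_c, ctx$att_c,
                        ctx$m10, ctx$hbi, ctx$qq, ctx$metal0, ctx$dummy0,
                        ctx$lj_cutoff, ctx$elec_cutoff)
  structure(list(vdw = e[1], hbond_metal = e[2], electrostatic = e[3],
                 total = e[4]), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("vdW %10.4f  metal-HB %10.4f  elec %10.4f  total %10.4f kcal/mol\n",
              x$vdw, x$hbond_metal, x$electrostatic, x$total))
  invisible(x)
}

#' Intermolecular ligand-receptor energy
#'
#' Sum over all ligand-receptor atom pairs of the Lennard-Jones terms
#' (12-6, or 12-10 for hydrogen-bond-like pairs, with the metal acceptor
#' wells angularly weighted through the vacancy dummy) plus screened
#' Coulomb electrostatics. Dummy atoms contribute no direct energy.
#'
#' @param ligand typed, charged `mc_ligand` (its stored coordinates are the
#'   pose unless `pose_coords` is given).
#' @param receptor typed, charged `mc_receptor`.
#' @param params an `lj_params`.
#' @param lj_cutoff,elec_cutoff truncation distances, Angstrom (defaults 8
#'   and 20).
#' @param pose_coords optional n x 3 matrix of ligand coordinates.
#' @return an `energy_breakdown` with components `vdw`, `hbond_metal`,
#'   `electrostatic`, `total` (kcal/mol).
#' @export
intermolecular_energy <- function(ligand, receptor, params,
                                  lj_cutoff = 8, elec_cutoff = 20,
                                  pose_coords = NULL) {
  ctx <- make_energy_context(ligand, receptor, params, lj_cutoff, elec_cutoff)
  lxyz <- if (is.null(pose_coords)) coords(ligand) else pose_coords
  context_energy(ctx, lxyz)
}
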
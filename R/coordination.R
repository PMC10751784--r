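# First coordination sphere detection and vacancy dummy-atom placement.
#
# Metals are treated as hydrogen-bond donors: a zero-charge, zero-parameter
# dummy pseudo-atom at the vacant coordination site marks the direction
# along which a protein acceptor is expected to coordinate.

#' Detect the metal's first coordination sphere
#'
#' Ligating atoms are the non-hydrogen, non-dummy atoms within the dative
#' bond cutoff (1.25 x sum of covalent radii) of the metal, sorted by
#' distance.
#'
#' @param ligand an `mc_ligand` containing a metal atom.
#' @return a `coordination_sphere`: list with `metal_index`,
#'   `ligating_atom_indices`, `coordination_number`, and
#'   `ligand_unit_vectors` (rows = metal-to-ligator unit vectors).
#' @export
detect_sphere <- function(ligand) {
  m <- ligand$metal_index
  if (is.na(m)) stop("ligand has no metal atom")
  xyz <- coords(ligand)
  el <- ligand$atoms$element
  cand <- setdiff(which(el != "H" & el != "DD"), m)
  d <- sqrt(rowSums((xyz[cand, , drop = FALSE] -
                       matrix(xyz[m, ], length(cand), 3, byrow = TRUE))^2))
  cut <- 1.25 * (covalent_radius(el[m]) + covalent_radius(el[cand]))
  lig <- cand[d < cut]
  dl <- d[d < cut]
  ord <- order(dl)
  lig <- lig[ord]; dl <- dl[ord]
  cn <- length(lig)
  if (cn == 0) stop("coordination number 0: no atoms within the dative cutoff")
  if (cn > 6) {
    stop(sprintf("coordination number %d > 6; distances: %s", cn,
                 paste(sprintf("%.2f", dl), collapse = ", ")))
  }
  uv <- t(vapply(lig, function(i) .unit(xyz[i, ] - xyz[m, ]), numeric(3)))
  structure(list(metal_index = m, ligating_atom_indices = lig,
                 coordination_number = cn, ligand_unit_vectors = uv),
            class = "coordination_sphere")
}

#' @export
print.coordination_sphere <- function(x, ...) {
  cat(sprintf("<coordination_sphere> CN = %d (metal atom %d; ligators %s)\n",
              x$coordination_number, x$metal_index,
              paste(x$ligating_atom_indices, collapse = ", ")))
  invisible(x)
}

#' Place the vacancy dummy atom
#'
#' The dummy goes along the negated, normalized sum of the metal-to-ligator
#' unit vectors, at `bond_length` from the metal. When the sphere is
#' geometrically balanced (||sum|| < 0.2, e.g. square planar or octahedral)
#' the direction falls back to the best-fit-plane normal of the ligators,
#' pointing into the half-space containing fewer ligand atoms; an exact tie
#' takes the orientation whose first non-zero component is positive.
#'
#' @param ligand an `mc_ligand`.
#' @param sphere a `coordination_sphere` from [detect_sphere()]; computed
#'   when NULL.
#' @param bond_length metal-dummy distance in Angstrom (default 2.0, a
#'   typical first-sphere bond length).
#' @return the ligand with one zero-charge DD atom appended (bonded to the
#'   metal only). Idempotent: a ligand that already has a dummy is returned
#'   unchanged.
#' @export
place_dummy <- function(ligand, sphere = NULL, bond_length = 2.0) {
  if (!is.na(ligand$dummy_index)) return(ligand)
  if (is.null(sphere)) sphere <- detect_sphere(ligand)
  xyz <- coords(ligand)
  m <- sphere$metal_index
  s <- colSums(sphere$ligand_unit_vectors)
  if (.vnorm(s) >= 0.2) {
    v <- .unit(-s)
  } else {
    if (sphere$coordination_number == 6) {
      stop("coordination sphere is saturated and balanced (CN = 6); ",
           "no vacancy to mark - set vacant_site = FALSE")
    }
    v <- .plane_normal_direction(ligand, sphere, xyz)
  }
  pos <- xyz[m, ] + bond_length * v
  dummy <- data.frame(element = "DD", x = pos[1], y = pos[2], z = pos[3],
                      charge = 0, ad_type = "DD")
  a <- ligand$atoms
  for (col in setdiff(names(a), names(dummy))) dummy[[col]] <- NA
  ligand$atoms <- rbind(a, dummy[, names(a)])
  di <- nrow(ligand$atoms)
  ligand$dummy_index <- di
  ligand$bonds <- .check_bonds(rbind(ligand$bonds, c(m, di)), di)
  ligand
}

# Best-fit-plane normal of the ligator unit vectors, oriented toward the
# half-space holding fewer ligand atoms; tie -> first non-zero component
# positive.
.plane_normal_direction <- function(ligand, sphere, xyz) {
  uv <- sphere$ligand_unit_vectors
  if (nrow(uv) < 3) {
    # two roughly antiparallel ligators: any perpendicular works; pick the
    # most stable one deterministically
    b <- uv[1, ]
    ref <- if (abs(b[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- .unit(pracma_cross(b, ref))
  } else {
    s <- svd(sweep(uv, 2, colMeans(uv)))
    n <- s$v[, 3]
  }
  m <- sphere$metal_index
  others <- setdiff(seq_len(nrow(xyz)), m)
  side <- as.vector((xyz[others, , drop = FALSE] -
                       matrix(xyz[m, ], length(others), 3, byrow = TRUE)) %*% n)
  n_pos <- sum(side > 1e-8); n_neg <- sum(side < -1e-8)
  if (n_pos < n_neg) return(.unit(n))
  if (n_neg < n_pos) return(.unit(-n))
  nz <- which(abs(n) > 1e-8)[1]
  if (n[nz] < 0) n <- -n
  .unit(n)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Apply the vacant-site option
#'
#' With `vacant_site = TRUE` (the default) the vacancy dummy is placed via
#' [place_dummy()]; with FALSE the ligand is returned unchanged (use this
#' for coordinatively saturated compounds, where the metal has no
#' directional hydrogen-bond-like interaction).
#'
#' @param ligand an `mc_ligand`.
#' @param vacant_site logical flag (default TRUE).
#' @param bond_length metal-dummy distance, Angstrom.
#' @return the ligand, with or without a dummy atom.
#' @export
apply_vacant_site <- function(ligand, vacant_site = TRUE, bond_length = 2.0) {
  if (!isTRUE(vacant_site)) return(ligand)
  place_dummy(ligand, bond_length = bond_length)
}
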
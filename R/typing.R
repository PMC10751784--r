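# AutoDock-style atom typing and ligand torsion-tree construction.
#
# Seven protein/organic types: C (aliphatic carbon), A (aromatic carbon),
# HD (donor hydrogen), N / NA (non-acceptor / acceptor nitrogen),
# OA (acceptor oxygen), SA (acceptor sulfur); plus H (non-polar hydrogen),
# the metal's own element symbol, and DD for the vacancy dummy.

#' Assign AutoDock-style atom types
#'
#' Deterministic rules over the bond graph: H bonded to N/O/S becomes HD,
#' other hydrogens H; carbons in a detected aromatic ring become A, others
#' C; nitrogens without a bonded hydrogen and with fewer than three heavy
#' neighbours (an available lone pair) become NA, others N; all oxygens OA;
#' all sulfurs SA; a metal is typed by its element symbol; DD stays DD.
#'
#' @param mol an `mc_ligand` or `mc_receptor` with bonds perceived (receptor
#'   bonds are perceived on the fly).
#' @return the molecule with `ad_type` filled in for every atom.
#' @export
assign_types <- function(mol) {
  atoms <- mol$atoms
  bonds <- if (!is.null(mol$bonds)) mol$bonds else perceive_bonds(mol)
  n <- nrow(atoms)
  el <- atoms$element
  nbrs <- .neighbor_list(n, bonds)
  arom <- .aromatic_atoms(atoms, bonds, nbrs)
  types <- character(n)
  for (i in seq_len(n)) {
    e <- el[i]
    types[i] <- if (e == "DD") "DD"
    else if (is_metal(e)) e
    else if (e == "H") {
      if (any(el[nbrs[[i]]] %in% c("N", "O", "S"))) "HD" else "H"
    } else if (e == "C") {
      if (arom[i]) "A" else "C"
    } else if (e == "N") {
      heavy <- sum(el[nbrs[[i]]] != "H")
      has_h <- any(el[nbrs[[i]]] == "H")
      if (!has_h && heavy < 3) "NA" else "N"
    } else if (e == "O") "OA"
    else if (e == "S") "SA"
    else stop("no typing rule for element: ", e)
  }
  mol$atoms$ad_type <- types
  mol
}

.neighbor_list <- function(n, bonds) {
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    nbrs[[i]] <- c(nbrs[[i]], j)
    nbrs[[j]] <- c(nbrs[[j]], i)
  }
  nbrs
}

# Rings of size 3..7 via bounded DFS; returned as a list of atom-index
# vectors (each ring reported once).
.find_rings <- function(n, nbrs, max_size = 7L) {
  rings <- list()
  seen <- character(0)
  dfs <- function(path) {
    tip <- path[length(path)]
    for (nx in nbrs[[tip]]) {
      if (length(path) >= 3L && nx == path[1]) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!(nx %in% path) && length(path) < max_size && nx > path[1]) {
        dfs(c(path, nx))
      }
    }
  }
  for (s in seq_len(n)) dfs(s)
  # keep smallest rings: drop a ring if it is a union of two smaller ones
  if (length(rings) > 1) {
    keep <- vapply(seq_along(rings), function(k) {
      rk <- rings[[k]]
      !any(vapply(rings, function(ro) {
        length(ro) < length(rk) && all(ro %in% rk)
      }, TRUE))
    }, TRUE)
    rings <- rings[keep]
  }
  rings
}

# Aromatic ring heuristic: 5- or 6-membered ring, all members C/N/O/S, each
# ring carbon with at most 3 neighbours, ring planar within 0.15 A.
.aromatic_atoms <- function(atoms, bonds, nbrs) {
  n <- nrow(atoms)
  arom <- logical(n)
  rings <- .find_rings(n, nbrs)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  for (ring in rings) {
    if (!(length(ring) %in% c(5L, 6L))) next
    el <- atoms$element[ring]
    if (!all(el %in% c("C", "N", "O", "S"))) next
    deg_ok <- all(vapply(ring, function(i) {
      atoms$element[i] != "C" || length(nbrs[[i]]) <= 3L
    }, TRUE))
    if (!deg_ok) next
    p <- xyz[ring, , drop = FALSE]
    p <- sweep(p, 2, colMeans(p))
    dev <- svd(p)$d[3] / sqrt(length(ring))  # rms out-of-plane
    if (dev < 0.15) arom[ring] <- TRUE
  }
  arom
}

#' Build the ligand torsion tree
#'
#' Rotatable bonds are acyclic single bonds between non-terminal heavy
#' atoms, excluding amide C-N bonds and any bond involving the metal or an
#' atom of its first coordination sphere (the coordination core stays
#' rigid). The root is the atom whose removal leaves the most balanced
#' fragments (smallest largest-fragment size; ties to the lowest index).
#'
#' @param ligand a typed `mc_ligand`.
#' @param max_torsions hard cap on rotatable bonds (default 10); more is an
#'   error because pose search degrades beyond it.
#' @return the ligand with `torsion_tree` set: a list with `root` (atom
#'   index) and `torsions`, each `list(bond = c(proximal, distal), moving =
#'   <distal atom indices>)` in root-outward order.
#' @export
build_torsion_tree <- function(ligand, max_torsions = 10L) {
  atoms <- ligand$atoms
  bonds <- ligand$bonds
  n <- nrow(atoms)
  el <- atoms$element
  nbrs <- .neighbor_list(n, bonds)
  rings <- .find_rings(n, nbrs)
  in_ring_bond <- function(i, j) {
    any(vapply(rings, function(r) (i %in% r) && (j %in% r), TRUE))
  }
  sphere <- integer(0)
  if (!is.na(ligand$metal_index)) {
    sphere <- c(ligand$metal_index, nbrs[[ligand$metal_index]])
  }
  heavy_deg <- vapply(seq_len(n), function(i) sum(el[nbrs[[i]]] != "H"), 0L)
  rot <- list()
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    if (el[i] == "H" || el[j] == "H") next
    if (el[i] == "DD" || el[j] == "DD") next
    if (i %in% sphere || j %in% sphere) next
    if (heavy_deg[i] < 2L || heavy_deg[j] < 2L) next   # terminal heavy atom
    if (in_ring_bond(i, j)) next
    if (.is_amide(i, j, el, nbrs, atoms)) next
    rot[[length(rot) + 1L]] <- c(i, j)
  }
  if (length(rot) > max_torsions) {
    stop(sprintf("%d rotatable bonds exceed the cap of %d", length(rot), max_torsions))
  }
  root <- .pick_root(n, bonds, el)
  ligand$torsion_tree <- .torsion_tree_from_bonds(ligand, root, rot)
  ligand
}

# Amide: C-N bond where the carbon also binds an oxygen at < 1.30 A
# (carbonyl-like) -- excluded from rotation.
.is_amide <- function(i, j, el, nbrs, atoms) {
  for (ord in list(c(i, j), c(j, i))) {
    ci <- ord[1]; ni <- ord[2]
    if (el[ci] == "C" && el[ni] == "N") {
      for (o in nbrs[[ci]]) {
        if (el[o] == "O") {
          d <- sqrt(sum((unlist(atoms[ci, c("x", "y", "z")]) -
                           unlist(atoms[o, c("x", "y", "z")]))^2))
          if (d < 1.30) return(TRUE)
        }
      }
    }
  }
  FALSE
}

# Root = atom minimizing the size of the largest connected fragment left
# after its removal; dummy excluded; tie -> lowest index.
.pick_root <- function(n, bonds, el) {
  cand <- which(el != "DD" & el != "H")
  if (!length(cand)) cand <- seq_len(n)
  score <- vapply(cand, function(a) {
    keep <- bonds[bonds[, 1] != a & bonds[, 2] != a, , drop = FALSE]
    comp <- .components(n, keep)
    comp[a] <- NA
    if (all(is.na(comp))) 0L else max(table(comp[!is.na(comp)]))
  }, 0L)
  cand[which.min(score)]
}

# Orient rotatable bonds away from the root and compute moving sets.
.torsion_tree_from_bonds <- function(ligand, root, rot_bonds) {
  n <- nrow(ligand$atoms)
  torsions <- list()
  if (length(rot_bonds)) {
    # order bonds by distance from root (BFS over the bond graph)
    nbrs <- .neighbor_list(n, ligand$bonds)
    depth <- rep(NA_integer_, n); depth[root] <- 0L
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nbrs[[v]]) if (is.na(depth[w])) {
        depth[w] <- depth[v] + 1L
        queue <- c(queue, w)
      }
    }
    ord <- order(vapply(rot_bonds, function(b) min(depth[b]), 0L),
                 vapply(rot_bonds, function(b) min(b), 0L))
    rot_bonds <- rot_bonds[ord]
    for (b in rot_bonds) {
      i <- b[1]; j <- b[2]
      keep <- !(ligand$bonds[, 1] == min(i, j) & ligand$bonds[, 2] == max(i, j))
      comp <- .components(n, ligand$bonds[keep, , drop = FALSE])
      if (comp[i] == comp[j]) next  # ring bond slipped through; skip
      prox <- if (comp[i] == comp[root]) i else j
      dist <- if (prox == i) j else i
      moving <- which(comp == comp[dist])
      torsions[[length(torsions) + 1L]] <-
        list(bond = c(prox, dist), moving = moving,
             moving_sans_pivot = setdiff(moving, dist))
    }
  }
  list(root = root, torsions = torsions)
}

#' Number of rotatable bonds of a ligand
#' @param ligand an `mc_ligand` with a torsion tree.
#' @return integer count.
#' @export
n_torsions <- function(ligand) {
  if (is.null(ligand$torsion_tree)) stop("no torsion tree; run build_torsion_tree")
  length(ligand$torsion_tree$torsions)
}
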
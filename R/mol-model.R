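# Molecular data model: ligands (metal-organic compounds) and rigid
# receptors, plus readers/writers for XYZ, PDB and PDBQT.
#
# A ligand is a list with class "mc_ligand":
#   atoms   data.frame(element, x, y, z, charge, ad_type)
#   bonds   integer matrix, columns i, j (i < j), one row per bond
#   metal_index   index of the metal atom, or NA
#   dummy_index   index of the vacancy dummy atom ("DD"), or NA
#   torsion_tree  NULL until build_torsion_tree() is called
# A receptor ("mc_receptor") holds atoms (plus residue tags) and an
# optional crystallographic resolution.

#' Construct a ligand from atom data
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (defaults to 0) and `ad_type` (defaults to NA).
#' @param bonds optional two-column integer matrix of bonds; perceived from
#'   covalent radii when NULL.
#' @return an object of class `mc_ligand`.
#' @export
new_ligand <- function(atoms, bonds = NULL) {
  stopifnot(is.data.frame(atoms), all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms$element <- .norm_element(atoms$element)
  bad <- !.known_element(atoms$element)
  if (any(bad)) {
    stop("unknown element symbol(s): ", paste(unique(atoms$element[bad]), collapse = ", "))
  }
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$ad_type)) atoms$ad_type <- NA_character_
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  rownames(atoms) <- NULL
  lig <- structure(list(
    atoms = atoms,
    bonds = NULL,
    metal_index = .find_metal(atoms$element),
    dummy_index = .find_dummy(atoms$element),
    torsion_tree = NULL
  ), class = "mc_ligand")
  if (!is.na(lig$dummy_index) && atoms$charge[lig$dummy_index] != 0) {
    stop("dummy atom must carry zero charge")
  }
  lig$bonds <- if (is.null(bonds)) perceive_bonds(lig) else .check_bonds(bonds, nrow(atoms))
  .check_connected(lig)
  lig
}

.find_metal <- function(elements) {
  idx <- which(is_metal(elements))
  if (length(idx) == 0L) return(NA_integer_)
  if (length(idx) > 1L) stop("multiple metal atoms are not supported")
  idx
}

.find_dummy <- function(elements) {
  idx <- which(elements == "DD" | elements == "Dd")
  if (length(idx) > 1L) stop("at most one dummy atom is allowed")
  if (length(idx) == 0L) NA_integer_ else idx
}

.check_bonds <- function(bonds, natoms) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1L | bonds > natoms)) stop("bond index out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bond")
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
  }
  colnames(bonds) <- c("i", "j")
  bonds
}

.check_connected <- function(lig) {
  n <- nrow(lig$atoms)
  keep <- setdiff(seq_len(n), lig$dummy_index)
  if (length(keep) <= 1L) return(invisible(TRUE))
  comp <- .components(n, lig$bonds)
  if (length(unique(comp[keep])) > 1L) {
    warning("ligand bond graph is not connected (ignoring the dummy)")
  }
  invisible(TRUE)
}

# Connected components of an atom graph; returns component id per atom.
.components <- function(n, bonds) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below 1.15 times the sum of
#' their covalent radii; pairs involving the metal use a 1.25 factor to
#' capture longer dative bonds. The dummy atom is only ever bonded to the
#' metal.
#'
#' @param mol an `mc_ligand` or `mc_receptor`, or a data.frame of atoms.
#' @return integer matrix with columns `i`, `j` (i < j).
#' @export
perceive_bonds <- function(mol) {
  atoms <- if (is.data.frame(mol)) mol else mol$atoms
  n <- nrow(atoms)
  el <- .norm_element(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- covalent_radius(el)
  metal <- is_metal(el)
  dummy <- el == "DD"
  out <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    d <- as.matrix(stats::dist(xyz))
    cut <- outer(r, r, "+")
    fac <- matrix(1.15, n, n)
    fac[metal, ] <- 1.25
    fac[, metal] <- 1.25
    adj <- d < cut * fac & upper.tri(d)
    # dummy bonds only to the metal (fixed geometry, not distance)
    if (any(dummy)) {
      adj[dummy, ] <- FALSE
      adj[, dummy] <- FALSE
      if (any(metal)) {
        di <- which(dummy); mi <- which(metal)
        adj[min(di, mi), max(di, mi)] <- TRUE
      }
    }
    out <- which(adj, arr.ind = TRUE)
    out <- cbind(pmin(out[, 1], out[, 2]), pmax(out[, 1], out[, 2]))
  }
  out <- matrix(as.integer(out), ncol = 2)
  colnames(out) <- c("i", "j")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' @export
print.mc_ligand <- function(x, ...) {
  cat(sprintf("<mc_ligand> %d atoms, %d bonds", nrow(x$atoms), nrow(x$bonds)))
  if (!is.na(x$metal_index)) {
    cat(sprintf(", metal %s@%d", x$atoms$element[x$metal_index], x$metal_index))
  }
  if (!is.na(x$dummy_index)) cat(sprintf(", dummy@%d", x$dummy_index))
  if (!is.null(x$torsion_tree)) {
    cat(sprintf(", %d rotatable bond(s)", length(x$torsion_tree$torsions)))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.mc_receptor <- function(x, ...) {
  cat(sprintf("<mc_receptor> %d atoms", nrow(x$atoms)))
  if (!is.null(x$source_resolution) && !is.na(x$source_resolution)) {
    cat(sprintf(", resolution %.2f A", x$source_resolution))
  }
  cat("\n")
  invisible(x)
}

#' Coordinates of a molecule as an n x 3 matrix
#' @param mol ligand or receptor.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(mol) {
  out <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(out) <- NULL
  out
}

#' Replace coordinates of a molecule
#' @param mol ligand or receptor.
#' @param xyz n x 3 numeric matrix.
#' @return the molecule with new coordinates.
#' @export
set_coords <- function(mol, xyz) {
  stopifnot(nrow(xyz) == nrow(mol$atoms), ncol(xyz) == 3)
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

# ---------------------------------------------------------------------------
# XYZ

#' Read a ligand from an (extended) XYZ file
#'
#' Standard XYZ with an optional fifth numeric column holding per-atom
#' partial charges (elementary charge units). Without that column charges
#' are set to zero and a warning is recorded.
#'
#' @param path path to the XYZ file.
#' @param charge_column read charges from a fifth column when present
#'   (default TRUE).
#' @return an `mc_ligand` with bonds perceived from covalent radii.
#' @export
read_xyz <- function(path, charge_column = TRUE) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("malformed XYZ header: empty file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("malformed XYZ header: first line must be the atom count")
  if (length(lines) < n + 2) {
    stop(sprintf("malformed XYZ: header declares %d atoms but file has %d atom lines",
                 n, max(0L, length(lines) - 2L)))
  }
  body <- lines[3:(n + 2)]
  toks <- strsplit(trimws(body), "\\s+")
  el <- vapply(toks, `[`, "", 1L)
  el <- .norm_element(el)
  bad <- which(!.known_element(el))
  if (length(bad)) {
    stop(sprintf("unknown element symbol '%s' on line %d", el[bad[1]], bad[1] + 2L))
  }
  num <- function(k) vapply(toks, function(t) suppressWarnings(as.numeric(t[k])), 0)
  xyz <- cbind(num(2), num(3), num(4))
  if (any(!is.finite(xyz))) stop("malformed XYZ: non-numeric coordinate")
  has_q <- all(vapply(toks, length, 0L) >= 5L)
  if (charge_column && has_q) {
    q <- num(5)
    if (any(!is.finite(q))) stop("malformed XYZ: non-numeric charge column")
  } else {
    q <- rep(0, n)
    if (charge_column) warning("no charge column in XYZ; all charges set to 0")
  }
  new_ligand(data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        charge = q))
}

#' Write a ligand to an (extended) XYZ file
#'
#' @param ligand an `mc_ligand`.
#' @param path output path.
#' @param charges write the extended charge column (default TRUE).
#' @return the path, invisibly.
#' @export
write_xyz <- function(ligand, path, charges = TRUE) {
  a <- ligand$atoms
  hdr <- c(sprintf("%d", nrow(a)), "generated by mcdock")
  body <- if (charges) {
    sprintf("%-3s %14.8f %14.8f %14.8f %10.6f", a$element, a$x, a$y, a$z, a$charge)
  } else {
    sprintf("%-3s %14.8f %14.8f %14.8f", a$element, a$x, a$y, a$z)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# PDB (receptor)

#' Read a rigid receptor from a PDB file
#'
#' Waters (HOH/WAT/H2O) and HETATM groups are removed unless
#' `keep_nonresidues` is TRUE (needed when a cofactor takes part in
#' binding). Alternate locations are resolved to the highest occupancy
#' (ties keep the first listed). Multi-model files are rejected unless a
#' model is selected explicitly.
#'
#' @param path path to a PDB file.
#' @param keep_nonresidues keep HETATM records (cofactors); default FALSE.
#' @param model model number to read from a multi-model file; NULL (the
#'   default) errors on multi-model input.
#' @param resolution optional crystallographic resolution in Angstrom to
#'   attach; when NULL it is parsed from REMARK 2 if present.
#' @return an `mc_receptor`.
#' @export
read_pdb <- function(path, keep_nonresidues = FALSE, model = NULL,
                     resolution = NULL) {
  lines <- readLines(path)
  nmodels <- sum(grepl("^MODEL ", lines))
  if (nmodels > 1) {
    if (is.null(model)) {
      stop(sprintf("PDB file has %d models; select one with model = <n>", nmodels))
    }
    starts <- grep("^MODEL ", lines)
    ends <- grep("^ENDMDL", lines)
    if (model < 1 || model > nmodels) stop("model out of range")
    pre <- if (starts[1] > 1) lines[1:(starts[1] - 1)] else character(0)
    lines <- c(pre, lines[(starts[model] + 1):(ends[model] - 1)])
  }
  if (is.null(resolution)) {
    rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(rem)) {
      m <- regmatches(rem[1], regexpr("[0-9]+\\.[0-9]+", rem[1]))
      if (length(m)) resolution <- as.numeric(m)
    }
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  if (!keep_nonresidues) a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[!(a$resid %in% c("HOH", "WAT", "H2O")), , drop = FALSE]
  if (nrow(a) == 0) stop("no receptor atoms left after filtering")
  a <- .resolve_altloc(a)
  el <- a$elesy
  miss <- is.na(el) | trimws(el) == ""
  if (any(miss)) el[miss] <- .element_from_name(a$elety[miss])
  el <- .norm_element(el)
  bad <- !.known_element(el)
  if (any(bad)) stop("unknown element symbol(s) in PDB: ",
                     paste(unique(el[bad]), collapse = ", "))
  atoms <- data.frame(
    element = el, x = a$x, y = a$y, z = a$z,
    charge = 0, ad_type = NA_character_,
    atom_name = trimws(a$elety), resid = a$resid, resno = a$resno,
    chain = a$chain, stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 source_resolution = if (is.null(resolution)) NA_real_ else resolution),
            class = "mc_receptor")
}

# Keep, per atom site (chain/resno/atom name), the altloc with the highest
# occupancy; ties keep the first listed.
.resolve_altloc <- function(a) {
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  if (!anyDuplicated(key)) return(a)
  occ <- a$o
  occ[is.na(occ)] <- 1
  keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(ix) {
    ix[which.max(occ[ix])]
  }), use.names = FALSE)
  a[sort(keep), , drop = FALSE]
}

# Derive an element symbol from a PDB atom name (e.g. " CA " -> C, "1HB" -> H).
.element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- substr(nm, 1, 2)
  ifelse(.known_element(.norm_element(two)) & nchar(nm) > 1 &
           .norm_element(two) %in% .METALS,
         .norm_element(two), substr(nm, 1, 1))
}

# ---------------------------------------------------------------------------
# PDBQT

#' Write a ligand or receptor to a PDBQT file
#'
#' AutoDock4-style columns: partial charge in columns 71-76 and the atom
#' type in columns 78-79. Ligand files carry the ROOT/BRANCH torsion-tree
#' blocks and a TORSDOF record; atoms are written in torsion-tree traversal
#' order (the input order whenever that order is already tree-consistent).
#' Metals are written with the element symbol as type, the vacancy dummy as
#' type DD.
#'
#' @param mol an `mc_ligand` (with torsion tree built) or `mc_receptor`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pdbqt <- function(mol, path) {
  a <- mol$atoms
  untyped <- which(is.na(a$ad_type) | a$ad_type == "")
  if (length(untyped)) {
    stop("untyped atom(s) at index: ", paste(untyped, collapse = ", "),
         " (run assign_types first)")
  }
  fmt <- function(i, serial) {
    name <- sprintf("%s%d", a$element[i], i)
    if (nchar(name) > 4) name <- substr(name, 1, 4)
    resid <- if (!is.null(a$resid)) a$resid[i] else "LIG"
    resno <- if (!is.null(a$resno)) a$resno[i] else 1L
    chain <- if (!is.null(a$chain) && !is.na(a$chain[i])) a$chain[i] else "A"
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
            "ATOM", serial, name, " ", resid, chain, resno, " ",
            a$x[i], a$y[i], a$z[i], 1, 0, a$charge[i], a$ad_type[i])
  }
  if (inherits(mol, "mc_receptor")) {
    writeLines(vapply(seq_len(nrow(a)), function(i) fmt(i, i), ""), path)
    return(invisible(path))
  }
  tt <- mol$torsion_tree
  if (is.null(tt)) stop("ligand has no torsion tree; run build_torsion_tree first")
  lines <- character(0)
  serial <- 0L
  serial_of <- integer(nrow(a))
  emit <- function(ix) {
    for (i in ix) {
      serial <<- serial + 1L
      serial_of[i] <<- serial
      lines <<- c(lines, fmt(i, serial))
    }
  }
  # group atoms into rigid groups separated by rotatable bonds
  groups <- .rigid_groups(mol)
  root_group <- groups$group_of[tt$root]
  lines <- c(lines, "ROOT")
  emit(sort(groups$members[[root_group]]))
  lines <- c(lines, "ENDROOT")
  # depth-first emission of branches
  emit_branch <- function(parent_group) {
    for (k in seq_along(tt$torsions)) {
      tor <- tt$torsions[[k]]
      gi <- groups$group_of[tor$bond[1]]; gj <- groups$group_of[tor$bond[2]]
      if (gi == parent_group || gj == parent_group) {
        child <- if (gi == parent_group) gj else gi
        if (groups$visited[child]) next
        groups$visited[child] <<- TRUE
        prox <- if (gi == parent_group) tor$bond[1] else tor$bond[2]
        dist <- if (gi == parent_group) tor$bond[2] else tor$bond[1]
        lines <<- c(lines, sprintf("BRANCH %d %d", serial_of[prox], serial + 1L))
        emit(sort(groups$members[[child]]))
        emit_branch(child)
        lines <<- c(lines, sprintf("ENDBRANCH %d %d", serial_of[prox], serial_of[dist]))
      }
    }
  }
  groups$visited <- logical(length(groups$members))
  groups$visited[root_group] <- TRUE
  emit_branch(root_group)
  lines <- c(lines, sprintf("TORSDOF %d", length(tt$torsions)))
  writeLines(lines, path)
  invisible(path)
}

# Split the ligand into rigid groups: connected components after removing
# rotatable bonds (the dummy travels with the metal's group).
.rigid_groups <- function(lig) {
  n <- nrow(lig$atoms)
  tt <- lig$torsion_tree
  rot <- if (length(tt$torsions)) {
    do.call(rbind, lapply(tt$torsions, function(t) sort(t$bond)))
  } else matrix(integer(0), ncol = 2)
  keep <- rep(TRUE, nrow(lig$bonds))
  for (k in seq_len(nrow(rot))) {
    keep <- keep & !(lig$bonds[, 1] == rot[k, 1] & lig$bonds[, 2] == rot[k, 2])
  }
  comp <- .components(n, lig$bonds[keep, , drop = FALSE])
  ids <- unique(comp)
  members <- lapply(ids, function(g) which(comp == g))
  group_of <- match(comp, ids)
  list(members = members, group_of = group_of)
}

#' Read a ligand or receptor from a PDBQT file
#'
#' Inverts [write_pdbqt()]: atoms are returned in file order with charges
#' and types from the fixed columns; bonds are re-perceived; for ligand
#' files the torsion tree is rebuilt from the BRANCH records.
#'
#' @param path path to a PDBQT file.
#' @param as one of "auto", "ligand", "receptor"; "auto" returns a ligand
#'   when ROOT records are present.
#' @return an `mc_ligand` or `mc_receptor`.
#' @export
read_pdbqt <- function(path, as = c("auto", "ligand", "receptor")) {
  as <- match.arg(as)
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  al <- lines[is_atom]
  if (!length(al)) stop("no ATOM records in PDBQT")
  el_type <- trimws(substr(al, 78, 79))
  atoms <- data.frame(
    element = NA_character_,
    x = as.numeric(substr(al, 31, 38)),
    y = as.numeric(substr(al, 39, 46)),
    z = as.numeric(substr(al, 47, 54)),
    charge = as.numeric(substr(al, 71, 76)),
    ad_type = el_type,
    stringsAsFactors = FALSE
  )
  atoms$element <- vapply(seq_along(el_type), function(i) {
    t <- el_type[i]
    if (t %in% c("C", "A")) "C"
    else if (t %in% c("HD", "H")) "H"
    else if (t %in% c("N", "NA")) "N"
    else if (t == "OA") "O"
    else if (t == "SA") "S"
    else t  # metal symbol or DD
  }, "")
  is_lig <- any(grepl("^ROOT", lines))
  if (as == "receptor" || (as == "auto" && !is_lig)) {
    rownames(atoms) <- NULL
    return(structure(list(atoms = atoms, source_resolution = NA_real_),
                     class = "mc_receptor"))
  }
  lig <- new_ligand(atoms)
  lig$atoms$ad_type <- atoms$ad_type
  # rebuild torsion list from BRANCH serials (serial = position in file order)
  br <- grep("^BRANCH", lines, value = TRUE)
  torsions <- lapply(br, function(s) {
    ij <- as.integer(strsplit(trimws(sub("^BRANCH", "", s)), "\\s+")[[1]])
    list(bond = ij)
  })
  root_line <- which(grepl("^ROOT", lines))[1]
  # root atom: first atom after ROOT
  after <- which(is_atom & seq_along(lines) > root_line)
  root_atom <- which(cumsum(is_atom) == cumsum(is_atom)[after[1]])[1]
  root_atom <- sum(is_atom[1:after[1]])
  lig$torsion_tree <- .torsion_tree_from_bonds(lig, root_atom,
                                               lapply(torsions, `[[`, "bond"))
  lig
}
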
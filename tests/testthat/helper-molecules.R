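# Small molecule builders used across the tests. Everything is generated
# in code; no binary fixtures.

# Water: O at origin, two H at 0.96 A, 104.5 degree angle.
water_ligand <- function() {
  a <- 104.5 * pi / 180
  new_ligand(data.frame(
    element = c("O", "H", "H"),
    x = c(0, 0.96, 0.96 * cos(a)),
    y = c(0, 0, 0.96 * sin(a)),
    z = 0, charge = c(-0.8, 0.4, 0.4)))
}

# Benzene: planar hexagon, C-C 1.39 A, radial H.
benzene_ligand <- function() {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  new_ligand(rbind(
    data.frame(element = "C", x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0),
    data.frame(element = "H", x = 2.48 * cos(ang), y = 2.48 * sin(ang), z = 0)))
}

# Imidazole: regular pentagon (N1-H, C2, N3, C4, C5) with radial hydrogens
# on N1, C2, C4, C5.
imidazole_ligand <- function() {
  ang <- seq(90, 90 + 360, by = 72)[1:5] * pi / 180
  r <- 1.16
  at <- data.frame(element = c("N", "C", "N", "C", "C"),
                   x = r * cos(ang), y = r * sin(ang), z = 0)
  at <- rbind(at, data.frame(element = "H",
                             x = 2.2 * cos(ang)[c(1, 2, 4, 5)],
                             y = 2.2 * sin(ang)[c(1, 2, 4, 5)], z = 0))
  new_ligand(at)
}

# Methane: tetrahedral.
methane_ligand <- function() {
  d <- 1.09 / sqrt(3)
  new_ligand(data.frame(
    element = c("C", "H", "H", "H", "H"),
    x = c(0, d, d, -d, -d), y = c(0, d, -d, d, -d), z = c(0, d, -d, -d, d)))
}

# Bare carbon chains (zigzag, C-C 1.54 A): ethane/butane skeletons for
# torsion-rule tests.
carbon_chain <- function(n) {
  ax <- 1.54 * sin(55.5 * pi / 180)
  lat <- 1.54 * cos(55.5 * pi / 180)
  new_ligand(data.frame(element = "C", x = (1:n) * ax,
                        y = lat * ((1:n) %% 2), z = 0))
}

# A minimal PDB text: protein-like ATOM records, optional HETATM waters and
# a cofactor. Returns the path of a temp file.
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb"),
                           n_res = 3, waters = 0, cofactor = FALSE,
                           altloc = FALSE, models = 1) {
  rec <- function(type, serial, name, alt, resn, chain, resno, x, y, z, occ, el) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, alt, resn, chain, resno, " ", x, y, z, occ, 0, el)
  }
  body <- character(0)
  serial <- 0
  one_model <- function(shift = 0) {
    lines <- character(0)
    for (i in seq_len(n_res)) {
      for (at in list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"))) {
        serial <<- serial + 1
        lines <- c(lines, rec("ATOM", serial, at[1], " ", "ALA", "A", i,
                              3.8 * i + shift, serial %% 3, 0.5 * serial %% 5, 1, at[2]))
      }
      if (altloc && i == 1) {
        serial <<- serial + 1
        lines <- c(lines, rec("ATOM", serial, "CB", "A", "ALA", "A", i,
                              3.8 * i + 1, 1, 1, 0.4, "C"))
        serial <<- serial + 1
        lines <- c(lines, rec("ATOM", serial, "CB", "B", "ALA", "A", i,
                              3.8 * i + 1.2, 1, 1, 0.6, "C"))
      }
    }
    for (w in seq_len(waters)) {
      for (at in list(c("O", "O"), c("H1", "H"), c("H2", "H"))) {
        serial <<- serial + 1
        lines <- c(lines, rec("HETATM", serial, at[1], " ", "HOH", "W", 100 + w,
                              20 + w, 20, 20 + 0.3 * serial %% 2, 1, at[2]))
      }
    }
    if (cofactor) {
      for (k in 1:4) {
        serial <<- serial + 1
        lines <- c(lines, rec("HETATM", serial, paste0("C", k), " ", "HEM", "A", 200,
                              10 + k, 10, 10, 1, "C"))
      }
    }
    lines
  }
  out <- character(0)
  if (models > 1) {
    for (m in seq_len(models)) {
      out <- c(out, sprintf("MODEL     %4d", m), one_model(shift = m), "ENDMDL")
    }
  } else {
    out <- one_model()
  }
  writeLines(c(out, "END"), path)
  path
}

# Independent R-level energy oracle: plain double loop over atom pairs
# built from the exported pair functions (no cutoffs unless given).
oracle_energy <- function(ligand, receptor, params, lxyz = coords(ligand),
                          lj_cutoff = Inf, elec_cutoff = Inf) {
  rxyz <- coords(receptor)
  lt <- ligand$atoms$ad_type; rt <- receptor$atoms$ad_type
  lq <- ligand$atoms$charge; rq <- receptor$atoms$charge
  m <- ligand$metal_index; dd <- ligand$dummy_index
  total <- 0
  for (i in seq_len(nrow(lxyz))) {
    if (lt[i] == "DD") next
    for (j in seq_len(nrow(rxyz))) {
      r <- sqrt(sum((lxyz[i, ] - rxyz[j, ])^2))
      pr <- get_pair(params, lt[i], rt[j])
      if (r <= lj_cutoff) {
        e <- lj_energy(r, pr$eps, pr$rmin, pr$exponents)
        if (!is.na(m) && i == m && rt[j] %in% c("NA", "OA", "SA") && !is.na(dd)) {
          w <- hbond_weight(lxyz[m, ], lxyz[dd, ], rxyz[j, ])
          rep_part <- pr$eps * 5 * (pr$rmin / r)^12
          att_part <- pr$eps * 6 * (pr$rmin / r)^10
          e <- rep_part - w * att_part
        }
        total <- total + e
      }
      if (r <= elec_cutoff && lq[i] != 0 && rq[j] != 0) {
        total <- total + electrostatic_energy(lq[i], rq[j], r)
      }
    }
  }
  total
}
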
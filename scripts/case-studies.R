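#!/usr/bin/env Rscript
# Optional, network-dependent sanity check against three published
# metalloprotein co-crystal structures (PDB 2BZH, 1XRW, 3GSK). Downloads
# the structures from the PDB, extracts the metal-organic compound as the
# reference, docks it back into its own pocket, and reports best-pose
# RMSDs. Informative only: real compounds need externally computed partial
# charges (the quantum step is outside this package), so zero charges are
# used here and the numbers are qualitative.
#
# Not part of the automated checks; requires internet access.

suppressMessages(library(mcdock))

ids <- c("2BZH", "1XRW", "3GSK")
dir.create("scratch/case-studies", recursive = TRUE, showWarnings = FALSE)

for (id in ids) {
  pdb_path <- file.path("scratch/case-studies", paste0(id, ".pdb"))
  if (!file.exists(pdb_path)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", id)
    message("downloading ", url)
    ok <- tryCatch({ download.file(url, pdb_path, quiet = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok) { message("skipping ", id, " (no network?)"); next }
  }
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  het <- pdb$atom[pdb$atom$type == "HETATM" &
                    !(pdb$atom$resid %in% c("HOH", "WAT")), ]
  metal_rows <- het[is_metal(mcdock:::.norm_element(het$elesy)), ]
  if (nrow(metal_rows) == 0) { message(id, ": no metal HETATM found"); next }
  res_id <- metal_rows$resid[1]
  comp <- het[het$resid == res_id, ]
  message(sprintf("%s: compound %s with %d atoms", id, res_id, nrow(comp)))
  lig <- try(assign_types(build_torsion_tree(assign_types(new_ligand(data.frame(
    element = mcdock:::.norm_element(comp$elesy),
    x = comp$x, y = comp$y, z = comp$z, charge = 0))))), silent = TRUE)
  if (inherits(lig, "try-error")) { message(id, ": could not build ligand"); next }
  lig <- tryCatch(apply_vacant_site(lig, TRUE), error = function(e) lig)
  rec <- assign_types(read_pdb(pdb_path))
  metal <- lig$atoms$element[lig$metal_index]
  prm <- default_params(metal)
  ref <- coords(lig)
  box <- docking_box(colMeans(ref[seq_len(nrow(comp)), , drop = FALSE]), 20)
  res <- ga_dock(lig, rec, prm, box, n_runs = 10, seed = 1)
  rmsd <- pose_rmsd(res$poses[[1]]$coords, ref,
                    elements = lig$atoms$element,
                    dummy_index = lig$dummy_index)
  message(sprintf("%s: best-pose RMSD %.2f A (energy %.2f kcal/mol)",
                  id, rmsd, res$poses[[1]]$energy))
}
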
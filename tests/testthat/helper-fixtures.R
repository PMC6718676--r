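# Shared fixture builders; everything is generated in code at test time.

# minimal topology: n_mem upper-leaflet headgroup atoms + protein atoms
# given as a data.frame(residue_id, x, y, z) of single-atom residues
make_test_traj <- function(protein_atoms, mem_z = rep(20, 3),
                           frame_interval = 100, n_frames = 1,
                           drift = function(k, m) m) {
  n_m <- length(mem_z)
  n_p <- nrow(protein_atoms)
  top <- rbind(
    data.frame(atom_id = seq_len(n_p), atom_name = "CA",
               residue_id = protein_atoms$residue_id, residue_name = "ALA",
               chain_tag = "PROT", leaflet = "none"),
    data.frame(atom_id = n_p + seq_len(n_m), atom_name = "N",
               residue_id = seq_len(n_m), residue_name = "DOP",
               chain_tag = "MEMB", leaflet = "upper"))
  base <- rbind(as.matrix(protein_atoms[, c("x", "y", "z")]),
                cbind(seq_len(n_m) * 8, 0, mem_z))
  coords <- array(NA_real_, c(n_p + n_m, 3, n_frames))
  for (k in seq_len(n_frames)) coords[, , k] <- drift(k, base)
  trajectory(top, coords, frame_interval = frame_interval)
}

# a small bilayer + pseudo-protein docking run
make_docking_sim <- function(height = 30, angle = 45, noise_sd = 0,
                             duration_ns = 1, frame_interval = 100,
                             n_lipids = 60, atoms_per_residue = 1,
                             seed = 11) {
  bl <- build_bilayer(bilayer_spec(n_lipids = n_lipids, patch_side = 60,
                                   z_jitter_sd = 0.5),
                      seed = seed)
  sch <- docking_schedule(c(0, duration_ns), rep(height, 2), rep(angle, 2),
                          noise_sd = noise_sd, seed = seed + 1)
  simulate_docking_trajectory(
    pseudo_protein(atoms_per_residue = atoms_per_residue, seed = seed + 2),
    bl, sch, frame_interval = frame_interval, duration_ns = duration_ns)
}

# PDB text fixture writer for malformed-file contract tests
write_pdb_lines <- function(models, path) {
  fmt <- function(i, name, resid, chain, resno, x, y, z, b) {
    sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            i, name, resid, chain, resno, x, y, z, 1, b)
  }
  lines <- character(0)
  for (m in seq_along(models)) {
    lines <- c(lines, sprintf("MODEL %8d", m))
    df <- models[[m]]
    for (r in seq_len(nrow(df))) {
      lines <- c(lines, fmt(r, df$name[r], df$resid[r], df$chain[r],
                            df$resno[r], df$x[r], df$y[r], df$z[r], df$b[r]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

simple_model_df <- function(n = 10, z = 20) {
  data.frame(name = "N", resid = "DOP", chain = "M", resno = seq_len(n),
             x = seq_len(n) * 5, y = 0, z = z, b = 1)
}
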
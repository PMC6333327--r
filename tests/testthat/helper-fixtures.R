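# Hand-written PDB fixtures, independent of any writer in the package or
# in bio3d, so parsing is tested against known text.

pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     element = "") {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, chain, resid, x, y, z, element)
}

# 3 heavy atoms (C, N, O), one residue
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    pdb_line(1, "C", "ALA", "A", 1, 0, 0, 0, "C"),
    pdb_line(2, "N", "ALA", "A", 1, 1.5, 0, 0, "N"),
    pdb_line(3, "O", "ALA", "A", 1, 0, 1.5, 0, "O"),
    "END"), path)
  path
}

# 5 atoms, 2 of them hydrogens; element column left blank to exercise the
# name-based fallback
write_h_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "HA2", "GLY", "A", 1, 0.5, 0.5, 0),
    pdb_line(3, "N", "GLY", "A", 1, 1.2, 0, 0),
    pdb_line(4, "1HB", "GLY", "A", 1, 0.5, -0.5, 0),
    pdb_line(5, "O", "GLY", "A", 1, 2.0, 1.0, 0),
    "END"), path)
  path
}

# two models whose coordinates differ as written
write_multimodel_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "MODEL     1",
    pdb_line(1, "C", "ALA", "A", 1, 0, 0, 0, "C"),
    pdb_line(2, "N", "ALA", "A", 1, 1.5, 0, 0, "N"),
    pdb_line(3, "O", "ALA", "A", 1, 0, 1.5, 0, "O"),
    "ENDMDL",
    "MODEL     2",
    pdb_line(1, "C", "ALA", "A", 1, 0.5, 0, 0, "C"),
    pdb_line(2, "N", "ALA", "A", 1, 2.0, 0, 0, "N"),
    pdb_line(3, "O", "ALA", "A", 1, 0.5, 1.5, 0, "O"),
    "ENDMDL", "END"), path)
  path
}

# a neighborhood object assembled by hand (for definitional tests that
# bypass build_neighborhood's size checks)
manual_neighborhood <- function(ref, center, members) {
  rel <- sweep(ref$xyz[members, , drop = FALSE], 2L, ref$xyz[center, ])
  structure(list(center = center, members = members, radius = NA_real_,
                 rel = rel, R = r_matrix(rel), n = length(members),
                 cond = NA_real_),
            class = "nap_neighborhood")
}

# small protein-like test system shared across statistic tests
helix_system <- function(n_atoms = 240L, T = 40L, noise = 0.05,
                         seed = 5L) {
  ref <- make_reference("helix", n_atoms = n_atoms, seed = seed)
  ens <- mode_ensemble(ref, list(), noise_sigma = noise, T = T, seed = seed)
  list(ref = ref, ens = ens)
}
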
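# Shared fixtures, built once per test run.

toy16 <- make_toy_protein(16, seed = 1)
toy_sys <- build_go_system(toy16$beads, toy16$contacts)

# wide hairpin + tunnel family used for tethered checks
wide_hp <- make_toy_protein(16, "hairpin", seed = 1, strand_sep = 0.8)
toy_tun <- make_toy_tunnel(6, 1.0, 0.35)

tethered_system <- function(L, protein = wide_hp, tunnel = toy_tun,
                            params = cg_params()) {
  attach_linker_and_tether(
    build_go_system(protein$beads, protein$contacts, tunnel, params), L)
}

# a minimal two-residue PDB file written on the fly
write_mini_pdb <- function(path, drop_ca = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       3.988   2.835   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.504   2.695   0.000  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.030   1.583   0.000  1.00  0.00           O",
    "END")
  if (drop_ca) lines <- lines[-7] # GLY loses its CA
  writeLines(lines, path)
  path
}

# one-nucleotide RNA fixture
write_mini_rna_pdb <- function(path, drop_n3 = FALSE) {
  lines <- c(
    "ATOM      1  P     G A   1       0.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  O5'   G A   1       1.000   1.000   0.000  1.00  0.00           O",
    "ATOM      3  C4'   G A   1       2.500   1.500   0.500  1.00  0.00           C",
    "ATOM      4  N3    G A   1       4.200   3.100   1.200  1.00  0.00           N",
    "ATOM      5  N9    G A   1       3.600   2.500   1.000  1.00  0.00           N",
    "END")
  if (drop_n3) lines <- lines[-4]
  writeLines(lines, path)
  path
}

# numerical gradient of the total energy, central differences
numerical_forces <- function(system, pos, h = 1e-6) {
  num <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (d in 1:3) {
      p1 <- pos; p1[i, d] <- p1[i, d] + h
      p2 <- pos; p2[i, d] <- p2[i, d] - h
      num[i, d] <- -(cg_energy(system, p1)$energy -
                       cg_energy(system, p2)$energy) / (2 * h)
    }
  }
  num
}

# unimodality up to tolerance: one interior peak, rising before, falling after
is_unimodal_interior <- function(x, tol = 0) {
  k <- which.max(x)
  if (k == 1 || k == length(x)) return(FALSE)
  all(diff(x[1:k]) >= -tol) && all(diff(x[k:length(x)]) <= tol)
}
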
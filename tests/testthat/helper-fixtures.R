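# Shared helpers: small in-code fixtures used across test files.

# two-chain, two-residue PDB text written to a temp file
write_minimal_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.759   7.087  -4.916  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.164   7.818  -5.822  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      10.521   6.318  -4.136  1.00  0.00           C",
    "ATOM      6  N   GLY B   1      13.288   7.160  -3.700  1.00  0.00           N",
    "ATOM      7  CA  GLY B   1      14.359   8.081  -3.339  1.00  0.00           C",
    "ATOM      8  C   GLY B   1      15.402   7.430  -2.428  1.00  0.00           C",
    "ATOM      9  O   GLY B   1      15.201   6.324  -1.920  1.00  0.00           O",
    "HETATM   10  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "END"
  )
  writeLines(lines, path)
  path
}

# PDB with alternate conformers for one atom
write_altloc_pdb <- function(occ_a = 0.6, occ_b = 0.4,
                             path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.759   7.087  -4.916  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.164   7.818  -5.822  1.00  0.00           O",
    sprintf("ATOM      5  CB AALA A   1      10.521   6.318  -4.136%6.2f  0.00           C", occ_a),
    sprintf("ATOM      6  CB BALA A   1      10.411   6.318  -4.136%6.2f  0.00           C", occ_b),
    "ATOM      7  N   GLY B   2      13.288   7.160  -3.700  1.00  0.00           N",
    "ATOM      8  CA  GLY B   2      14.359   8.081  -3.339  1.00  0.00           C",
    "END"
  )
  writeLines(lines, path)
  path
}

# a toy 2-chain model of single-atom residues at given CA positions
toy_ca_model <- function(positions_a, positions_b = NULL) {
  res <- list()
  for (i in seq_len(nrow(positions_a)))
    res[[length(res) + 1]] <- ppiface:::point_residue("A", i, positions_a[i, ])
  if (!is.null(positions_b))
    for (i in seq_len(nrow(positions_b)))
      res[[length(res) + 1]] <- ppiface:::point_residue("B", i,
                                                        positions_b[i, ])
  ppiface:::fixture_model("toy", res)
}
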
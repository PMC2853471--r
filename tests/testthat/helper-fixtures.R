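# Shared fixtures, generated in code.

# tiny labeled chain set with a learnable center-residue rule:
# label 1 iff the center residue is in `signal_set`
center_rule_dataset <- function(n_chains = 30, L = 40,
                                signal_set = c("G", "Y", "T"), seed = 5) {
  set.seed(seed)
  ids <- sprintf("cr%02d", seq_len(n_chains))
  chains <- setNames(vapply(ids, function(i)
    paste(sample(aa_alphabet(FALSE), L, replace = TRUE), collapse = ""), ""), ids)
  labels <- lapply(chains, function(s)
    as.integer(strsplit(s, "")[[1]] %in% signal_set))
  list(chains = chains, labels = labels)
}

# two well-separated Gaussian blobs (linearly separable by construction:
# the gap between clusters is many standard deviations)
separable_blobs <- function(n = 30, d = 5, gap = 10, seed = 0) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * d, 0, 0.5), n),
             matrix(rnorm(n * d, gap, 0.5), n))
  list(x = x, y = rep(c(0L, 1L), each = n))
}

# minimal hand-laid PDB lines: one TYR with its OH 3.0 A from a NAD atom,
# one ALA with CB 20 A away, one GLY with CA 3.5 A away
toy_pdb_lines <- function() {
  c("ATOM      1  N   TYR A   1      -1.200  -0.900   0.000  1.00  0.00           N",
    "ATOM      2  CA  TYR A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   TYR A   1       1.200  -0.900   0.000  1.00  0.00           C",
    "ATOM      4  O   TYR A   1       1.200  -2.100   0.000  1.00  0.00           O",
    "ATOM      5  OH  TYR A   1       0.000   3.000   0.000  1.00  0.00           O",
    "ATOM      6  N   ALA A   2       2.600  -0.900   0.000  1.00  0.00           N",
    "ATOM      7  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      8  C   ALA A   2       5.000  -0.900   0.000  1.00  0.00           C",
    "ATOM      9  O   ALA A   2       5.000  -2.100   0.000  1.00  0.00           O",
    "ATOM     10  CB  ALA A   2       3.800 -20.000   0.000  1.00  0.00           C",
    "ATOM     11  N   GLY A   3       6.400  -0.900   0.000  1.00  0.00           N",
    "ATOM     12  CA  GLY A   3       7.600   2.500   0.000  1.00  0.00           C",
    "ATOM     13  C   GLY A   3       8.800  -0.900   0.000  1.00  0.00           C",
    "ATOM     14  O   GLY A   3       8.800  -2.100   0.000  1.00  0.00           O",
    "HETATM   15  PA  NAD A 101       0.000   6.000   0.000  1.00  0.00           P",
    "HETATM   16  O1  NAD A 101       7.600   6.000   0.000  1.00  0.00           O",
    "END")
}
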
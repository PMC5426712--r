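# shared fixtures: tiny hand-written PDB texts and toy builders

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

# a hand-written 3-atom PDB (C, N, O) with B-factors 10, 20, 30
pdb3_lines <- c(
  "ATOM      1  C   ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
  "ATOM      2  N   ALA A   1       1.500   0.000   0.000  1.00 20.00           N",
  "ATOM      3  O   ALA A   1       0.000   2.000   0.000  1.00 30.00           O",
  "END")

# two-model PDB of the same two atoms, second model translated
pdb2m_lines <- c(
  "MODEL        1",
  "ATOM      1  C   GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  O   GLY A   1       3.000   4.000   0.000  1.00  0.00           O",
  "ENDMDL",
  "MODEL        2",
  "ATOM      1  C   GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  O   GLY A   1       4.000   4.000   0.000  1.00  0.00           O",
  "ENDMDL",
  "END")

pdb_water_lines <- c(
  "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
  "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
  "END")

# point-atom structure at given coordinates (f == 1 under ff_point())
point_structure <- function(xyz, tau = NULL) {
  sas_structure(as.matrix(xyz), rep("X", nrow(as.matrix(xyz))), tau = tau)
}

# naive triple-loop Debye evaluation, the independent oracle for the
# vectorized implementation
debye_naive <- function(s, q, ff) {
  n <- n_atoms(s)
  F <- vapply(seq_len(n),
              function(k) effective_form_factor(s$element[k], q, ff),
              numeric(length(q)))
  F <- matrix(F, nrow = length(q))
  D <- as.matrix(dist(s$xyz))
  I <- numeric(length(q))
  for (iq in seq_along(q)) {
    acc <- 0
    for (k in seq_len(n)) for (l in seq_len(n)) {
      x <- q[iq] * D[k, l]
      acc <- acc + F[iq, k] * F[iq, l] * (if (x == 0) 1 else sin(x) / x)
    }
    I[iq] <- acc
  }
  I
}

random_rigid_motion <- function(s, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  out <- s
  out$xyz <- sweep(s$xyz %*% R, 2, rnorm(3, sd = 20), "+")
  out
}
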
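# Independent oracles and fixture builders used across the test suite.

# Brute-force chord-pattern invariant: explicit enumeration of strictly
# increasing index tuples. Independent of the cumulative-sum engine.
brute_invariant <- function(W, pattern) {
  chords <- pattern$chords
  abs_flags <- pattern$abs_flags
  n <- nrow(W)
  m <- 2L * length(chords)
  if (n < m) return(0)
  tups <- utils::combn(n, m)
  total <- 0
  for (ci in seq_len(ncol(tups))) {
    tup <- tups[, ci]
    p <- 1
    for (j in seq_along(chords)) {
      v <- W[tup[chords[[j]][1L]], tup[chords[[j]][2L]]]
      if (abs_flags[j]) v <- abs(v)
      p <- p * v
    }
    total <- total + p
  }
  total
}

# Random symmetric writhe-like matrix with the zero band on |i - j| <= 1.
rand_writhe_like <- function(n, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i, n)) {
      if (j - i >= 2L) W[i, j] <- W[j, i] <- stats::runif(1, -1, 1)
    }
  }
  W
}

# Signed Monte-Carlo estimate of the mutual Gauss integral of two segments:
# project along random directions, count crossings with handedness sign.
mc_segment_writhe <- function(a0, a1, b0, b1, m = 1e5, seed = 1) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * m), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  ref <- matrix(rep(c(1, 0, 0), each = m), ncol = 3)
  flip <- abs(u[, 1]) > 0.9
  ref[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), ncol = 3)
  e1 <- ref - u * rowSums(ref * u); e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
              u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
              u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
  P <- function(p) cbind(e1 %*% p, e2 %*% p)
  A0 <- P(a0); A1 <- P(a1); B0 <- P(b0); B1 <- P(b1)
  ort <- function(a, b, c) (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  o1 <- ort(A0, A1, B0); o2 <- ort(A0, A1, B1)
  o3 <- ort(B0, B1, A0); o4 <- ort(B0, B1, A1)
  cross <- o1 * o2 < 0 & o3 * o4 < 0
  d1 <- a1 - a0; d2 <- b1 - b0
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  vals <- numeric(m)
  w <- which(cross)
  if (length(w)) {
    dx1 <- A1[w, 1] - A0[w, 1]; dy1 <- A1[w, 2] - A0[w, 2]
    dx2 <- B1[w, 1] - B0[w, 1]; dy2 <- B1[w, 2] - B0[w, 2]
    den <- dx1 * dy2 - dy1 * dx2
    ss <- ((B0[w, 1] - A0[w, 1]) * dy2 - (B0[w, 2] - A0[w, 2]) * dx2) / den
    tt <- ((B0[w, 1] - A0[w, 1]) * dy1 - (B0[w, 2] - A0[w, 2]) * dx1) / den
    for (k in seq_along(w)) {
      x1 <- a0 + ss[k] * d1
      x2 <- b0 + tt[k] * d2
      vals[w[k]] <- sign(sum(cr * (x1 - x2)))
    }
  }
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(m))
}

# Minimal single-chain PDB fixture text: altloc pair on residue 2, residue 3
# has no C-alpha, two models.
tiny_pdb_lines <- function() {
  c("MODEL     1",
    "ATOM      1  CA  ALA A   1      11.000  12.000  13.000  1.00  0.00           C",
    "ATOM      2  CA AALA A   2      14.000  12.500  13.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   2      99.000  99.000  99.000  0.40  0.00           C",
    "ATOM      4  N   ALA A   3      15.000  15.000  15.000  1.00  0.00           N",
    "ATOM      5  CA  ALA A   4      17.000  13.000  13.500  1.00  0.00           C",
    "ATOM      6  CA  ALA A   5      19.500  14.000  15.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL     2",
    "ATOM      1  CA  ALA A   1      12.000  12.000  13.000  1.00  0.00           C",
    "ATOM      2  CA AALA A   2      14.000  12.500  13.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   2      99.000  99.000  99.000  0.40  0.00           C",
    "ATOM      4  N   ALA A   3      15.000  15.000  15.000  1.00  0.00           N",
    "ATOM      5  CA  ALA A   4      17.000  13.000  13.500  1.00  0.00           C",
    "ATOM      6  CA  ALA A   5      19.500  14.000  15.000  1.00  0.00           C",
    "ENDMDL", "END")
}

# The same four C-alpha positions (altloc resolved, residue 3 absent) as a
# minimal mmCIF atom_site loop.
tiny_cif_lines <- function() {
  c("data_tiny",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 11.000 12.000 13.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . ALA A 1 2 ? 14.000 12.500 13.000 1.00 0.00 ? 2 ALA A CA 1",
    "ATOM 3 C CA . ALA A 1 3 ? 17.000 13.000 13.500 1.00 0.00 ? 4 ALA A CA 1",
    "ATOM 4 C CA . ALA A 1 4 ? 19.500 14.000 15.000 1.00 0.00 ? 5 ALA A CA 1",
    "#")
}

rigid_motion <- function(coords, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(coords %*% q, 2, stats::runif(3, -20, 20), `+`)
}

mirror_z <- function(coords) {
  coords[, 3] <- -coords[, 3]
  coords
}
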
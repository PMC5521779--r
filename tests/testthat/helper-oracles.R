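# Independent oracles and shared fixture shortcuts for the test suite.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation-matrix dihedral oracle: rotate the frame so the central bond
# lies on +z (Rodrigues), project the outer bonds onto the xy-plane and
# take the planar signed angle, oriented so that looking from atom 2
# towards atom 3 a clockwise far bond is positive (IUPAC right-handed).
# Deliberately a different construction from the package's atan2 formula.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  b2 <- b2 / sqrt(sum(b2^2))
  z <- c(0, 0, 1)
  ax <- cross3(b2, z)
  s <- sqrt(sum(ax^2))
  co <- sum(b2 * z)
  R <- if (s < 1e-12) {
    if (co > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE) / s
    diag(3) + s * K + (1 - co) * (K %*% K)
  }
  u <- as.numeric(R %*% (p1 - p2))
  w <- as.numeric(R %*% (p4 - p3))
  ang <- atan2(u[2] * w[1] - u[1] * w[2], u[1] * w[1] + u[2] * w[2]) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Brute-force AUC: concordant-pair counting over all positive/negative
# score pairs, ties counted one half (Mann-Whitney).
oracle_auc <- function(truth, scores) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Shared synthetic half-life table (deterministic).
test_half_life <- function() synthetic_half_life_table(seed = 1)

# A small well-formed peptide with one interior Asn; B-factors vary so
# z-score normalization is well defined.
test_peptide_structure <- function(sequence = "GANGA", ...) {
  build_peptide_structure(peptide_spec(
    sequence, phi = -60, psi = -45, chi1 = -65, chi2 = -20,
    bfactor = function(n) seq(8, 45, length.out = n), ...))
}
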
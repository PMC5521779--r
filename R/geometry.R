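# Vector geometry shared by descriptor extraction and the peptide builder.

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by four points using the atan2
#' construction, with the IUPAC sign convention: 0 degrees is the
#' eclipsed (cis) arrangement, 180 degrees is trans, and the sign is
#' right-handed looking from the second to the third point.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (coordinates in Angstrom).
#' @return Angle in degrees in the half-open interval (-180, 180].
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)) # trans, 180
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) == 0 || vnorm(b2) == 0 || vnorm(b3) == 0) {
    stop("dihedral undefined: two consecutive points coincide")
  }
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("dihedral undefined: three consecutive points are collinear")
  }
  m1 <- vcross(n1, b2 / vnorm(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  # fold -180 onto +180 so the range is (-180, 180]
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place a fourth point D from reference points A, B, C such that
# |CD| = bond, angle(B, C, D) = angle (degrees) and dihedral(A, B, C, D) =
# torsion (degrees). Natural-extension reference frame; used by the
# synthetic peptide builder.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- vcross(ab, bc)
  if (vnorm(n) < 1e-10) stop("nerf_place: collinear reference atoms")
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Euclidean distance between two 3-vectors.
dist3 <- function(a, b) vnorm(a - b)
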
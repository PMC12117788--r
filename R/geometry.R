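# Internal 3D geometry primitives used by the structure builders.
# All coordinates are in Angstrom, all angles in degrees.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle defined by three points
#'
#' Returns the angle at `b` (degrees) of the triangle `a`-`b`-`c`.
#' @param a,b,c numeric 3-vectors (Angstrom).
#' @return Angle in degrees in `[0, 180]`.
#' @keywords internal
point_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ca <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(max(-1, min(1, ca))) * 180 / pi
}

#' Dihedral angle of four points
#'
#' Signed torsion a-b-c-d in degrees, IUPAC sign convention (the convention
#' under which the C-N-CA-CB improper of an L-amino acid is about -122.6).
#' @param a,b,c,d numeric 3-vectors.
#' @return Torsion in degrees in `(-180, 180]`.
#' @keywords internal
point_torsion <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  c1 <- cross3(b1, b2)
  c2 <- cross3(b2, b3)
  x <- sum(c1 * c2)
  y <- sum(cross3(c1, c2) * b2 / vec_norm(b2))
  atan2(y, x) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Positions a new atom `d` bonded to `c`, given the bond length `|c-d|`,
#' the angle `b-c-d` and the torsion `a-b-c-d`.
#'
#' @param a,b,c numeric 3-vectors of the three reference atoms.
#' @param bond bond length c-d in Angstrom.
#' @param angle angle b-c-d in degrees.
#' @param torsion torsion a-b-c-d in degrees.
#' @return numeric 3-vector: coordinates of the placed atom.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ch <- torsion * pi / 180
  bc <- unit_vec(c - b)
  n <- unit_vec(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
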
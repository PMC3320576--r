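# Vector geometry primitives.  Most functions are vectorized over rows so the
# enumeration engine can place one atom for many conformations in a single
# call: coordinate arguments are n x 3 matrices (or length-3 vectors, which
# are promoted to one-row matrices).

as_rowmat <- function(p) {
  if (is.matrix(p)) p else matrix(p, nrow = 1L)
}

row_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

row_dot <- function(a, b) {
  a[, 1L] * b[, 1L] + a[, 2L] * b[, 2L] + a[, 3L] * b[, 3L]
}

row_norm <- function(a) sqrt(row_dot(a, a))

row_unit <- function(a) a / row_norm(a)

#' Wrap angles into the canonical torsion range
#'
#' Maps arbitrary angles in degrees onto `[-180, 180)`; in particular `+180`
#' maps to `-180`.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in `[-180, 180)`.
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y >= 180] <- -180  # guard against floating residue of the modulus
  y
}

#' Measure a signed torsion angle
#'
#' Computes the dihedral angle defined by four points with the standard
#' biopolymer sign convention: looking down the `p2 -> p3` bond, the torsion
#' is the angle from the `p1` side to the `p4` side, positive clockwise, and
#' a cis (eclipsed) arrangement scores 0 degrees.  Reflecting all four points
#' through any plane negates the result.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors, or n x 3 matrices for a
#'   vectorized call (all four must then have the same number of rows).
#' @param check if `TRUE`, raise an error when either bonded triple is
#'   collinear (the torsion is then undefined).
#' @return torsion angle(s) in degrees, in `[-180, 180)`.
#' @export
measure_dihedral <- function(p1, p2, p3, p4, check = TRUE) {
  p1 <- as_rowmat(p1); p2 <- as_rowmat(p2)
  p3 <- as_rowmat(p3); p4 <- as_rowmat(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c1 <- row_cross(b1, b2)
  c2 <- row_cross(b2, b3)
  if (check) {
    eps <- 1e-10 * pmax(row_norm(b1) * row_norm(b2), 1e-12)
    if (any(row_norm(c1) <= eps) || any(row_norm(c2) <= 1e-10 * row_norm(b2) * row_norm(b3)))
      stop("undefined torsion: three consecutive points are collinear")
  }
  x <- row_dot(c1, c2)
  y <- row_dot(row_cross(c1, c2), b2 / row_norm(b2))
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Measure a bond angle
#'
#' @param p1,p2,p3 coordinates (vectors or n x 3 matrices); the angle is at
#'   `p2`.
#' @return angle(s) in degrees, in `[0, 180]`.
#' @export
measure_angle <- function(p1, p2, p3) {
  p1 <- as_rowmat(p1); p2 <- as_rowmat(p2); p3 <- as_rowmat(p3)
  u <- row_unit(p1 - p2)
  v <- row_unit(p3 - p2)
  acos(pmin(1, pmax(-1, row_dot(u, v)))) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF extension)
#'
#' Given three already-placed reference atoms A-B-C, positions a new atom D
#' bonded to C such that `|C-D| = bond`, the B-C-D angle equals `angle`, and
#' `measure_dihedral(A, B, C, D) == torsion`.
#'
#' @param A,B,C reference coordinates (vectors or n x 3 matrices).
#' @param bond bond length C-D in Angstrom (scalar or length-n).
#' @param angle bond angle B-C-D in degrees (scalar or length-n).
#' @param torsion dihedral A-B-C-D in degrees (scalar or length-n).
#' @return coordinates of D (n x 3 matrix, or a length-3 vector when all
#'   inputs were vectors).
#' @export
place_atom <- function(A, B, C, bond, angle, torsion) {
  vec_in <- !is.matrix(A) && !is.matrix(B) && !is.matrix(C)
  A <- as_rowmat(A); B <- as_rowmat(B); C <- as_rowmat(C)
  n <- max(nrow(A), nrow(B), nrow(C), length(torsion))
  if (nrow(A) == 1L && n > 1L) A <- A[rep(1L, n), , drop = FALSE]
  if (nrow(B) == 1L && n > 1L) B <- B[rep(1L, n), , drop = FALSE]
  if (nrow(C) == 1L && n > 1L) C <- C[rep(1L, n), , drop = FALSE]
  th <- angle * pi / 180
  ta <- torsion * pi / 180
  bc <- row_unit(C - B)
  nrm <- row_unit(row_cross(B - A, bc))
  m <- row_cross(nrm, bc)
  D <- C + bond * (-cos(th) * bc + sin(th) * (cos(ta) * m + sin(ta) * nrm))
  if (vec_in && n == 1L) drop(D) else D
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis length-3 direction vector (normalized internally).
#' @param theta rotation angle in degrees (right-handed about `axis`).
#' @return a 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  th <- theta * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * (u %o% u)
}

#' Reflect coordinates through a plane
#'
#' @param xyz n x 3 coordinate matrix (or length-3 vector).
#' @param normal plane normal (default the z axis, i.e. the xy-plane).
#' @param point a point on the plane (default the origin).
#' @return reflected coordinates, same shape as `xyz`.
#' @export
reflect_coords <- function(xyz, normal = c(0, 0, 1), point = c(0, 0, 0)) {
  vec_in <- !is.matrix(xyz)
  xyz <- as_rowmat(xyz)
  n <- normal / sqrt(sum(normal^2))
  d <- (xyz - matrix(point, nrow(xyz), 3L, byrow = TRUE)) %*% n
  out <- xyz - 2 * d %*% t(n)
  dimnames(out) <- dimnames(xyz)
  if (vec_in) drop(out) else out
}

# Random rigid motion helper used by invariance tests and fixtures.
random_isometry <- function(xyz, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- rotation_about_axis(ax, stats::runif(1, 0, 360))
  t0 <- stats::rnorm(3, sd = 5)
  xyz %*% t(R) + matrix(t0, nrow(xyz), 3L, byrow = TRUE)
}
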
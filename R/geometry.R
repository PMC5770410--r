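# Internal 3D vector geometry used throughout the package.
# All angles are in degrees; coordinates in Angstrom.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Normalize an angle in degrees to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector with every value wrapped into (-180, 180].
#' @export
normalize_angle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees about the (not necessarily unit)
#' vector `axis`, right-handed.
#'
#' @param axis length-3 numeric, rotation axis.
#' @param angle rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  th <- deg2rad(angle)
  c_ <- cos(th); s_ <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * (u %o% u)
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: cis (eclipsed) is 0 degrees, the angle is measured
#' looking from b to c, positive clockwise. Computed with the atan2 form,
#' which is numerically stable away from the collinear degeneracy.
#'
#' @param p1,p2,p3,p4 length-3 numeric positions (Angstrom).
#' @return signed dihedral in degrees, in (-180, 180].
#' @export
measure_torsion <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  n1 <- vnorm(b1)
  if (n1 < 1e-12) stop("undefined dihedral: coincident axis points")
  b1 <- b1 / n1
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  if (vnorm(v) < 1e-9 || vnorm(w) < 1e-9)
    stop("undefined dihedral: three consecutive points are collinear")
  x <- sum(v * w)
  y <- sum(cross3(b1, v) * w)
  normalize_angle(rad2deg(atan2(y, x)))
}

# NeRF atom placement: position a new atom d given positions of a, b, c,
# the bond length c-d, the angle b-c-d (deg) and the torsion a-b-c-d (deg).
place_atom <- function(a, b, c, length, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  d2 <- c(-length * cos(th),
          length * sin(th) * cos(ph),
          length * sin(th) * sin(ph))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d2 + c)
}
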
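# Unit-quaternion utilities (scalar-first convention, q = (w, x, y, z)).
# Rotations act on column vectors; quaternions q and -q are the same rotation.

#' Uniform random unit quaternions
#' @param n Number of quaternions.
#' @return `n x 4` matrix of unit quaternions.
#' @export
rand_quaternion <- function(n) {
  m <- matrix(rnorm(4 * n), ncol = 4)
  m / sqrt(rowSums(m^2))
}

#' Convert a unit quaternion to a rotation matrix
#' @param q Length-4 unit quaternion (w, x, y, z).
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#' @param R 3x3 rotation matrix.
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# quaternion product a * b
quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

# Geodesic rotation angle between rows of Q and a single quaternion q
quat_angle_to <- function(Q, q) {
  d <- abs(Q %*% q)
  d[d > 1] <- 1
  2 * acos(d)
}

#' Orientation of a 3-site water as a unit quaternion
#'
#' Builds the body frame of a water molecule (bisector along +z, hydrogens in
#' the xz plane, matching [water_geometry()]) and returns the rotation from
#' the canonical frame to the observed one.
#'
#' @param o,h1,h2 Length-3 coordinate vectors of O, H1, H2.
#' @export
water_orientation <- function(o, h1, h2) {
  b1 <- h1 - o; b2 <- h2 - o
  z <- b1 + b2; z <- z / sqrt(sum(z^2))
  x <- b1 - b2; x <- x - sum(x * z) * z; x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  matrix_to_quat(cbind(x, y, z))
}
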
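# Low-level vector and rotation helpers shared across the package.
# All rotations are proper (det = +1); angles are degrees at the API surface
# and radians internally.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

#' Normalize a 3-vector to unit length
#'
#' @param v numeric length-3 vector.
#' @return unit vector in the direction of `v`.
#' @keywords internal
unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-300) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Unsigned angle between two vectors, in radians, stable near 0 and pi.
vec_angle <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  atan2(vnorm(cross3(a, b)), sum(a * b))
}

# Angle between two lines (direction sign ignored), radians in [0, pi/2].
line_angle <- function(a, b) {
  ang <- vec_angle(a, b)
  min(ang, pi - ang)
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

rot_x <- function(rad) {
  c_ <- cos(rad); s_ <- sin(rad)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

rot_y <- function(rad) {
  c_ <- cos(rad); s_ <- sin(rad)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

rot_z <- function(rad) {
  c_ <- cos(rad); s_ <- sin(rad)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from intrinsic Z-Y-X Tait-Bryan angles
#'
#' Builds `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)`, the rotation convention used for
#' every joint coordinate system in the package: first rotation (rz,
#' flexion-extension) about the fixed-ACS Z, second (ry,
#' abduction-adduction) about the floating Y, third (rx, long-axis rotation)
#' about the mobile-ACS X.
#'
#' @param rz_deg,ry_deg,rx_deg rotation angles in degrees.
#' @return 3x3 rotation matrix.
#' @seealso [euler_zyx()] for the inverse.
#' @export
#' @examples
#' rot_zyx(30, 0, 0)  # pure flexion-extension of 30 degrees
rot_zyx <- function(rz_deg, ry_deg, rx_deg) {
  rot_z(rz_deg * DEG2RAD) %*% rot_y(ry_deg * DEG2RAD) %*% rot_x(rx_deg * DEG2RAD)
}

#' Intrinsic Z-Y-X Tait-Bryan angles of a rotation matrix
#'
#' Inverse of [rot_zyx()]. The second angle is restricted to the principal
#' range \[-90, 90\] degrees; at the gimbal singularity (|ry| = 90 within
#' tolerance) only the difference/sum of rz and rx is determined, so by
#' convention rx is reported as 0, rz carries the whole determined rotation,
#' and `gimbal` is set.
#'
#' @param R 3x3 rotation matrix.
#' @param gimbal_tol singularity threshold on |cos(ry)|.
#' @return list with `rz_deg`, `ry_deg`, `rx_deg`, `gimbal` (logical).
#' @export
euler_zyx <- function(R, gimbal_tol = 1e-8) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  sy <- clamp1(-R[3, 1])
  ry <- asin(sy)
  if (abs(cos(ry)) < gimbal_tol || 1 - abs(sy) < gimbal_tol^2) {
    # rz and rx axes collinear: report the determined combination as rz
    rz <- atan2(-R[1, 2], R[2, 2])
    rx <- 0
    gimbal <- TRUE
  } else {
    rz <- atan2(R[2, 1], R[1, 1])
    rx <- atan2(R[3, 2], R[3, 3])
    gimbal <- FALSE
  }
  list(rz_deg = rz * RAD2DEG, ry_deg = ry * RAD2DEG, rx_deg = rx * RAD2DEG,
       gimbal = gimbal)
}

# --- quaternions (w, x, y, z), unit, scalar-first -------------------------

quat_to_rot <- function(q) {
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / vnorm(q)
}

# Uniform random rotation (Shoemake's subgroup algorithm); consumes 3 draws
# from the session RNG.
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_to_rot(q)
}

#' Unwrap an angle time series across the +/-180 degree seam
#'
#' Kinematic time series decomposed frame-by-frame into principal-range Euler
#' angles can jump by ~360 degrees when the true motion crosses +/-180. This
#' adds or subtracts full turns so consecutive samples never differ by more
#' than 180 degrees. Raw principal values should be kept alongside; this is a
#' plotting/continuity convenience only.
#'
#' @param deg numeric vector of angles in degrees, in frame order.
#' @return numeric vector, same length, continuous across the seam.
#' @export
unwrap_deg <- function(deg) {
  if (length(deg) < 2) return(deg)
  d <- diff(deg)
  corr <- cumsum(round(d / 360)) * -360
  deg + c(0, corr)
}
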
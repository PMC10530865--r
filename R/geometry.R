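## Internal 3D geometry helpers: internal-coordinate atom placement (NeRF),
## torsion/angle measurement, rotations, and least-squares superposition.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three reference positions `a`, `b`, `c`, returns the position `d`
#' such that |c-d| = `bond`, the angle b-c-d equals `angle` (degrees) and the
#' torsion a-b-c-d equals `dihedral` (degrees).
#'
#' @param a,b,c numeric 3-vectors, reference positions.
#' @param bond bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral torsion a-b-c-d in degrees.
#' @return numeric 3-vector, the placed position.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- deg2rad(angle)
  tor <- deg2rad(dihedral)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Torsion a-b-c-d in degrees, in (-180, 180].
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

bond_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

## Rotation matrix for a unit quaternion (w, x, y, z).
quat_to_rot <- function(q) {
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

## Uniform random rotation matrices (Shoemake quaternion method); uses the
## current RNG stream, so determinism is controlled by the caller's seed.
random_rotations <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  lapply(seq_len(n), function(i) {
    q <- c(sqrt(1 - u1[i]) * sin(2 * pi * u2[i]),
           sqrt(1 - u1[i]) * cos(2 * pi * u2[i]),
           sqrt(u1[i]) * sin(2 * pi * u3[i]),
           sqrt(u1[i]) * cos(2 * pi * u3[i]))
    quat_to_rot(q)
  })
}

## Rotation about an arbitrary axis (Rodrigues), angle in degrees.
axis_rotation <- function(axis, angle) {
  u <- unit(axis)
  th <- deg2rad(angle)
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the rotation `R` and translation `t` minimising the RMSD between
#' `R %*% x + t` and `y` over paired coordinate rows.
#'
#' @param x,y n x 3 coordinate matrices (mobile and fixed, respectively).
#' @return list with `rotation` (3x3), `translation` (3-vector) and `rmsd`
#'   of the fit.
#' @keywords internal
kabsch_fit <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3, ncol(y) == 3)
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2, cx)
  y0 <- sweep(y, 2, cy)
  s <- svd(t(x0) %*% y0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cy - as.vector(R %*% cx)
  fitted <- sweep(x %*% t(R), 2, t_vec, "+")
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((fitted - y)^2))))
}

apply_transform <- function(xyz, transform) {
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
}
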
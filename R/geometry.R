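# Internal 3D geometry helpers shared by the structure generators, the
# elastic-network Hessians and the superposition code.

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

rot_z <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3L, 3L)
}

rot_x <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(1, 0, 0, 0, ct, st, 0, -st, ct), 3L, 3L)
}

rot_y <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, 0, -st, 0, 1, 0, st, 0, ct), 3L, 3L)
}

# Angle at b (radians) between vectors b->a and b->c.
calc_angle <- function(a, b, c) {
  u <- unit(a - b); v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v))))
}

# Signed dihedral a-b-c-d in radians, IUPAC sign convention.
calc_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (vec_norm(n1) < 1e-10 || vec_norm(n2) < 1e-10)
    stop("undefined dihedral: collinear atoms")
  atan2(sum(cross3(n1, n2) * unit(b2)), sum(n1 * n2))
}

# Natural extension reference frame: place atom D bonded to C with bond
# length r, angle B-C-D `ang` and torsion A-B-C-D `tors` (both radians).
nerf <- function(a, b, c, r, ang, tors) {
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-r * cos(ang), r * sin(ang) * cos(tors), r * sin(ang) * sin(tors))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Least-squares rigid superposition (Kabsch, reflection-guarded).
# Returns rotation R and translation t such that  Q %*% R + t  best fits P.
kabsch <- function(p, q) {
  if (nrow(p) != nrow(q)) stop("coordinate sets differ in size")
  if (nrow(p) < 3L) stop("need at least 3 points for superposition")
  cp <- colMeans(p); cq <- colMeans(q)
  pp <- sweep(p, 2L, cp); qq <- sweep(q, 2L, cq)
  s <- svd(crossprod(qq, pp))
  if (min(s$d) < 1e-12 && sum(s$d > 1e-8) < 2L)
    stop("degenerate (collinear) coordinates in superposition")
  d <- sign(det(s$u %*% t(s$v)))
  dm <- diag(c(1, 1, d))
  r <- s$u %*% dm %*% t(s$v)
  t0 <- cp - as.numeric(cq %*% r)
  list(rotation = r, translation = t0)
}

apply_rigid <- function(coords, rot, trans) {
  sweep(coords %*% rot, 2L, trans, "+")
}

# Random proper rotation from a seeded RNG stream.
random_rotation <- function() {
  m <- matrix(stats::rnorm(9L), 3L, 3L)
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) r <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  r
}

# Orthonormal rigid-body basis (3 translations + 3 rotations about the
# centroid) for a set of bead coordinates; 3N x 6 matrix.
rt_basis <- function(coords) {
  n <- nrow(coords)
  ctr <- colMeans(coords)
  x <- sweep(coords, 2L, ctr)
  basis <- matrix(0, 3L * n, 6L)
  for (k in 1:3) basis[seq(k, 3L * n, by = 3L), k] <- 1
  axes <- diag(3L)
  for (k in 1:3) {
    v <- t(apply(x, 1L, function(p) cross3(axes[k, ], p)))
    basis[, 3L + k] <- as.numeric(t(v))
  }
  qr.Q(qr(basis))[, 1:6, drop = FALSE]
}
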
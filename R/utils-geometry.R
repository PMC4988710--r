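## Small rigid-body geometry kit shared by the DNA builder, the restraint
## engine, docking and assembly. All rotations are right-handed, act on
## column vectors, and angles are in radians unless a function name says
## degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rotX <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rotY <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

rotZ <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

## Rotation of `angle` about an arbitrary unit axis (Rodrigues form).
rotAxis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Uniform random rotation via the quaternion method (Shoemake).
randomRotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

## n x 3 coordinate matrix transformed by rotation R (about the origin)
## then translation t.
transformCoords <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, t, "+")
}

vecNorm <- function(v) sqrt(sum(v^2))

unitVec <- function(v) v / vecNorm(v)

crossProd3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Angle between two vectors in degrees, in [0, 180].
vecAngleDeg <- function(a, b) {
  ct <- sum(a * b) / (vecNorm(a) * vecNorm(b))
  rad2deg(acos(max(-1, min(1, ct))))
}

## Dihedral angle p1-p2-p3-p4 in degrees, in (-180, 180].
dihedralDeg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- crossProd3(b1, b2)
  n2 <- crossProd3(b2, b3)
  m <- crossProd3(n1, unitVec(b2))
  -rad2deg(atan2(sum(m * n2), sum(n1 * n2)))
}

## Pairwise distance matrix between two coordinate sets (na x nb).
crossDist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * (a %*% t(b))
  sqrt(pmax(d2, 0))
}

## RMS deviation of points from their least-squares plane.
planeRms <- function(xyz) {
  x <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(x)
  sqrt(mean((x %*% sv$v[, 3])^2))
}

## Least-squares rigid superposition (Kabsch): rotation R and translation t
## such that  moving %*% t(R) + t  best fits `fixed`.
kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cf - R %*% cm))
}

## Root-mean-square coordinate deviation, no superposition.
rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

## Principal axis of a point cloud, oriented from the first toward the last
## point (so helix axes point N -> C).
principalAxis <- function(xyz) {
  x <- sweep(xyz, 2, colMeans(xyz))
  v <- svd(x)$v[, 1]
  if (sum(v * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) v <- -v
  unitVec(v)
}

## Evaluate an expression under a temporary RNG state seeded with `seed`,
## restoring the caller's state afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
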
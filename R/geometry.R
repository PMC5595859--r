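# Internal vector geometry helpers. All coordinates are in Angstrom,
# all angles in degrees.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize zero vector")
  v / n
}

## Angle at vertex b of the triangle a-b-c, in degrees [0, 180].
angle3 <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

## Angle between two direction vectors, degrees [0, 180].
vec_angle <- function(u, v) {
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

## Best-fit plane of an n x 3 coordinate matrix: returns centroid, unit
## normal (smallest-variance direction) and the maximal out-of-plane
## deviation of the points.
fit_plane <- function(xyz) {
  ctr <- unname(colMeans(xyz))
  centered <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(centered) / nrow(xyz), symmetric = TRUE)
  normal <- ev$vectors[, 3L]
  dev <- abs(centered %*% normal)
  list(centroid = ctr, normal = normal, max_dev = max(dev))
}

## Canonicalize the sign of a unit normal: positive component along +z,
## ties broken along +x then +y.
canonical_normal <- function(n, tol = 1e-6) {
  for (i in c(3L, 1L, 2L)) {
    if (abs(n[i]) > tol) {
      if (n[i] < 0) n <- -n
      return(n)
    }
  }
  n
}

## Pairwise Euclidean distances between rows of two coordinate matrices.
cross_dist <- function(a, b) {
  stopifnot(ncol(a) == 3L, ncol(b) == 3L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

## Apply a rigid motion (rotation matrix R, translation t) to an n x 3
## coordinate matrix. Exposed for invariance testing.
rigid_transform <- function(xyz, R, t) {
  sweep(xyz %*% t(R), 2, t, "+")
}

## Random rotation matrix from a seeded RNG stream (uniform via QR).
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_dec <- qr(m)
  R <- qr.Q(qr_dec)
  d <- diag(qr.R(qr_dec))
  R <- R %*% diag(sign(d))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
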
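# Independent oracles used to check the package implementations. Each is
# coded from a different construction than the function it verifies.

# Dihedral via explicit Rodrigues-rotation construction: rotate p1 about
# the p2->p3 axis until it falls in the half-plane of p4, reading off the
# signed rotation angle (positive = clockwise looking from p2 to p3).
oracle_dihedral <- function(p1, p2, p3, p4) {
  axis <- p3 - p2
  axis <- axis / sqrt(sum(axis^2))
  reject <- function(v) v - sum(v * axis) * axis
  a <- reject(p1 - p2)
  b <- reject(p4 - p3)
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  # signed angle of the rotation about +axis carrying a onto b
  ang <- atan2(sum(cross3_oracle(a, b) * axis), sum(a * b)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

cross3_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# planar angle via normalized dot product
oracle_planar <- function(p1, p2, p3) {
  u <- (p1 - p2) / sqrt(sum((p1 - p2)^2))
  v <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  acos(min(1, max(-1, sum(u * v)))) * 180 / pi
}

# periodic absolute error by brute-force shift minimisation
oracle_ae <- function(p, a) {
  min(abs(p - a + 360 * (-1:1)))
}

# Spearman via explicit average ranks then Pearson
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mean_x <- mean(rx); mean_y <- mean(ry)
  num <- sum((rx - mean_x) * (ry - mean_y))
  den <- sqrt(sum((rx - mean_x)^2) * sum((ry - mean_y)^2))
  num / den
}

# Optimal superposition RMSD via the quaternion (Horn) closed form:
# the largest eigenvalue of the 4x4 key matrix gives the optimal rotation
# without ever constructing it.
oracle_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  ac <- scale(a, scale = FALSE)
  bc <- scale(b, scale = FALSE)
  M <- t(ac) %*% bc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,      Szx - Sxz,      Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,     Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,      Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(ac^2) + sum(bc^2) - 2 * lam) / nrow(a)
  sqrt(max(0, msd))
}

# random rigid motion (proper rotation + translation)
random_rigid <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  list(R = R, t = rnorm(3, sd = 10))
}

transform_chain <- function(chain, rigid) {
  co <- chain$coords
  for (i in seq_len(dim(co)[1]))
    for (a in seq_len(4)) {
      p <- co[i, a, ]
      if (!anyNA(p)) co[i, a, ] <- as.numeric(rigid$R %*% p + rigid$t)
    }
  backbone_chain(chain$sequence, co, chain$chain_id)
}
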
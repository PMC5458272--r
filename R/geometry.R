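# Rigid-body geometry helpers shared by the structure, pharmacophore and
# screening modules. Coordinates are plain n x 3 matrices in Angstrom.

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping point set `P` onto `Q`.
#' Proper rotations only: no reflection is ever applied, so mirror-image
#' point sets keep a non-zero residual.
#'
#' @param P,Q numeric n x 3 matrices with matching row order.
#' @return list with `R` (3 x 3 rotation), `t` (translation applied after
#'   rotation), and `rmsd` of the superposed sets.
#' @keywords internal
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tv <- cq - as.vector(R %*% cp)
  Pr <- apply_rigid(P, R, tv)
  list(R = R, t = tv, rmsd = sqrt(mean(rowSums((Pr - Q)^2))))
}

apply_rigid <- function(X, R, t) {
  sweep(X %*% t(R), 2, -t)
}

rmsd_plain <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  sqrt(mean(rowSums((A - B)^2)))
}

# Best-fit RMSD after Kabsch superposition.
rmsd_fit <- function(A, B) kabsch(A, B)$rmsd

#' Dihedral angle in degrees for points p1-p2-p3-p4
#' @keywords internal
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix: angle in degrees about unit axis.
rotation_about_axis <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Unit normal of the best-fit plane through X (n >= 3 points).
plane_normal <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  s <- svd(Xc)
  unitv(s$v[, 3])
}

# Random proper rotation matrix (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

cdist <- function(A, B) {
  # pairwise Euclidean distances, nrow(A) x nrow(B)
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
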
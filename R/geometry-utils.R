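# Small rigid-body geometry helpers shared by the builders and the
# refinement moves. All coordinates are in Angstrom, right-handed frame.

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("zero-length vector where a direction is required")
  v / n
}

# Rodrigues rotation matrix for a rotation of `theta` radians about `axis`.
rotation3 <- function(axis, theta) {
  a <- unit3(axis)
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Rotate an n x 3 coordinate block about a pivot point.
rotate_about <- function(X, R, pivot) {
  sweep(sweep(X, 2, pivot) %*% t(R), 2, -pivot)
}

# Orthonormal frame completing a given z-like direction.
frame_from_axis <- function(axis, u_ref = NULL) {
  w <- unit3(axis)
  if (is.null(u_ref)) u_ref <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- u_ref - sum(u_ref * w) * w
  u <- unit3(u)
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  list(u = u, v = v, w = w)
}

# First principal axis of an n x 3 coordinate block (unit vector).
principal_axis <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 1)
  unit3(sv$v[, 1])
}

# Optimal (Kabsch) superposition RMSD of X onto Y (both n x 3, matched rows).
kabsch_rmsd <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- Xc %*% t(R)
  sqrt(mean(rowSums((fit - Yc)^2)))
}
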
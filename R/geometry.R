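# Internal 3D geometry helpers shared by the synthetic generator and the
# refinement engine.  All angles are in degrees at the interface.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) v / vnorm(v)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
# NeRF placement: position atom D given three reference atoms A-B-C, the
# C-D bond length, the B-C-D angle and the A-B-C-D dihedral (IUPAC sign).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  theta <- angle * pi / 180
  chi <- dihedral * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(theta),
         bond * sin(theta) * cos(chi),
         -bond * sin(theta) * sin(chi))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Signed dihedral a-b-c-d in degrees, IUPAC convention.
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

rotation_matrix <- function(axis, angle) {
  u <- unitv(axis)
  co <- cos(angle); si <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * co + si * ux + (1 - co) * (u %o% u)
}

# Kabsch: rigid transform (R, t) mapping point rows of P onto Q in the
# least-squares sense, proper rotation enforced.
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cq - as.numeric(R %*% cp))
}

apply_rigid <- function(X, R, t) {
  sweep(X %*% t(R), 2, t, "+")
}

# RMSD between two coordinate matrices after optimal superposition.
superposed_rmsd <- function(A, B) {
  tf <- kabsch_fit(A, B)
  A2 <- apply_rigid(A, tf$R, tf$t)
  sqrt(mean(rowSums((A2 - B)^2)))
}
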
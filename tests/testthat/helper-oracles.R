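# Independent oracles kept deliberately separate from the implementation
# paths they check.

# Horn's quaternion method for optimal rigid superposition: the RMSD after
# superposition follows from the largest eigenvalue of the 4x4 key matrix,
# an independent route from the SVD-based Kabsch implementation.
quaternion_rmsd <- function(p, q) {
  p <- sweep(p, 2, colMeans(p))
  q <- sweep(q, 2, colMeans(q))
  s <- crossprod(p, q)  # sum p_i q_i^T
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  key <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz
  ), nrow = 4, byrow = TRUE)
  lam <- max(eigen(key, symmetric = TRUE)$values)
  msd <- (sum(p^2) + sum(q^2) - 2 * lam) / nrow(p)
  sqrt(max(msd, 0))
}

# Random proper rotation matrix.
random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  qr_ <- qr(m)
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# Apply a frame-wide rigid motion to a structure frame.
rigid_move <- function(frame, rotation = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, shift, FUN = "+")
  frame$atoms$x <- xyz[, 1]
  frame$atoms$y <- xyz[, 2]
  frame$atoms$z <- xyz[, 3]
  frame
}

# Analytic Yukawa force magnitude in kT/A between charges q1, q2 at
# distance r in a solvent dielectric with screening kappa.
yukawa_force_mag <- function(q1, q2, r, eps, kappa, temperature = 310) {
  332.0637 * abs(q1 * q2) * exp(-kappa * r) * (1 + kappa * r) /
    (eps * r^2) / (0.0019872041 * temperature)
}

# Build a 2-atom charged-pair trajectory with prescribed per-frame
# separations along x.
pair_trajectory <- function(separations, q1 = 1, q2 = -1,
                            frame_interval = 0.1) {
  at <- data.frame(
    serial = 1:2, name = c("Q1", "Q2"), resname = "ION",
    chain = c("A", "B"), resno = 1:2,
    mass = 22.99, charge = c(q1, q2), radius = 1.5,
    lj_epsilon = 0.1, lj_rmin_half = 1.5,
    stringsAsFactors = FALSE)
  n_fr <- length(separations)
  coords <- array(0, dim = c(2, 3, n_fr))
  for (k in seq_len(n_fr)) coords[2, 1, k] <- separations[k]
  trajectory(at, coords, seq_len(n_fr) * frame_interval)
}

sel_chain_a <- selection("A", chain = "A")
sel_chain_b <- selection("B", chain = "B")
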
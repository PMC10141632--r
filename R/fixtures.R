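# Synthetic-structure generators. Each fixture is built so the downstream
# statistic has a closed-form or brute-force oracle: rigid pseudo-domains
# make cleft statistics exact, controlled donor-H-acceptor geometry probes
# the hydrogen-bond cutoffs, point charges and Born spheres give analytic
# electrostatics. Atoms carry full parameter sets (mass, charge, radius, LJ)
# so every analysis runs without external tables.

# Rigid 4-atom tetrahedral pseudo-domain template, centroid at the origin.
# Equal masses, so the mass center is the centroid (exact).
domain_template <- function(resname, chain, resno, serial0) {
  local <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 0.75
  data.frame(
    serial = serial0 + seq_len(4) - 1L,
    name = paste0("C", 1:4),
    resname = resname,
    chain = chain,
    resno = resno,
    x = local[, 1], y = local[, 2], z = local[, 3],
    mass = 12.011,
    charge = 0,
    radius = 1.70,
    lj_epsilon = 0.11,
    lj_rmin_half = 2.00,
    stringsAsFactors = FALSE
  )
}

#' Two rigid pseudo-domains with prescribed mass-center distance fluctuations
#'
#' Generates a trajectory of two rigid tetrahedral pseudo-domains whose
#' mass-center distance is drawn per frame from a Normal distribution
#' truncated to positive values (by resampling, which leaves the mean
#' essentially unbiased when `sd` is small relative to `mean_distance`).
#' Because the domains are internally rigid, the cleft-size series computed
#' downstream equals the generator's draws exactly; they are stored in the
#' returned object as `$meta$draws` for oracle checks.
#'
#' @param n_frames Number of frames (>= 1).
#' @param frame_interval Time between frames in ns (> 0); frames are stamped
#'   `frame_interval, 2*frame_interval, ...`.
#' @param mean_distance Target mean mass-center distance in Angstrom (> 0).
#' @param sd Standard deviation of the per-frame distance in Angstrom (>= 0).
#' @param seed Integer seed; the same spec and seed reproduce the
#'   trajectory to full precision.
#' @return A `trajectory` with 8 atoms (two 4-atom domains, chains A and B).
#' @export
make_two_domain_trajectory <- function(n_frames, frame_interval = 0.1,
                                       mean_distance = 10, sd = 0.5,
                                       seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (mean_distance <= 0) stop("mean_distance must be positive")
  if (sd < 0) stop("sd must be non-negative")

  draws <- with_seed(seed, {
    d <- stats::rnorm(n_frames, mean_distance, sd)
    while (any(bad <- d <= 0)) {
      d[bad] <- stats::rnorm(sum(bad), mean_distance, sd)
    }
    d
  })

  dom_a <- domain_template("DMA", "A", 1L, 1L)
  dom_b <- domain_template("DMB", "B", 2L, 5L)
  atoms <- rbind(dom_a, dom_b)

  base <- as.matrix(atoms[, c("x", "y", "z")])
  coords <- array(0, dim = c(nrow(atoms), 3, n_frames))
  for (k in seq_len(n_frames)) {
    xyz <- base
    xyz[5:8, 1] <- xyz[5:8, 1] + draws[k]   # domain B centroid at (d_k, 0, 0)
    coords[, , k] <- xyz
  }

  traj <- trajectory(atoms, coords, seq_len(n_frames) * frame_interval)
  traj$meta <- list(kind = "two_domain", seed = seed, draws = draws,
                    mean_distance = mean_distance, sd = sd)
  traj
}

# Donor/acceptor residue templates for hydrogen-bond fixtures.
hbond_atoms <- function(n_pos, h_pos, o_pos) {
  data.frame(
    serial = 1:3,
    name = c("N", "HN", "O"),
    resname = c("DON", "DON", "ACC"),
    chain = "A",
    resno = c(1L, 1L, 2L),
    x = c(n_pos[1], h_pos[1], o_pos[1]),
    y = c(n_pos[2], h_pos[2], o_pos[2]),
    z = c(n_pos[3], h_pos[3], o_pos[3]),
    mass = c(14.007, 1.008, 15.999),
    charge = c(-0.47, 0.31, -0.51),
    radius = c(1.55, 1.20, 1.52),
    lj_epsilon = c(0.20, 0.046, 0.12),
    lj_rmin_half = c(1.85, 0.2245, 1.70),
    stringsAsFactors = FALSE
  )
}

#' Donor-H-acceptor triple at controlled geometry
#'
#' Places a donor nitrogen at the origin, an acceptor oxygen at exactly
#' `d_DA` Angstrom along x, and the donor hydrogen at 1.0 Angstrom from the
#' nitrogen such that the D-H vector deviates from the D->A direction by
#' exactly `dev_angle` degrees. Used to probe the hydrogen-bond distance and
#' angle cutoffs on either side.
#'
#' @param d_DA Donor-acceptor distance in Angstrom (> 1).
#' @param dev_angle Deviation of D-H from D->A collinearity in degrees
#'   (0 <= dev_angle < 90).
#' @return A 3-atom `structure_frame`.
#' @export
make_hbond_triple <- function(d_DA, dev_angle = 0) {
  if (d_DA <= 1.0) stop("d_DA must exceed 1 Angstrom")
  if (dev_angle < 0 || dev_angle >= 90) stop("dev_angle must be in [0, 90)")
  th <- dev_angle * pi / 180
  h <- c(cos(th), sin(th), 0)
  structure_frame(hbond_atoms(c(0, 0, 0), h, c(d_DA, 0, 0)))
}

#' Charged nitrogen-oxygen pair at an exact separation
#'
#' A lysine-like ammonium nitrogen (NZ, +1e) and a glutamate-like
#' carboxylate oxygen (OE1, -1e) placed on the x-axis at exactly `d_NO`
#' Angstrom, for probing the salt-bridge distance cutoff.
#'
#' @param d_NO Nitrogen-oxygen distance in Angstrom (> 1).
#' @return A 2-atom `structure_frame`.
#' @export
make_salt_bridge_pair <- function(d_NO) {
  if (d_NO <= 1.0) stop("d_NO must exceed 1 Angstrom")
  structure_frame(data.frame(
    serial = 1:2,
    name = c("NZ", "OE1"),
    resname = c("LYS", "GLU"),
    chain = "A",
    resno = c(1L, 2L),
    x = c(0, d_NO), y = 0, z = 0,
    mass = c(14.007, 15.999),
    charge = c(1, -1),
    radius = c(1.85, 1.70),
    lj_epsilon = c(0.20, 0.12),
    lj_rmin_half = c(1.85, 1.70),
    stringsAsFactors = FALSE
  ))
}

#' Two point charges on the x-axis
#'
#' The textbook configuration for which the screened and unscreened Coulomb
#' force has a closed form; the two atoms sit on separate chains so they can
#' be addressed as two selections.
#'
#' @param q1,q2 Charges in units of e.
#' @param separation Distance in Angstrom (> 0).
#' @return A 2-atom `structure_frame`.
#' @export
make_point_charge_pair <- function(q1, q2, separation) {
  if (separation <= 0) stop("separation must be positive")
  structure_frame(data.frame(
    serial = 1:2,
    name = c("Q1", "Q2"),
    resname = "ION",
    chain = c("A", "B"),
    resno = c(1L, 2L),
    x = c(0, separation), y = 0, z = 0,
    mass = 22.99,
    charge = c(q1, q2),
    radius = 1.50,
    lj_epsilon = 0.10,
    lj_rmin_half = 1.50,
    stringsAsFactors = FALSE
  ))
}

#' Single charged sphere at the origin
#'
#' The Born ion: one atom of charge `q` and radius `radius` at the origin.
#' Its polar solvation energy has the closed form
#' \eqn{-\frac{332.0637\, q^2}{2a}\left(\frac{1}{\epsilon_{in}} -
#' \frac{1}{\epsilon_{out}}\right)} kcal/mol, the oracle for the
#' Poisson-Boltzmann solver.
#'
#' @param q Charge in e.
#' @param radius Sphere radius in Angstrom (> 0).
#' @return A 1-atom `structure_frame`.
#' @export
make_born_sphere <- function(q, radius) {
  if (radius <= 0) stop("radius must be positive")
  structure_frame(data.frame(
    serial = 1L, name = "Q1", resname = "ION", chain = "A", resno = 1L,
    x = 0, y = 0, z = 0,
    mass = 22.99, charge = q, radius = radius,
    lj_epsilon = 0.10, lj_rmin_half = radius,
    stringsAsFactors = FALSE
  ))
}

#' Analytic Born solvation energy
#'
#' @param q Charge in e.
#' @param radius Sphere radius in Angstrom.
#' @param eps_in,eps_out Interior and exterior dielectric constants.
#' @return Energy in kcal/mol.
#' @export
born_energy <- function(q, radius, eps_in = 2, eps_out = 80) {
  -(.ke * q^2 / (2 * radius)) * (1 / eps_in - 1 / eps_out)
}

#' Trajectory with a prescribed per-frame contact pattern
#'
#' A donor-H-acceptor triple whose donor-acceptor distance is 2.9 Angstrom
#' (well inside the hydrogen-bond criterion, collinear) in frames flagged
#' `TRUE` and 6.0 Angstrom otherwise, so the occupancy of the pair equals
#' `100 * mean(mask)` by construction.
#'
#' @param mask Logical vector, one entry per frame (non-empty).
#' @param frame_interval Time between frames in ns.
#' @return A `trajectory` of 3 atoms with `length(mask)` frames.
#' @export
make_occupancy_trajectory <- function(mask, frame_interval = 0.1) {
  if (!length(mask)) stop("mask must be non-empty")
  mask <- as.logical(mask)
  if (any(is.na(mask))) stop("mask must not contain NA")
  atoms <- hbond_atoms(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  n_fr <- length(mask)
  coords <- array(0, dim = c(3, 3, n_fr))
  base <- as.matrix(atoms[, c("x", "y", "z")])
  for (k in seq_len(n_fr)) {
    xyz <- base
    xyz[3, 1] <- if (mask[k]) 2.9 else 6.0
    coords[, , k] <- xyz
  }
  traj <- trajectory(atoms, coords, seq_len(n_fr) * frame_interval)
  traj$meta <- list(kind = "occupancy_mask", mask = mask)
  traj
}
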
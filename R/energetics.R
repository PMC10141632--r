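# MM/PBSA machinery: E = E_c + E_v + E_p + E_np per entity, and the
# single-trajectory binding free energy
# dE_bind = E(complex) - E(part A) - E(part B), with parts cut unchanged
# from each complex frame. E_np is affine in the solvent-accessible
# surface area: E_np = alpha * SASA + beta.

#' Inter-selection Coulomb energy
#'
#' \eqn{\sum_{i \in A, j \in B} k_e q_i q_j / (\epsilon r_{ij})} in
#' kcal/mol.
#'
#' @param frame A `structure_frame` with charges assigned.
#' @param selA,selB Disjoint selections.
#' @param dielectric Uniform dielectric constant (default 1).
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(frame, selA, selB, dielectric = 1) {
  ia <- resolve_selection(frame, selA)
  ib <- resolve_selection(frame, selB)
  if (length(intersect(ia, ib))) stop("selections overlap")
  q <- frame$atoms$charge
  if (anyNA(q[c(ia, ib)])) stop("charges not assigned on all selected atoms")
  xyz <- coords_matrix(frame)
  e <- 0
  for (j in ib) {
    dv <- sweep(xyz[ia, , drop = FALSE], 2, xyz[j, ])
    r <- sqrt(rowSums(dv^2))
    if (any(r < 1e-12)) stop("coincident atoms (r = 0)")
    e <- e + sum(.ke * q[ia] * q[j] / (dielectric * r))
  }
  e
}

# All-pairs Coulomb within one selection (intra-entity term of Eq-style
# entity energies; cancels exactly in binding differences).
coulomb_energy_intra <- function(frame, sel, dielectric = 1) {
  idx <- resolve_selection(frame, sel)
  if (length(idx) < 2) return(0)
  q <- frame$atoms$charge[idx]
  xyz <- coords_matrix(frame)[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  e <- 0
  for (i in seq_len(length(idx) - 1)) {
    for (j in (i + 1):length(idx)) {
      e <- e + .ke * q[i] * q[j] / (dielectric * d[i, j])
    }
  }
  e
}

#' Inter-selection Lennard-Jones energy
#'
#' CHARMM-form 12-6 potential
#' \eqn{\sum \epsilon_{ij}[(R_{min,ij}/r)^{12} - 2 (R_{min,ij}/r)^6]} with
#' Lorentz-Berthelot combination (geometric-mean well depth, arithmetic sum
#' of Rmin/2).
#'
#' @param frame A `structure_frame` with LJ parameters assigned.
#' @param selA,selB Disjoint selections.
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(frame, selA, selB) {
  ia <- resolve_selection(frame, selA)
  ib <- resolve_selection(frame, selB)
  if (length(intersect(ia, ib))) stop("selections overlap")
  eps <- frame$atoms$lj_epsilon
  rm2 <- frame$atoms$lj_rmin_half
  if (anyNA(eps[c(ia, ib)]) || anyNA(rm2[c(ia, ib)])) {
    stop("LJ parameters not assigned on all selected atoms")
  }
  xyz <- coords_matrix(frame)
  e <- 0
  for (j in ib) {
    dv <- sweep(xyz[ia, , drop = FALSE], 2, xyz[j, ])
    r <- sqrt(rowSums(dv^2))
    eij <- sqrt(eps[ia] * eps[j])
    rij <- rm2[ia] + rm2[j]
    sr6 <- (rij / r)^6
    e <- e + sum(eij * (sr6^2 - 2 * sr6))
  }
  e
}

lj_energy_intra <- function(frame, sel) {
  idx <- resolve_selection(frame, sel)
  if (length(idx) < 2) return(0)
  eps <- frame$atoms$lj_epsilon[idx]
  rm2 <- frame$atoms$lj_rmin_half[idx]
  xyz <- coords_matrix(frame)[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  e <- 0
  for (i in seq_len(length(idx) - 1)) {
    for (j in (i + 1):length(idx)) {
      sr6 <- ((rm2[i] + rm2[j]) / d[i, j])^6
      e <- e + sqrt(eps[i] * eps[j]) * (sr6^2 - 2 * sr6)
    }
  }
  e
}

# Deterministic near-uniform unit-sphere points (golden-spiral / Fibonacci
# lattice), so SASA is reproducible at fixed n_points.
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the atomic spheres by sampling `n_points`
#' near-uniform points on each atom's expanded sphere (radius + probe) and
#' counting the fraction not occluded by any neighbor's expanded sphere.
#'
#' @param frame A `structure_frame` with radii assigned.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sample points per atom (>= 100; default 1000, giving
#'   about 1% accuracy on an isolated sphere).
#' @return A list of class `sasa_result`: `per_atom` (Angstrom^2),
#'   `total`, `probe_radius`, `n_sphere_points`.
#' @export
sasa <- function(frame, probe = 1.4, n_points = 1000) {
  if (n_points < 100) stop("n_points must be >= 100")
  a <- frame$atoms
  if (anyNA(a$radius)) stop("radii must be assigned for SASA")
  n_at <- nrow(a)
  xyz <- coords_matrix(frame)
  rext <- a$radius + probe
  pts <- sphere_points(n_points)
  per <- numeric(n_at)
  for (i in seq_len(n_at)) {
    surf <- sweep(pts * rext[i], 2, xyz[i, ], FUN = "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n_at)) {
      if (j == i) next
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij >= rext[i] + rext[j]) next
      d2 <- rowSums(sweep(surf, 2, xyz[j, ])^2)
      free <- free & d2 >= rext[j]^2
      if (!any(free)) break
    }
    per[i] <- 4 * pi * rext[i]^2 * mean(free)
  }
  structure(list(per_atom = per, total = sum(per), probe_radius = probe,
                 n_sphere_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA %.2f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$per_atom), x$probe_radius,
              x$n_sphere_points))
  invisible(x)
}

#' SASA-linear nonpolar solvation model
#'
#' `E_np = slope * SASA + intercept`, with the conventional surface-tension
#' coefficient 0.0054 kcal/(mol Angstrom^2) and offset 0.92 kcal/mol.
#'
#' @param slope kcal/mol per Angstrom^2 (default 0.0054).
#' @param intercept kcal/mol (default 0.92).
#' @return An object of class `nonpolar_model`.
#' @export
nonpolar_model <- function(slope = 0.0054, intercept = 0.92) {
  structure(list(slope = slope, intercept = intercept),
            class = "nonpolar_model")
}

#' Nonpolar solvation energy from a SASA total
#'
#' @param sasa_total Total SASA in Angstrom^2 (>= 0), or a `sasa_result`.
#' @param model A `nonpolar_model`.
#' @return Energy in kcal/mol.
#' @export
nonpolar_energy <- function(sasa_total, model = nonpolar_model()) {
  if (inherits(sasa_total, "sasa_result")) sasa_total <- sasa_total$total
  if (sasa_total < 0) stop("SASA must be non-negative")
  model$slope * sasa_total + model$intercept
}

#' Polar solvation energy from the Poisson-Boltzmann solver
#'
#' Reaction-field energy
#' \eqn{\frac{1}{2}\sum_i q_i [\phi_{solv}(r_i) - \phi_{ref}(r_i)]}: the
#' solvated state uses the two-dielectric cavity (solute/solvent
#' dielectrics and screening from `medium`), the reference a homogeneous
#' solute-dielectric medium with no salt. Both solves share the identical
#' grid and charge discretization, so the grid self-energy cancels in the
#' difference. The Born ion provides the closed-form oracle.
#'
#' @param frame A `structure_frame` with charges and radii assigned.
#' @param medium An `ionic_medium`.
#' @param grid A `grid_spec`.
#' @return Energy in kcal/mol.
#' @export
polar_solvation <- function(frame, medium = ionic_medium(),
                            grid = grid_spec()) {
  if (all(frame$atoms$charge == 0)) return(0)
  solv <- solve_lpb(frame, medium, grid)
  ref_medium <- ionic_medium(
    solvent_dielectric = medium$solute_dielectric,
    solute_dielectric = medium$solute_dielectric,
    ionic_strength_mM = 0,
    temperature = medium$temperature)
  ref <- solve_lpb(frame, ref_medium, grid)
  kt <- kT_kcal(medium$temperature)
  0.5 * kt * sum(solv$qgrid * (solv$phi - ref$phi))
}

#' Full energy breakdown of one entity
#'
#' `E = E_c + E_v + E_p + E_np` for the atoms of `sel` taken in isolation:
#' all-pairs Coulomb and Lennard-Jones within the selection, plus
#' Poisson-Boltzmann polar and SASA-linear nonpolar solvation of the
#' extracted entity.
#'
#' @param frame A `structure_frame` with full parameters assigned.
#' @param sel Selection defining the entity; `NULL` uses all atoms.
#' @param medium An `ionic_medium`.
#' @param grid A `grid_spec`.
#' @param model A `nonpolar_model`.
#' @param coulomb_dielectric Dielectric used in `E_c` (default the
#'   medium's solute dielectric).
#' @param sasa_points Sphere points for the SASA term.
#' @return A list of class `energy_breakdown`: `coulomb`, `vdw`, `polar`,
#'   `nonpolar`, `total` (kcal/mol).
#' @export
energy_breakdown <- function(frame, sel = NULL, medium = ionic_medium(),
                             grid = grid_spec(), model = nonpolar_model(),
                             coulomb_dielectric = medium$solute_dielectric,
                             sasa_points = 500) {
  idx <- if (is.null(sel)) seq_len(n_atoms(frame)) else
    resolve_selection(frame, sel)
  sub <- subset_frame(frame, idx)
  ec <- coulomb_energy_intra(sub, seq_len(n_atoms(sub)), coulomb_dielectric)
  ev <- lj_energy_intra(sub, seq_len(n_atoms(sub)))
  ep <- polar_solvation(sub, medium, grid)
  enp <- nonpolar_energy(sasa(sub, n_points = sasa_points), model)
  structure(list(coulomb = ec, vdw = ev, polar = ep, nonpolar = enp,
                 total = ec + ev + ep + enp),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "E_c %.4f + E_v %.4f + E_p %.4f + E_np %.4f = %.4f kcal/mol\n",
    x$coulomb, x$vdw, x$polar, x$nonpolar, x$total))
  invisible(x)
}

#' Single-trajectory MM/PBSA binding free energy
#'
#' For every frame in the window, the two parts are extracted unchanged
#' from the complex frame and
#' `dE = E(complex) - E(A) - E(B)` is evaluated term by term. The
#' intra-part Coulomb and Lennard-Jones contributions cancel exactly in
#' the difference, leaving the inter-part terms plus the desolvation
#' (`dE_p`) and surface-burial (`dE_np`) contributions; the nonpolar
#' intercept is applied once per entity, so `dE_np = slope * dSASA -
#' intercept`. The record reports the mean and SD over the window frames.
#'
#' @param traj A `trajectory` with full parameters assigned.
#' @param partA,partB Disjoint selections that together form the complex.
#' @param medium An `ionic_medium`.
#' @param grid A `grid_spec`.
#' @param model A `nonpolar_model`.
#' @param t_start,t_end Analysis window in ns, half-open `(t_start, t_end]`.
#' @param coulomb_dielectric Dielectric for the Coulomb term (default the
#'   medium's solute dielectric, 2).
#' @param sasa_points Sphere points per atom for the SASA terms.
#' @return A list of class `binding_energy_record`: `delta_e` (mean),
#'   `sd`, per-term mean deltas, `n_frames`, and the per-frame table.
#' @export
mmpbsa_binding <- function(traj, partA, partB, medium = ionic_medium(),
                           grid = grid_spec(), model = nonpolar_model(),
                           t_start = -Inf, t_end = Inf,
                           coulomb_dielectric = medium$solute_dielectric,
                           sasa_points = 500) {
  ia <- resolve_selection(traj, partA)
  ib <- resolve_selection(traj, partB)
  if (length(intersect(ia, ib))) stop("the two parts overlap")
  keep <- which(traj$times > t_start & traj$times <= t_end)
  if (!length(keep)) stop("no frames fall in the window")
  rows <- list()
  for (k in keep) {
    fr <- get_frame(traj, k)
    icx <- sort(c(ia, ib))
    e_cx <- energy_breakdown(fr, icx, medium, grid, model,
                             coulomb_dielectric, sasa_points)
    e_a <- energy_breakdown(fr, ia, medium, grid, model,
                            coulomb_dielectric, sasa_points)
    e_b <- energy_breakdown(fr, ib, medium, grid, model,
                            coulomb_dielectric, sasa_points)
    rows[[length(rows) + 1]] <- data.frame(
      time_ns = traj$times[k],
      d_coulomb = e_cx$coulomb - e_a$coulomb - e_b$coulomb,
      d_vdw = e_cx$vdw - e_a$vdw - e_b$vdw,
      d_polar = e_cx$polar - e_a$polar - e_b$polar,
      d_nonpolar = e_cx$nonpolar - e_a$nonpolar - e_b$nonpolar,
      delta_e = e_cx$total - e_a$total - e_b$total)
  }
  tab <- do.call(rbind, rows)
  structure(list(
    delta_e = mean(tab$delta_e),
    sd = if (nrow(tab) > 1) stats::sd(tab$delta_e) else 0,
    d_coulomb = mean(tab$d_coulomb), d_vdw = mean(tab$d_vdw),
    d_polar = mean(tab$d_polar), d_nonpolar = mean(tab$d_nonpolar),
    n_frames = nrow(tab), window = c(t_start, t_end), per_frame = tab
  ), class = "binding_energy_record")
}

#' @export
print.binding_energy_record <- function(x, ...) {
  cat(sprintf(
    "dE_bind = %.4f +/- %.4f kcal/mol over %d frames (dE_c %.4f, dE_v %.4f, dE_p %.4f, dE_np %.4f)\n",
    x$delta_e, x$sd, x$n_frames,
    x$d_coulomb, x$d_vdw, x$d_polar, x$d_nonpolar))
  invisible(x)
}
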
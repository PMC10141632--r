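# Inter-selection electrostatic forces in an ionic medium, and their
# decomposition into a binding component (projection onto the mass-center
# connection line; positive = attraction) and a sliding component
# (perpendicular remainder): F_binding = |F_T| cos(alpha),
# F_sliding = |F_T| sin(alpha).

#' Ionic solvent medium
#'
#' Dielectric and screening environment for electrostatics. The inverse
#' Debye length is always recomputed from the fields via [debye_kappa()],
#' never stored, so it cannot go stale.
#'
#' @param solvent_dielectric Relative permittivity of the solvent
#'   (default 80, water).
#' @param solute_dielectric Relative permittivity inside the solute
#'   (default 2, protein interior).
#' @param ionic_strength_mM Ionic strength of a 1:1 electrolyte in mmol/L
#'   (default 150, physiological KCl).
#' @param temperature Temperature in K (default 310).
#' @return An object of class `ionic_medium`.
#' @export
ionic_medium <- function(solvent_dielectric = 80, solute_dielectric = 2,
                         ionic_strength_mM = 150, temperature = 310) {
  if (solvent_dielectric < 1 || solute_dielectric < 1) {
    stop("dielectric constants must be >= 1")
  }
  if (ionic_strength_mM < 0) stop("ionic strength must be non-negative")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(solvent_dielectric = solvent_dielectric,
                 solute_dielectric = solute_dielectric,
                 ionic_strength_mM = ionic_strength_mM,
                 temperature = temperature),
            class = "ionic_medium")
}

#' Inverse Debye screening length
#'
#' \eqn{\kappa^2 = 8\pi k_e I / (\epsilon_s k_B T)} with the ionic strength
#' `I` converted to a number density in 1/Angstrom^3 (both ion species of a
#' 1:1 salt counted). At the defaults (150 mM, 310 K, eps 80) the Debye
#' length 1/kappa is about 8 Angstrom.
#'
#' @param medium An `ionic_medium`.
#' @return kappa in 1/Angstrom; exactly 0 at zero ionic strength.
#' @export
debye_kappa <- function(medium) {
  if (medium$ionic_strength_mM == 0) return(0)
  n_i <- medium$ionic_strength_mM / 1000 * .mol_per_L_to_per_A3
  sqrt(8 * pi * .ke * n_i /
         (medium$solvent_dielectric * kT_kcal(medium$temperature)))
}

#' Screened electrostatic force between two selections
#'
#' Sum over inter-selection atom pairs of the Yukawa (Debye-Hueckel
#' screened Coulomb) force in the solvent dielectric,
#' \eqn{k_e q_i q_j e^{-\kappa r}(1+\kappa r)/(\epsilon_s r^2)}, reported
#' as the force ON `target` FROM `source` in kT/Angstrom at the medium
#' temperature. At zero ionic strength this is the plain Coulomb force.
#'
#' @param frame A `structure_frame` with charges assigned.
#' @param source,target Disjoint selections.
#' @param medium An `ionic_medium`.
#' @return Numeric length-3 force vector in kT/Angstrom.
#' @export
pairwise_force <- function(frame, source, target, medium = ionic_medium()) {
  is_ <- resolve_selection(frame, source)
  it <- resolve_selection(frame, target)
  if (length(intersect(is_, it))) stop("source and target selections overlap")
  q <- frame$atoms$charge
  if (anyNA(q[c(is_, it)])) stop("charges not assigned on all selected atoms")
  xyz <- coords_matrix(frame)
  kap <- debye_kappa(medium)
  eps <- medium$solvent_dielectric
  f <- c(0, 0, 0)
  for (j in it) {
    dv <- sweep(xyz[is_, , drop = FALSE] * -1, 2, xyz[j, ], FUN = "+")
    # dv rows = r_j - r_i, direction source -> target
    r <- sqrt(rowSums(dv^2))
    if (any(r < 1e-12)) stop("coincident source/target atoms (r = 0)")
    # charge product grouped first so the force is exactly antisymmetric
    # under swapping source and target (Newton's third law to the bit)
    mag <- .ke * (q[is_] * q[j]) * exp(-kap * r) * (1 + kap * r) / (eps * r^2)
    # repulsive (same sign) pushes target away from source: along +dv
    f <- f + colSums(dv / r * mag)
  }
  f / kT_kcal(medium$temperature)
}

#' Decompose a force along the mass-center connection
#'
#' Projects the total force on the target onto the unit vector from the
#' target's center toward the source's center. `binding` is that signed
#' projection (positive = attraction toward the source), `sliding` the
#' non-negative perpendicular magnitude, and `alpha` the angle between the
#' force and the center line, so that `binding = |F| cos(alpha)` and
#' `sliding = |F| sin(alpha)`.
#'
#' @param total Length-3 force vector on the target (any unit).
#' @param center_source,center_target Mass centers of source and target.
#' @return An object of class `force_record`: `total`, `binding`,
#'   `sliding`, `alpha` (degrees), `magnitude`.
#' @export
decompose_force <- function(total, center_source, center_target) {
  axis <- center_source - center_target
  len <- sqrt(sum(axis^2))
  if (len < 1e-12) stop("source and target centers coincide")
  u <- axis / len
  fmag <- sqrt(sum(total^2))
  binding <- sum(total * u)
  sliding <- sqrt(max(fmag^2 - binding^2, 0))
  alpha <- if (fmag > 0) {
    acos(pmin(1, pmax(-1, binding / fmag))) * 180 / pi
  } else 0
  structure(list(total = total, binding = binding, sliding = sliding,
                 alpha = alpha, magnitude = fmag),
            class = "force_record")
}

#' @export
print.force_record <- function(x, ...) {
  cat(sprintf(
    "|F| = %.4g, binding = %.4g, sliding = %.4g, alpha = %.2f deg\n",
    x$magnitude, x$binding, x$sliding, x$alpha))
  invisible(x)
}

#' Frame-averaged force decomposition with 95% confidence intervals
#'
#' For every frame in the window `(t_start, t_end]`, computes the screened
#' inter-selection force and its binding/sliding decomposition, then
#' reports the mean of each component with a Student-t 95% confidence
#' interval over the per-frame sample.
#'
#' @param traj A `trajectory` with charges and masses assigned.
#' @param source,target Disjoint selections.
#' @param medium An `ionic_medium`.
#' @param t_start,t_end Window bounds in ns; at least 2 frames must fall
#'   inside (the CI is undefined for one frame).
#' @param conf Confidence level (default 0.95).
#' @return A list of class `force_summary`: per-component means, CI
#'   half-widths and bounds, `n_frames`, and the per-frame table.
#' @export
average_force <- function(traj, source, target, medium = ionic_medium(),
                          t_start = -Inf, t_end = Inf, conf = 0.95) {
  keep <- which(traj$times > t_start & traj$times <= t_end)
  if (!length(keep)) stop("no frames fall in the window")
  if (length(keep) < 2) {
    stop("confidence interval undefined for a single frame")
  }
  is_ <- resolve_selection(traj, source)
  it <- resolve_selection(traj, target)
  per <- lapply(keep, function(k) {
    fr <- get_frame(traj, k)
    ft <- pairwise_force(fr, is_, it, medium)
    dec <- decompose_force(ft, mass_center(fr, is_), mass_center(fr, it))
    data.frame(time_ns = traj$times[k], fx = ft[1], fy = ft[2], fz = ft[3],
               binding = dec$binding, sliding = dec$sliding,
               alpha = dec$alpha, magnitude = dec$magnitude)
  })
  tab <- do.call(rbind, per)
  ci <- function(x) {
    n <- length(x)
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
    c(mean = mean(x), half = half)
  }
  comp <- lapply(tab[c("binding", "sliding", "alpha", "magnitude")], ci)
  structure(list(
    mean_binding = comp$binding["mean"], ci_binding = comp$binding["half"],
    mean_sliding = comp$sliding["mean"], ci_sliding = comp$sliding["half"],
    mean_alpha = comp$alpha["mean"], ci_alpha = comp$alpha["half"],
    mean_magnitude = comp$magnitude["mean"],
    ci_magnitude = comp$magnitude["half"],
    conf = conf, n_frames = nrow(tab), per_frame = tab
  ), class = "force_summary")
}

#' @export
print.force_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d frames: binding %.4g +/- %.2g, sliding %.4g +/- %.2g kT/A (%.0f%% CI)\n",
    x$n_frames, x$mean_binding, x$ci_binding,
    x$mean_sliding, x$ci_sliding, 100 * x$conf))
  invisible(x)
}
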
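# Mass-center topology of a two-lobed domain: the distance between the
# mass centers of the N-lobe and C-lobe measures the cleft that houses the
# nucleotide-binding pocket. Windowed statistics, Kabsch RMSD stability
# checks and a rigid separation protocol operate on the same objects.

#' Mass center of a selection
#'
#' @param frame A `structure_frame` with masses assigned.
#' @param sel A `selection` or integer atom indices; `NULL` uses all atoms.
#' @param weighted If `FALSE`, the unweighted geometric center is returned
#'   instead of the mass-weighted one (sensitivity checks).
#' @return Numeric length-3 position in Angstrom.
#' @export
mass_center <- function(frame, sel = NULL, weighted = TRUE) {
  idx <- if (is.null(sel)) seq_len(n_atoms(frame)) else
    resolve_selection(frame, sel)
  m <- if (weighted) frame$atoms$mass[idx] else rep(1, length(idx))
  if (sum(m) <= 0) stop("zero total mass in selection")
  xyz <- coords_matrix(frame)[idx, , drop = FALSE]
  unname(colSums(xyz * m) / sum(m))
}

#' Per-frame mass-center distance between two selections
#'
#' The cleft-size series: for every frame, the Euclidean distance between
#' the mass centers of the two selections.
#'
#' @param traj A `trajectory` with masses assigned.
#' @param selA,selB Selections (or index vectors) for the two lobes.
#' @param weighted Passed to [mass_center()].
#' @return A `cleft_series`: data.frame with columns `time_ns`,
#'   `distance_A`; the selection names are attached as attributes.
#' @export
cleft_series <- function(traj, selA, selB, weighted = TRUE) {
  ia <- resolve_selection(traj, selA)
  ib <- resolve_selection(traj, selB)
  m <- traj$atoms$mass
  wa <- if (weighted) m[ia] else rep(1, length(ia))
  wb <- if (weighted) m[ib] else rep(1, length(ib))
  if (sum(wa) <= 0 || sum(wb) <= 0) stop("zero total mass in selection")
  n_fr <- n_frames(traj)
  d <- numeric(n_fr)
  for (k in seq_len(n_fr)) {
    xyz <- traj$coords[, , k]
    ca <- colSums(xyz[ia, , drop = FALSE] * wa) / sum(wa)
    cb <- colSums(xyz[ib, , drop = FALSE] * wb) / sum(wb)
    d[k] <- sqrt(sum((ca - cb)^2))
  }
  out <- data.frame(time_ns = traj$times, distance_A = d)
  attr(out, "selections") <- c(sel_name(selA), sel_name(selB))
  class(out) <- c("cleft_series", "data.frame")
  out
}

sel_name <- function(sel) {
  if (inherits(sel, "selection")) sel$name else "indices"
}

#' Windowed mean and standard deviation of a cleft series
#'
#' Frames with time in the half-open window `(t_start, t_end]` contribute;
#' with 0.1 ns spacing a 70-100 ns window therefore holds exactly the 300
#' frames at 70.1, 70.2, ..., 100.0 ns. The SD uses the sample (n-1)
#' denominator.
#'
#' @param series A `cleft_series`.
#' @param t_start,t_end Window bounds in ns.
#' @return A list of class `window_stats`: `window`, `n_frames`, `mean`,
#'   `sd`.
#' @export
window_stats <- function(series, t_start, t_end) {
  keep <- series$time_ns > t_start & series$time_ns <= t_end
  if (!any(keep)) stop("no frames fall in the window (", t_start, ", ",
                       t_end, "]")
  v <- series$distance_A[keep]
  structure(list(window = c(t_start, t_end), n_frames = sum(keep),
                 mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0),
            class = "window_stats")
}

#' @export
print.window_stats <- function(x, ...) {
  cat(sprintf("window (%g, %g] ns: n = %d, mean = %.4f A, sd = %.4f A\n",
              x$window[1], x$window[2], x$n_frames, x$mean, x$sd))
  invisible(x)
}

#' RMSD after optimal rigid superposition (Kabsch)
#'
#' Superposes the selected atoms of `frame` onto `reference` with the
#' optimal translation and proper rotation, then reports the RMSD. Used as
#' the trajectory stability check (structures drifting under 4 Angstrom
#' from the start are conventionally called stable).
#'
#' @param frame,reference `structure_frame`s with equal selected atom
#'   counts.
#' @param sel Selection applied to both frames; `NULL` means all atoms.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(frame, reference, sel = NULL) {
  ix <- if (is.null(sel)) seq_len(n_atoms(frame)) else
    resolve_selection(frame, sel)
  iy <- if (is.null(sel)) seq_len(n_atoms(reference)) else
    resolve_selection(reference, sel)
  if (length(ix) != length(iy)) {
    stop("selections resolve to different atom counts (",
         length(ix), " vs ", length(iy), ")")
  }
  p <- coords_matrix(frame)[ix, , drop = FALSE]
  q <- coords_matrix(reference)[iy, , drop = FALSE]
  p <- sweep(p, 2, colMeans(p))
  q <- sweep(q, 2, colMeans(q))
  s <- svd(crossprod(p, q))                       # H = P^T Q
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)        # proper rotation
  sqrt(mean(rowSums((p %*% t(r) - q)^2)))
}

#' Rigidly separate one domain from another
#'
#' Translates the mobile selection by `displacement` Angstrom along the
#' unit vector from the fixed selection's mass center toward the mobile
#' selection's mass center (the same axis the binding/sliding force
#' decomposition projects onto). The mobile domain's internal geometry and
#' every other atom are untouched. Mimics pulling the kinase domain away
#' from the pseudokinase domain by 10, 15 or 20 Angstrom to model the first
#' steps of activation.
#'
#' @param frame A `structure_frame` with masses assigned.
#' @param mobile,fixed Disjoint selections.
#' @param displacement Non-negative displacement in Angstrom.
#' @return The displaced `structure_frame`.
#' @export
separate <- function(frame, mobile, fixed, displacement) {
  if (displacement < 0) stop("displacement must be non-negative")
  im <- resolve_selection(frame, mobile)
  if_ <- resolve_selection(frame, fixed)
  if (length(intersect(im, if_))) stop("mobile and fixed selections overlap")
  cm <- mass_center(frame, im)
  cf <- mass_center(frame, if_)
  axis <- cm - cf
  len <- sqrt(sum(axis^2))
  if (len < 1e-12) stop("mass centers coincide; separation axis undefined")
  shift <- displacement * axis / len
  frame$atoms$x[im] <- frame$atoms$x[im] + shift[1]
  frame$atoms$y[im] <- frame$atoms$y[im] + shift[2]
  frame$atoms$z[im] <- frame$atoms$z[im] + shift[3]
  frame
}
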
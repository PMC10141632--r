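#' Construct a structure frame
#'
#' A structure frame is a single snapshot of a molecular system: an atom
#' table with coordinates and (optionally) per-atom physical parameters.
#' It is the unit object consumed by the geometry, contact, electrostatics
#' and energetics functions.
#'
#' @param atoms A data.frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z`, `mass` and optionally `charge`
#'   (e), `radius` (Angstrom), `lj_epsilon` (kcal/mol), `lj_rmin_half`
#'   (Angstrom). Missing optional columns are added as `NA`.
#' @return An object of class `structure_frame`.
#' @export
structure_frame <- function(atoms) {
  required <- c("serial", "name", "resname", "chain", "resno",
                "x", "y", "z", "mass")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("charge", "radius", "lj_epsilon", "lj_rmin_half")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(!is.finite(atoms$mass) | atoms$mass <= 0)) {
    stop("all atoms must have positive mass")
  }
  if (any(!is.na(atoms$radius) & atoms$radius <= 0)) {
    stop("assigned radii must be positive")
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame> %d atoms, %d residues\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

#' Number of atoms in a frame
#' @param frame A `structure_frame`.
#' @return Integer atom count.
#' @export
n_atoms <- function(frame) {
  nrow(frame$atoms)
}

coords_matrix <- function(frame) {
  as.matrix(frame$atoms[, c("x", "y", "z")])
}

set_coords <- function(frame, xyz) {
  frame$atoms$x <- xyz[, 1]
  frame$atoms$y <- xyz[, 2]
  frame$atoms$z <- xyz[, 3]
  frame
}

#' Subset a frame to an atom index set
#'
#' Extracts the named atoms unchanged (single-trajectory convention: parts
#' are cut out of a complex frame without re-minimisation).
#'
#' @param frame A `structure_frame`.
#' @param idx Integer atom indices.
#' @return A `structure_frame` with only those atoms.
#' @export
subset_frame <- function(frame, idx) {
  if (!length(idx)) stop("cannot subset a frame to zero atoms")
  structure_frame(frame$atoms[idx, , drop = FALSE])
}

#' Construct a trajectory
#'
#' A trajectory is an ordered sequence of structure frames sharing one atom
#' table; only the coordinates vary with time. Every per-frame statistic in
#' the package traverses this object.
#'
#' @param atoms Atom table as in [structure_frame()] (coordinates columns
#'   are ignored; the template may omit them).
#' @param coords Numeric array of dimension `c(n_atoms, 3, n_frames)`.
#' @param times Numeric vector of frame times in ns, strictly increasing.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(atoms, coords, times) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  n_fr <- dim(coords)[3]
  if (length(times) != n_fr) {
    stop("length(times) must equal the number of frames")
  }
  if (n_fr > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  for (col in c("x", "y", "z")) atoms[[col]] <- NULL
  if (nrow(atoms) != dim(coords)[1]) {
    stop("atom table and coordinate array disagree on atom count")
  }
  structure(list(atoms = atoms, coords = coords, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms x %d frames, t = %.4g..%.4g ns\n",
              nrow(x$atoms), n_frames(x),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  dim(traj$coords)[3]
}

#' Extract one frame from a trajectory
#'
#' @param traj A `trajectory`.
#' @param i Frame index (1-based).
#' @return A `structure_frame` carrying the shared atom parameters and the
#'   coordinates of frame `i`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  atoms <- traj$atoms
  atoms$x <- traj$coords[, 1, i]
  atoms$y <- traj$coords[, 2, i]
  atoms$z <- traj$coords[, 3, i]
  structure_frame(atoms)
}

# Atom identity label "chain:resname resno" used in contact reports.
residue_label <- function(atoms, idx) {
  sprintf("%s:%s%d", atoms$chain[idx], atoms$resname[idx], atoms$resno[idx])
}

atom_label <- function(atoms, idx) {
  sprintf("%s:%s%d:%s", atoms$chain[idx], atoms$resname[idx],
          atoms$resno[idx], atoms$name[idx])
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
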
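# Structure and trajectory I/O.
#
# Trajectories travel as multi-model PDB (MODEL/ENDMDL, with the frame time
# in ns on a REMARK 250 line); parsing of the coordinate records is
# delegated to bio3d. PQR uses the whitespace-delimited pdb2pqr dialect
# (coordinates %8.3f, charge %8.4f, radius %7.4f).

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z) {
  # PDB v3 fixed columns; atom names of <4 chars are placed in cols 14-16,
  # column 17 (altLoc) stays blank, residue name sits in 18-20.
  nm <- ifelse(nchar(name) < 4, paste0(" ", name), name)
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial %% 100000, nm, substr(resname, 1, 3),
          substr(chain, 1, 1), resno %% 10000, x, y, z)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Each frame becomes one MODEL/ENDMDL block; the frame time is recorded as
#' `REMARK 250 TIME_NS <t>` inside the block so that [read_trajectory()]
#' recovers it.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("REMARK 250 TIME_NS %.6f", traj$times[k]), con)
    writeLines(pdb_atom_line(a$serial, a$name, a$resname, a$chain, a$resno,
                             traj$coords[, 1, k], traj$coords[, 2, k],
                             traj$coords[, 3, k]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a single frame as a PDB file
#'
#' @param frame A `structure_frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_pdb <- function(frame, path) {
  a <- frame$atoms
  writeLines(c(pdb_atom_line(a$serial, a$name, a$resname, a$chain, a$resno,
                             a$x, a$y, a$z), "END"), path)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' A file without MODEL records is read as a one-frame trajectory. All
#' models must contain the same number of atoms in the same order; a model
#' that differs is reported by its model number. Frame times come from
#' `REMARK 250 TIME_NS` lines when present, otherwise they are synthesized
#' as 1-based frame index times `frame_interval`.
#'
#' @param path PDB file path.
#' @param frame_interval Fallback frame spacing in ns used when the file
#'   carries no time remarks.
#' @return A `trajectory`. Atom masses are assigned from the element
#'   inferred from the atom name; charge/radius/LJ fields are left
#'   unassigned (see [assign_parameters()]).
#' @export
read_trajectory <- function(path, frame_interval = 0.1) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)

  if (length(model_starts) > 1) {
    block <- findInterval(which(is_atom), model_starts)
    counts <- tabulate(block, nbins = length(model_starts))
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      stop(sprintf("model %d has %d atoms but model 1 has %d",
                   bad, counts[bad], counts[1]))
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_at <- nrow(at)
  n_fr <- nrow(xyz)
  if (any(!is.finite(xyz))) stop("unparseable coordinates in ", path)

  coords <- array(0, dim = c(n_at, 3, n_fr))
  for (k in seq_len(n_fr)) {
    coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  }

  tm_lines <- grep("^REMARK 250 TIME_NS", lines, value = TRUE)
  if (length(tm_lines) == n_fr) {
    times <- as.numeric(sub("^REMARK 250 TIME_NS\\s+", "", tm_lines))
  } else {
    times <- seq_len(n_fr) * frame_interval
  }

  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    mass = guess_mass(at$elety),
    charge = NA_real_, radius = NA_real_,
    lj_epsilon = NA_real_, lj_rmin_half = NA_real_,
    stringsAsFactors = FALSE
  )
  trajectory(atoms, coords, times)
}

# Element (hence mass) from the atom name, PDB convention: leading digits
# stripped, first letter is the element for organic/one-letter elements.
guess_mass <- function(name) {
  el <- toupper(substr(gsub("^[0-9]+", "", name), 1, 1))
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
              S = 32.06, P = 30.974, Q = 22.99, D = 12.011)
  m <- masses[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Write a frame in PQR format
#'
#' Whitespace-delimited pdb2pqr dialect: the occupancy/B-factor columns are
#' replaced by per-atom charge (e) and radius (Angstrom). Every atom must
#' have both assigned; unassigned atoms abort the write and are listed.
#'
#' @param frame A `structure_frame` with charges and radii assigned.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(frame, path) {
  a <- frame$atoms
  bad <- is.na(a$charge) | is.na(a$radius)
  if (any(bad)) {
    stop("atoms without charge/radius: ",
         paste(atom_label(a, which(bad)), collapse = ", "))
  }
  lines <- sprintf("ATOM  %5d %-4s %-4s %1s %4d %11.3f %7.3f %7.3f %8.4f %7.4f",
                   a$serial, a$name, a$resname, a$chain, a$resno,
                   a$x, a$y, a$z, a$charge, a$radius)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a PQR file
#'
#' Parses the whitespace-delimited dialect written by [write_pqr()] (and by
#' pdb2pqr): `ATOM serial name resname chain resno x y z charge radius`.
#' A 9-field variant without the chain column is also accepted.
#'
#' @param path PQR file path.
#' @return A `structure_frame` with charge and radius populated and masses
#'   guessed from atom names.
#' @export
read_pqr <- function(path) {
  lines <- grep("^(ATOM|HETATM)", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) stop("no ATOM records in ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  if (!all(nf %in% c(10L, 11L))) {
    stop("unrecognised PQR record layout in ", path)
  }
  parse_one <- function(tk) {
    has_chain <- length(tk) == 11L
    off <- if (has_chain) 1L else 0L
    list(serial = as.integer(tk[2]), name = tk[3], resname = tk[4],
         chain = if (has_chain) tk[5] else "A",
         resno = as.integer(tk[5 + off]),
         x = as.numeric(tk[6 + off]), y = as.numeric(tk[7 + off]),
         z = as.numeric(tk[8 + off]),
         charge = as.numeric(tk[9 + off]), radius = as.numeric(tk[10 + off]))
  }
  rows <- lapply(toks, parse_one)
  atoms <- do.call(rbind, lapply(rows, as.data.frame,
                                 stringsAsFactors = FALSE))
  atoms$mass <- guess_mass(atoms$name)
  atoms$lj_epsilon <- NA_real_
  atoms$lj_rmin_half <- NA_real_
  structure_frame(atoms)
}
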
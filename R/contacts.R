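# Salt-bridge and hydrogen-bond detection with per-pair occupancy across a
# trajectory. Conventions: a salt bridge is a basic nitrogen within the
# cutoff of an acidic oxygen, reported once per residue pair; a hydrogen
# bond is a donor-H-acceptor triple whose donor-acceptor distance is within
# the cutoff AND whose D-H vector deviates from the D->A direction by at
# most the angle cutoff (the convention of the common MD analysis tools; an
# interior D-H...A angle convention gives different answers). Cutoffs are
# inclusive: a stated cutoff of 4 A admits a pair at exactly 4.0.

#' Geometric criteria for contact detection
#'
#' @param salt_bridge_cutoff Maximum basic-N to acidic-O distance in
#'   Angstrom (default 4).
#' @param hbond_distance_cutoff Maximum donor-acceptor distance in
#'   Angstrom (default 3.5).
#' @param hbond_angle_cutoff Maximum deviation of D-H from the D->A
#'   direction in degrees (default 20; must be < 90).
#' @param basic_atoms,acidic_atoms Data frames with columns `resname`,
#'   `name` defining the charged-atom chemistry; `resname = "*"` matches
#'   any residue. Defaults cover Lys NZ, Arg NE/NH1/NH2, the fixture
#'   ammonium, Asp/Glu carboxylates and nucleotide/phosphate oxygens.
#' @param hbond_max_dh Maximum covalent D-H bond length used to find
#'   attached hydrogens (Angstrom).
#' @return An object of class `contact_criteria`.
#' @export
contact_criteria <- function(salt_bridge_cutoff = 4.0,
                             hbond_distance_cutoff = 3.5,
                             hbond_angle_cutoff = 20,
                             basic_atoms = default_basic_atoms(),
                             acidic_atoms = default_acidic_atoms(),
                             hbond_max_dh = 1.25) {
  if (salt_bridge_cutoff <= 0 || hbond_distance_cutoff <= 0 ||
      hbond_angle_cutoff <= 0) {
    stop("all cutoffs must be positive")
  }
  if (hbond_angle_cutoff >= 90) stop("hbond_angle_cutoff must be < 90 degrees")
  structure(list(salt_bridge_cutoff = salt_bridge_cutoff,
                 hbond_distance_cutoff = hbond_distance_cutoff,
                 hbond_angle_cutoff = hbond_angle_cutoff,
                 basic_atoms = basic_atoms,
                 acidic_atoms = acidic_atoms,
                 hbond_max_dh = hbond_max_dh),
            class = "contact_criteria")
}

#' @rdname contact_criteria
#' @export
default_basic_atoms <- function() {
  data.frame(
    resname = c("LYS", "ARG", "ARG", "ARG", "HIS", "HIS"),
    name = c("NZ", "NE", "NH1", "NH2", "ND1", "NE2"),
    stringsAsFactors = FALSE
  )
}

#' @rdname contact_criteria
#' @export
default_acidic_atoms <- function() {
  data.frame(
    resname = c("ASP", "ASP", "GLU", "GLU",
                "*", "*", "*", "*", "*", "*", "*", "*", "*"),
    name = c("OD1", "OD2", "OE1", "OE2",
             "O1A", "O2A", "O3A", "O1B", "O2B", "O3B", "O1G", "O2G", "O3G"),
    stringsAsFactors = FALSE
  )
}

match_atom_set <- function(atoms, set) {
  hit <- rep(FALSE, nrow(atoms))
  for (r in seq_len(nrow(set))) {
    hit <- hit | ((set$resname[r] == "*" | atoms$resname == set$resname[r]) &
                    atoms$name == set$name[r])
  }
  which(hit)
}

#' Detect salt bridges in one frame
#'
#' Every basic-nitrogen / acidic-oxygen pair within the cutoff counts;
#' pairs are collapsed to one record per residue pair, keeping the minimum
#' distance over the pair's atoms (so a lysine straddling both carboxylate
#' oxygens yields one bridge).
#'
#' @param frame A `structure_frame`.
#' @param criteria A `contact_criteria`.
#' @return Data frame with columns `res_a`, `res_b`, `atom_a`, `atom_b`,
#'   `distance` (possibly empty).
#' @export
detect_salt_bridges <- function(frame, criteria = contact_criteria()) {
  a <- frame$atoms
  ib <- match_atom_set(a, criteria$basic_atoms)
  ia <- match_atom_set(a, criteria$acidic_atoms)
  empty <- data.frame(res_a = character(), res_b = character(),
                      atom_a = character(), atom_b = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!length(ib) || !length(ia)) return(empty)
  xyz <- coords_matrix(frame)
  rows <- list()
  for (i in ib) {
    d <- sqrt(rowSums(sweep(xyz[ia, , drop = FALSE], 2, xyz[i, ])^2))
    close <- which(d <= criteria$salt_bridge_cutoff)
    for (k in close) {
      j <- ia[k]
      rows[[length(rows) + 1]] <- data.frame(
        res_a = residue_label(a, i), res_b = residue_label(a, j),
        atom_a = a$name[i], atom_b = a$name[j], distance = d[k],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # one record per residue pair: keep the closest atom pair
  key <- paste(out$res_a, out$res_b, sep = "|")
  out <- out[order(key, out$distance), ]
  out <- out[!duplicated(paste(out$res_a, out$res_b, sep = "|")), ]
  rownames(out) <- NULL
  out
}

# Donor heavy atoms (N/O with a covalently attached H) and their hydrogens.
find_donors <- function(frame, max_dh) {
  a <- frame$atoms
  el <- toupper(substr(gsub("^[0-9]+", "", a$name), 1, 1))
  heavy <- which(el %in% c("N", "O"))
  hyd <- which(el == "H")
  if (!length(heavy) || !length(hyd)) {
    return(data.frame(donor = integer(), hydrogen = integer()))
  }
  xyz <- coords_matrix(frame)
  rows <- list()
  for (h in hyd) {
    d <- sqrt(rowSums(sweep(xyz[heavy, , drop = FALSE], 2, xyz[h, ])^2))
    k <- which.min(d)
    if (d[k] <= max_dh && a$resno[heavy[k]] == a$resno[h] &&
        a$chain[heavy[k]] == a$chain[h]) {
      rows[[length(rows) + 1]] <- data.frame(donor = heavy[k], hydrogen = h)
    }
  }
  if (!length(rows)) return(data.frame(donor = integer(), hydrogen = integer()))
  do.call(rbind, rows)
}

#' Detect hydrogen bonds in one frame
#'
#' Donors are N/O heavy atoms with a covalently attached hydrogen;
#' acceptors are any N/O of a different residue. A triple qualifies when
#' the donor-acceptor distance is within `hbond_distance_cutoff` and the
#' D-H vector deviates from the D->A direction by at most
#' `hbond_angle_cutoff` degrees.
#'
#' @inheritParams detect_salt_bridges
#' @return Data frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   labels), `res_a`, `res_b`, `distance`, `angle` (possibly empty).
#' @export
detect_hbonds <- function(frame, criteria = contact_criteria()) {
  a <- frame$atoms
  el <- toupper(substr(gsub("^[0-9]+", "", a$name), 1, 1))
  acceptors <- which(el %in% c("N", "O"))
  donors <- find_donors(frame, criteria$hbond_max_dh)
  empty <- data.frame(donor = character(), hydrogen = character(),
                      acceptor = character(), res_a = character(),
                      res_b = character(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE)
  if (!nrow(donors) || !length(acceptors)) return(empty)
  xyz <- coords_matrix(frame)
  rows <- list()
  for (r in seq_len(nrow(donors))) {
    di <- donors$donor[r]
    hi <- donors$hydrogen[r]
    for (ai in acceptors) {
      if (ai == di || ai == hi) next
      if (a$resno[ai] == a$resno[di] && a$chain[ai] == a$chain[di]) next
      v_da <- xyz[ai, ] - xyz[di, ]
      d_da <- sqrt(sum(v_da^2))
      if (d_da > criteria$hbond_distance_cutoff) next
      v_dh <- xyz[hi, ] - xyz[di, ]
      cosang <- sum(v_da * v_dh) / (d_da * sqrt(sum(v_dh^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang > criteria$hbond_angle_cutoff) next
      rows[[length(rows) + 1]] <- data.frame(
        donor = atom_label(a, di), hydrogen = atom_label(a, hi),
        acceptor = atom_label(a, ai),
        res_a = residue_label(a, di), res_b = residue_label(a, ai),
        distance = d_da, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-pair contact occupancy across a trajectory
#'
#' Runs a detector on every frame and reports, for each pair ever observed
#' (optionally restricted to pairs spanning two selections), the percentage
#' of all frames in which the contact criterion holds. Pairs that never
#' form do not appear.
#'
#' @param traj A `trajectory`.
#' @param detector `"hbond"`, `"salt_bridge"`, or a function
#'   `frame -> data.frame` with the corresponding columns.
#' @param selA,selB Optional selections; when both are given only contacts
#'   with one partner in each are counted.
#' @param criteria A `contact_criteria`.
#' @return Data frame of class `occupancy_records` with columns
#'   `partner_a`, `partner_b`, `type`, `occupancy` (percent), `n_present`,
#'   `n_frames`, sorted by descending occupancy.
#' @export
occupancy <- function(traj, detector = c("hbond", "salt_bridge"),
                      selA = NULL, selB = NULL,
                      criteria = contact_criteria()) {
  n_fr <- n_frames(traj)
  if (n_fr < 1) stop("trajectory has no frames")
  if (is.character(detector)) {
    detector <- match.arg(detector)
    type <- detector
    fun <- switch(detector,
                  hbond = function(fr) detect_hbonds(fr, criteria),
                  salt_bridge = function(fr) detect_salt_bridges(fr, criteria))
  } else {
    type <- "custom"
    fun <- detector
  }
  ia <- if (is.null(selA)) NULL else resolve_selection(traj, selA)
  ib <- if (is.null(selB)) NULL else resolve_selection(traj, selB)
  resA <- if (is.null(ia)) NULL else unique(residue_label(traj$atoms, ia))
  resB <- if (is.null(ib)) NULL else unique(residue_label(traj$atoms, ib))

  counts <- new.env(parent = emptyenv())
  for (k in seq_len(n_fr)) {
    hits <- fun(get_frame(traj, k))
    if (!nrow(hits)) next
    if (!is.null(resA) && !is.null(resB)) {
      spans <- (hits$res_a %in% resA & hits$res_b %in% resB) |
        (hits$res_a %in% resB & hits$res_b %in% resA)
      hits <- hits[spans, , drop = FALSE]
    }
    if (!nrow(hits)) next
    keys <- if ("donor" %in% names(hits)) {
      paste(hits$donor, hits$acceptor, sep = " -> ")
    } else {
      paste(hits$res_a, hits$res_b, sep = " -- ")
    }
    pa <- hits$res_a
    pb <- hits$res_b
    for (j in seq_along(keys)) {
      rec <- counts[[keys[j]]]
      if (is.null(rec)) {
        counts[[keys[j]]] <- list(n = 1L, pa = pa[j], pb = pb[j])
      } else {
        rec$n <- rec$n + 1L
        counts[[keys[j]]] <- rec
      }
    }
  }
  keys <- ls(counts)
  out <- data.frame(
    partner_a = vapply(keys, function(k) counts[[k]]$pa, character(1)),
    partner_b = vapply(keys, function(k) counts[[k]]$pb, character(1)),
    pair = keys,
    type = rep(type, length(keys)),
    n_present = vapply(keys, function(k) counts[[k]]$n, integer(1)),
    n_frames = rep(n_fr, length(keys)),
    stringsAsFactors = FALSE
  )
  out$occupancy <- 100 * out$n_present / out$n_frames
  out <- out[order(-out$occupancy, out$pair), ]
  rownames(out) <- NULL
  class(out) <- c("occupancy_records", "data.frame")
  out
}

#' Keep only high-occupancy contacts
#'
#' Strictly-greater-than filtering (a ">10%" threshold excludes a pair at
#' exactly 10%), sorted by descending occupancy.
#'
#' @param records An `occupancy_records` data frame.
#' @param threshold Occupancy threshold in percent, within `[0, 100]`.
#' @return The filtered, sorted records.
#' @export
filter_occupancy <- function(records, threshold) {
  if (threshold < 0 || threshold > 100) {
    stop("threshold must be within [0, 100]")
  }
  out <- records[records$occupancy > threshold, , drop = FALSE]
  out <- out[order(-out$occupancy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summed contact occupancy per residue
#'
#' Sums, for every residue appearing in the records, the occupancies of
#' all contacts it participates in. A residue donating several
#' high-occupancy bonds can exceed 100%; this is the sense in which a
#' residue "contributes over 100%-occupancy" interactions. This is an
#' aggregate over pairs, not a frame-wise statistic.
#'
#' @param records An `occupancy_records` data frame (one trajectory).
#' @return Data frame with columns `residue`, `total_occupancy`, sorted
#'   descending.
#' @export
residue_occupancy <- function(records) {
  if (!nrow(records)) {
    return(data.frame(residue = character(), total_occupancy = numeric(),
                      stringsAsFactors = FALSE))
  }
  long <- data.frame(residue = c(records$partner_a, records$partner_b),
                     occ = rep(records$occupancy, 2),
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(occ ~ residue, data = long, FUN = sum)
  names(agg) <- c("residue", "total_occupancy")
  agg <- agg[order(-agg$total_occupancy), ]
  rownames(agg) <- NULL
  agg
}
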
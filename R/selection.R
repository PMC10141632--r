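# Named residue-range selections (e.g. kinase N-lobe T815-P906, C-lobe
# S907-S1100). Intervals are closed and follow the structure's author
# numbering.

#' Define a named atom selection
#'
#' A selection is a predicate over the atom table: an optional chain, one
#' or more closed residue-number intervals, and/or a residue-name set.
#' Intervals may be given as strings with residue-letter anchors
#' (`"T815-P906"`); the letters are validated against the structure when it
#' carries standard residue names and are ignored otherwise.
#'
#' @param name Label for the selection.
#' @param chain Optional chain identifier.
#' @param intervals Either a 2-column matrix/list of `c(start, end)` pairs
#'   or a character vector such as `"T815-P906"` / `"815-906"`.
#' @param resnames Optional residue-name set.
#' @return An object of class `selection`.
#' @export
selection <- function(name, chain = NULL, intervals = NULL, resnames = NULL) {
  parsed <- NULL
  if (!is.null(intervals)) {
    if (is.character(intervals)) {
      parsed <- do.call(rbind, lapply(intervals, parse_residue_range))
    } else {
      if (is.list(intervals)) intervals <- do.call(rbind, intervals)
      intervals <- matrix(as.numeric(intervals), ncol = 2)
      parsed <- data.frame(start = intervals[, 1], end = intervals[, 2],
                           start_aa = NA_character_, end_aa = NA_character_,
                           stringsAsFactors = FALSE)
    }
    if (any(parsed$end < parsed$start)) {
      stop("selection '", name, "': interval end precedes start")
    }
  }
  structure(list(name = name, chain = chain, intervals = parsed,
                 resnames = resnames),
            class = "selection")
}

# "T815-P906" -> start/end numbers plus expected one-letter residue codes.
parse_residue_range <- function(txt) {
  m <- regmatches(txt, regexec("^([A-Za-z]?)(\\d+)-([A-Za-z]?)(\\d+)$",
                               trimws(txt)))[[1]]
  if (!length(m)) stop("cannot parse residue range '", txt, "'")
  data.frame(start = as.integer(m[3]), end = as.integer(m[5]),
             start_aa = ifelse(nzchar(m[2]), toupper(m[2]), NA),
             end_aa = ifelse(nzchar(m[4]), toupper(m[4]), NA),
             stringsAsFactors = FALSE)
}

#' Resolve a selection to atom indices
#'
#' @param x A `structure_frame` or `trajectory`.
#' @param sel A `selection` (or a plain integer index vector, passed
#'   through after validation).
#' @param strict If `TRUE`, a residue-letter anchor that contradicts the
#'   residue type at that position is an error; by default it is a warning.
#' @return Sorted integer vector of atom indices; an empty result is an
#'   error.
#' @export
resolve_selection <- function(x, sel, strict = FALSE) {
  atoms <- if (inherits(x, "trajectory")) x$atoms else x$atoms
  if (is.numeric(sel)) {
    idx <- sort(unique(as.integer(sel)))
    if (!length(idx) || any(idx < 1 | idx > nrow(atoms))) {
      stop("numeric selection out of range")
    }
    return(idx)
  }
  if (!inherits(sel, "selection")) stop("sel must be a selection object")

  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(sel$chain)) keep <- keep & atoms$chain %in% sel$chain
  if (!is.null(sel$resnames)) keep <- keep & atoms$resname %in% sel$resnames
  if (!is.null(sel$intervals)) {
    in_any <- rep(FALSE, nrow(atoms))
    for (r in seq_len(nrow(sel$intervals))) {
      in_any <- in_any | (atoms$resno >= sel$intervals$start[r] &
                          atoms$resno <= sel$intervals$end[r])
    }
    keep <- keep & in_any
    check_residue_anchors(atoms, sel, strict)
  }
  idx <- which(keep)
  if (!length(idx)) {
    stop("selection '", sel$name, "' matches no atoms")
  }
  sort(idx)
}

# Validate residue-letter anchors like the T of "T815" against the residue
# name found at that number, when the structure carries standard residues.
check_residue_anchors <- function(atoms, sel, strict) {
  aa1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", HSD = "H",
           ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
           PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y",
           VAL = "V", PTR = "Y")
  for (r in seq_len(nrow(sel$intervals))) {
    for (side in c("start", "end")) {
      expect <- sel$intervals[[paste0(side, "_aa")]][r]
      if (is.na(expect)) next
      resno <- sel$intervals[[side]][r]
      hit <- atoms$resno == resno &
        (is.null(sel$chain) | atoms$chain %in% sel$chain)
      resn <- unique(atoms$resname[hit])
      resn <- resn[resn %in% names(aa1)]
      if (!length(resn)) next  # fixture residues: anchors not checkable
      if (!any(aa1[resn] == expect)) {
        msg <- sprintf(
          "selection '%s': residue %d is %s, not '%s' as the anchor states",
          sel$name, resno, paste(resn, collapse = "/"), expect)
        if (strict) stop(msg) else warning(msg, call. = FALSE)
      }
    }
  }
  invisible(NULL)
}
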
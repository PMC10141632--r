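# Per-atom physical parameter assignment. A bundled CHARMM-like table
# covers the residue set the synthetic structures use plus common charged
# protein side-chain atoms and generic ions, keyed by (residue name, atom
# name). Lookups must be total over the atoms of a structure or assignment
# fails loudly, listing every unmatched atom.

#' Bundled per-atom parameter table
#'
#' Returns a data.frame keyed by `(resname, name)` giving partial charge
#' (e), radius (Angstrom), mass (amu) and Lennard-Jones well depth
#' (kcal/mol) / Rmin/2 (Angstrom). Values are CHARMM-like for the residues
#' the synthetic generators emit, charged protein side chains, and generic
#' monovalent ions.
#'
#' The protonation state of a phosphotyrosine phosphate is chemistry the
#' caller must decide (mono- vs dianionic changes the net charge by 1e), so
#' it is an explicit argument rather than a default: passing
#' `phosphate_charge` adds entries for residue `PTR` with the three
#' terminal oxygens sharing that total charge.
#'
#' @param phosphate_charge Optional total charge (e) of a phosphotyrosine
#'   phosphate group, typically -1 or -2. `NULL` omits the PTR entries.
#' @return A data.frame with columns `resname`, `name`, `charge`, `radius`,
#'   `mass`, `lj_epsilon`, `lj_rmin_half`.
#' @export
default_parameter_table <- function(phosphate_charge = NULL) {
  tab <- read.csv(text = "resname,name,charge,radius,mass,lj_epsilon,lj_rmin_half
DMA,C1,0,1.70,12.011,0.11,2.00
DMA,C2,0,1.70,12.011,0.11,2.00
DMA,C3,0,1.70,12.011,0.11,2.00
DMA,C4,0,1.70,12.011,0.11,2.00
DMB,C1,0,1.70,12.011,0.11,2.00
DMB,C2,0,1.70,12.011,0.11,2.00
DMB,C3,0,1.70,12.011,0.11,2.00
DMB,C4,0,1.70,12.011,0.11,2.00
DON,N,-0.47,1.55,14.007,0.20,1.85
DON,HN,0.31,1.20,1.008,0.046,0.2245
ACC,O,-0.51,1.52,15.999,0.12,1.70
ION,Q1,1,1.50,22.99,0.10,1.50
ION,Q2,-1,1.50,22.99,0.10,1.50
LYS,NZ,1,1.85,14.007,0.20,1.85
ARG,NE,-0.70,1.85,14.007,0.20,1.85
ARG,NH1,0.85,1.85,14.007,0.20,1.85
ARG,NH2,0.85,1.85,14.007,0.20,1.85
ASP,OD1,-0.76,1.70,15.999,0.12,1.70
ASP,OD2,-0.76,1.70,15.999,0.12,1.70
GLU,OE1,-0.76,1.70,15.999,0.12,1.70
GLU,OE2,-0.76,1.70,15.999,0.12,1.70
SOD,SOD,1,1.41,22.99,0.047,1.41
CLA,CLA,-1,2.27,35.45,0.15,2.27
", stringsAsFactors = FALSE)
  if (!is.null(phosphate_charge)) {
    per_o <- phosphate_charge / 3
    ptr <- data.frame(
      resname = "PTR", name = c("P", "O1P", "O2P", "O3P"),
      charge = c(1.1, per_o - 1.1 / 3, per_o - 1.1 / 3, per_o - 1.1 / 3),
      radius = c(1.85, 1.49, 1.49, 1.49),
      mass = c(30.974, 15.999, 15.999, 15.999),
      lj_epsilon = c(0.585, 0.12, 0.12, 0.12),
      lj_rmin_half = c(2.15, 1.70, 1.70, 1.70),
      stringsAsFactors = FALSE
    )
    tab <- rbind(tab, ptr)
  }
  tab
}

#' Assign charges, radii and LJ parameters from a table
#'
#' Populates the `charge`, `radius`, `lj_epsilon`, `lj_rmin_half` and
#' `mass` fields of every atom by `(resname, name)` lookup. Any atom
#' without a table entry aborts the assignment; all unmatched atoms are
#' listed in the error.
#'
#' @param frame A `structure_frame`.
#' @param table A parameter table as from [default_parameter_table()].
#' @return The frame with parameters populated; the net charge is attached
#'   as attribute `total_charge` and printed as a message.
#' @export
assign_parameters <- function(frame, table = default_parameter_table()) {
  a <- frame$atoms
  key <- paste(a$resname, a$name)
  tkey <- paste(table$resname, table$name)
  hit <- match(key, tkey)
  if (anyNA(hit)) {
    miss <- which(is.na(hit))
    stop("no parameters for atom(s): ",
         paste(atom_label(a, miss), collapse = ", "))
  }
  a$charge <- table$charge[hit]
  a$radius <- table$radius[hit]
  a$mass <- table$mass[hit]
  a$lj_epsilon <- table$lj_epsilon[hit]
  a$lj_rmin_half <- table$lj_rmin_half[hit]
  out <- structure_frame(a)
  total <- sum(a$charge)
  attr(out, "total_charge") <- total
  message(sprintf("assigned %d atoms; net charge %+.4f e", nrow(a), total))
  out
}
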
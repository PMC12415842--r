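# Reference tables: residue heavy-atom compositions, element masses, charges.

# Standard PDB heavy-atom names per amino acid (backbone N, CA, C, O first).
.AA_HEAVY_ATOMS <- list(
  ALA = c("N", "CA", "C", "O", "CB"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  GLY = c("N", "CA", "C", "O"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("N", "CA", "C", "O", "CB", "CG", "CD"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
          "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
          "CZ", "OH"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2")
)

.AA3 <- names(.AA_HEAVY_ATOMS)

.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974, "NA" = 22.990, CL = 35.45, ZN = 65.38,
                   K = 39.098, MG = 24.305, FE = 55.845)

# Single-bead pseudo-water carries the full molecular mass.
.WATER_MASS <- 18.0153

# Formal side-chain charges at pH 7 (His neutral by default).
.AA_CHARGE <- c(ARG = 1L, LYS = 1L, ASP = -1L, GLU = -1L, HIS = 0L)

#' Heavy-atom names for an amino-acid residue type
#' @param res_type three-letter residue code (e.g. "ARG")
#' @return character vector of PDB heavy-atom names
#' @keywords internal
aa_heavy_atoms <- function(res_type) {
  out <- .AA_HEAVY_ATOMS[[toupper(res_type)]]
  if (is.null(out)) stop("unknown amino-acid type: ", res_type)
  out
}

#' Infer the chemical element from a PDB atom name
#'
#' Used when the PDB element column is blank. Strips digits/primes and
#' handles the two-letter ion/metal names seen in simulation output.
#' @param name atom name as written in the PDB file
#' @param res_type residue name, used to disambiguate ions
#' @return element symbol (upper case)
#' @keywords internal
infer_element <- function(name, res_type = "") {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  rt <- toupper(res_type)
  if (rt %in% c("NA", "SOD") || nm %in% c("SOD")) return("NA")
  if (rt %in% c("CL", "CLA") || nm %in% c("CLA")) return("CL")
  if (rt %in% c("ZN", "ZN2") || nm %in% c("ZN")) return("ZN")
  if (nm == "") stop("cannot infer element from atom name: ", name)
  first <- substr(nm, 1, 1)
  if (first %in% c("C", "N", "O", "S", "P", "H")) return(first)
  substr(nm, 1, 2)
}

#' Element mass in atomic mass units
#' @param element element symbol
#' @param strict error on unknown elements (default); otherwise fall back
#'   to a carbon mass with a warning (for 'other'-component heteroatoms)
#' @return mass in amu
#' @keywords internal
element_mass <- function(element, strict = TRUE) {
  m <- .ELEMENT_MASS[toupper(element)]
  if (any(is.na(m))) {
    missing <- unique(element[is.na(m)])
    if (strict)
      stop("no mass tabulated for element(s): ",
           paste(missing, collapse = ", "))
    warning("no mass tabulated for element(s) ",
            paste(missing, collapse = ", "), "; using carbon mass")
    m[is.na(m)] <- .ELEMENT_MASS[["C"]]
  }
  unname(m)
}

#' Formal side-chain charge of a residue type
#' @param res_type three-letter code
#' @param his_charged count histidine as +1 (default FALSE)
#' @return integer charge
#' @keywords internal
residue_charge <- function(res_type, his_charged = FALSE) {
  q <- .AA_CHARGE[toupper(res_type)]
  q[is.na(q)] <- 0L
  if (his_charged) q[toupper(res_type) == "HIS"] <- 1L
  unname(q)
}
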
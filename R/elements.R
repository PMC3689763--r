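# Element tables used for mass computation and distance-based bond inference.
# Masses: IUPAC 2021 standard atomic weights (conventional values).
# Covalent radii: Cordero et al. single-bond radii, Angstrom.

.ATOMIC_MASS <- c(
  H = 1.008, D = 2.014, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, NA_ = 22.990, MG = 24.305, SI = 28.085, P = 30.974, S = 32.06,
  CL = 35.45, K = 39.098, CA = 40.078, MN = 54.938, FE = 55.845, CO = 58.933,
  NI = 58.693, CU = 63.546, ZN = 65.38, AS = 74.922, SE = 78.971,
  BR = 79.904, MO = 95.95, I = 126.904, W = 183.84, PT = 195.084,
  AU = 196.967, HG = 200.592
)
names(.ATOMIC_MASS)[names(.ATOMIC_MASS) == "NA_"] <- "NA"

.COVALENT_RADIUS <- c(
  H = 0.31, D = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  `NA` = 1.66, MG = 1.41, SI = 1.11, P = 1.07, S = 1.05, CL = 1.02,
  K = 2.03, CA = 1.76, MN = 1.39, FE = 1.32, CO = 1.26, NI = 1.24,
  CU = 1.32, ZN = 1.22, AS = 1.19, SE = 1.20, BR = 1.20, MO = 1.54,
  I = 1.39, W = 1.62, PT = 1.36, AU = 1.36, HG = 1.32
)

# Tolerance added to the sum of covalent radii when inferring bonds from
# distances (standard crystallographic heuristic); CONECT records win.
.BOND_TOLERANCE <- 0.45

.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

.WATER_RESNAMES <- c("HOH", "DOD", "WAT", "H2O")

#' Standard atomic mass of an element
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in g/mol.
#' @examples
#' atomicMass(c("C", "N"))
#' @export
atomicMass <- function(element) {
  el <- toupper(element)
  unknown <- setdiff(unique(el), names(.ATOMIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  unname(.ATOMIC_MASS[el])
}

.covalentRadius <- function(element) {
  el <- toupper(element)
  r <- .COVALENT_RADIUS[el]
  # fall back to a generous default for exotic elements
  r[is.na(r)] <- 1.5
  unname(r)
}

.isHydrogen <- function(element) toupper(element) %in% c("H", "D")
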
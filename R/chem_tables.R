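# Chemical reference tables: van der Waals radii, hydrogen-bond donor and
# acceptor atoms, formal charges, aromatic ring memberships, residue volumes
# and conservative-substitution groups.  These are package data in code form
# so that no external file is ever required.

# United/explicit-atom protein radii (Angstrom), keyed by element symbol.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  ZN = 1.39, MG = 1.73, CA = 1.73, `NA` = 2.27, K = 2.75, FE = 1.52,
  MN = 1.73, CU = 1.40, NI = 1.63, CO = 1.53, CD = 1.58, HG = 1.55
)

#' Van der Waals radii table
#'
#' Element-keyed van der Waals radii (Angstrom) used for surface-area and
#' clash calculations throughout the package.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() .vdw_radii

# Look up radii for a vector of element symbols; atoms with no table entry
# are a hard error (the caller lists them).
lookup_radius <- function(element, name = element) {
  el <- toupper(element)
  r <- .vdw_radii[el]
  bad <- which(is.na(r))
  if (length(bad)) {
    stopf("no van der Waals radius for element(s): %s (atom name(s) %s)",
          paste(unique(el[bad]), collapse = ", "),
          paste(unique(name[bad]), collapse = ", "))
  }
  unname(r)
}

# Infer element symbol from a PDB atom name when the element column is absent.
infer_element <- function(name) {
  nm <- toupper(trimws(name))
  nm <- sub("^[0-9']+", "", nm)
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN"),
                two, substr(nm, 1, 1))
  out
}

# Hydrogen-bond donor heavy atoms, with the bonded antecedent used for the
# antecedent-donor-acceptor angle.  Backbone amide N (antecedent CA) applies
# to every residue type except proline.
.sidechain_donors <- list(
  ARG = c(NE = "CZ", NH1 = "CZ", NH2 = "CZ"),
  LYS = c(NZ = "CE"),
  ASN = c(ND2 = "CG"),
  GLN = c(NE2 = "CD"),
  HIS = c(ND1 = "CG", NE2 = "CE1"),
  SER = c(OG = "CB"),
  THR = c(OG1 = "CB"),
  TYR = c(OH = "CZ"),
  TRP = c(NE1 = "CE2"),
  HOH = c(O = NA_character_)
)

.sidechain_acceptors <- list(
  ASP = c(OD1 = "CG", OD2 = "CG"),
  GLU = c(OE1 = "CD", OE2 = "CD"),
  ASN = c(OD1 = "CG"),
  GLN = c(OE1 = "CD"),
  SER = c(OG = "CB"),
  THR = c(OG1 = "CB"),
  TYR = c(OH = "CZ"),
  HIS = c(ND1 = "CG", NE2 = "CE1"),
  MET = c(SD = "CG"),
  HOH = c(O = NA_character_)
)

# Returns the antecedent atom name if (resname, atom) can donate, else NA.
donor_antecedent <- function(resname, atom) {
  if (atom == "N" && resname != "PRO" && resname != "HOH") return("CA")
  tab <- .sidechain_donors[[resname]]
  if (is.null(tab) || !(atom %in% names(tab))) return(NA_character_)
  tab[[atom]]
}

acceptor_antecedent <- function(resname, atom) {
  if (atom %in% c("O", "OXT") && resname != "HOH") return("C")
  tab <- .sidechain_acceptors[[resname]]
  if (is.null(tab) || !(atom %in% names(tab))) return(NA_character_)
  tab[[atom]]
}

is_donor_atom <- function(resname, atom) {
  (atom == "N" && !resname %in% c("PRO", "HOH")) ||
    (resname == "HOH" && atom == "O") ||
    (!is.null(.sidechain_donors[[resname]]) &&
       atom %in% names(.sidechain_donors[[resname]]))
}

is_acceptor_atom <- function(resname, atom) {
  (atom %in% c("O", "OXT") && resname != "HOH") ||
    (resname == "HOH" && atom == "O") ||
    (!is.null(.sidechain_acceptors[[resname]]) &&
       atom %in% names(.sidechain_acceptors[[resname]]))
}

# Formally charged side-chain atoms.  Histidine ring nitrogens are treated as
# tentatively cationic (protonation cannot be read off a crystal structure).
.anion_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.cation_atoms <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                      HIS = c("ND1", "NE2"))

is_anion_atom <- function(resname, atom) {
  (!is.null(.anion_atoms[[resname]]) && atom %in% .anion_atoms[[resname]]) ||
    atom == "OXT"
}

is_cation_atom <- function(resname, atom) {
  !is.null(.cation_atoms[[resname]]) && atom %in% .cation_atoms[[resname]]
}

# Atoms carrying the positive charge used for cation-pi geometry; the
# guanidinium carbon CZ stands for the delocalized arginine charge center.
.cation_pi_atoms <- list(ARG = c("CZ", "NH1", "NH2", "NE"), LYS = "NZ",
                         HIS = c("ND1", "NE2"))

# Aromatic ring member atoms.  Tryptophan uses its six-membered ring (the
# dominant pi face); histidine rings are included but flagged tentative.
.ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

aromatic_resnames <- function() names(.ring_atoms)

# Mean residue volumes (Angstrom^3), one-letter keyed (Zamyatnin-style set).
.residue_volume <- c(
  A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
  E = 138.4, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
  M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, W = 227.8,
  Y = 193.6, V = 140.0
)

# Side-chain formal charge at neutral pH, one-letter keyed.
.residue_charge <- c(D = -1, E = -1, K = 1, R = 1, H = 1)

residue_charge1 <- function(aa1) {
  ch <- .residue_charge[aa1]
  ifelse(is.na(ch), 0, ch)
}

.polar_set <- c("S", "T", "N", "Q", "Y", "C", "H", "K", "R", "D", "E", "W")

# Conservative-substitution groups in which a replacement is scored as
# partially compatible.
.subst_groups <- list(
  c("D", "E"), c("K", "R"), c("N", "Q"), c("S", "T"),
  c("I", "L", "V", "M"), c("F", "Y", "W")
)

same_subst_group <- function(a, b) {
  for (g in .subst_groups) if (a %in% g && b %in% g) return(TRUE)
  FALSE
}
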
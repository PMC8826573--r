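## Chemical role assignment for contact detection: hydrogen-bond donors
## and acceptors, charged centers, apolar carbons and van der Waals radii
## for the 20 standard amino acids.

.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90)

## side-chain N/O acceptors (backbone O and OXT are added for all residues)
.acceptor_atoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"),
  MET = character(0))

## side-chain donor heavy atoms (backbone N added for all but proline)
.donor_atoms <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH")

.cation_atoms <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))

.anion_atoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

## carbons with no covalently bound N or O, from standard residue topology
.apolar_atoms <- list(
  ALA = "CB",
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1", "CD"),
  MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  PRO = c("CB", "CG"),
  THR = "CG2",
  LYS = c("CB", "CG", "CD"),
  ARG = c("CB", "CG"),
  GLU = c("CB", "CG"),
  GLN = c("CB", "CG"),
  ASP = "CB",
  ASN = "CB",
  HIS = "CB",
  CYS = "CB")

.standard_resnames <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                        "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                        "PRO", "SER", "THR", "TRP", "TYR", "VAL",
                        "HID", "HIE", "HIP", "CYX")

.canon_resname <- function(rn) {
  rn <- toupper(rn)
  rn[rn %in% c("HID", "HIE", "HIP", "HSD", "HSE", "HSP")] <- "HIS"
  rn[rn == "CYX"] <- "CYS"
  rn
}

#' Assign chemical roles to atoms for contact detection
#'
#' Classifies every atom of a structure into the roles used by the
#' geometric contact predicates: hydrogen-bond donor heavy atoms and
#' acceptors, cationic nitrogens (Lys NZ, Arg guanidinium, protonated His
#' ring nitrogens), anionic oxygens (Asp/Glu carboxylates, C-terminal
#' OXT), apolar carbons (no bonded N/O), plus per-atom van der Waals
#' radii. Atoms of nonstandard residues receive a vdW radius only, with a
#' warning.
#'
#' @param structure a [Structure] or [Trajectory].
#' @return data.frame with logical columns donor, acceptor, cation,
#'   anion, apolar, hydrogen, heavy and numeric vdw.
#' @export
assignChemRoles <- function(structure) {
  a <- atoms(structure)
  rn <- .canon_resname(a$resname)
  nm <- a$name
  el <- a$element
  n <- nrow(a)
  std <- rn %in% .standard_resnames | rn %in% names(.apolar_atoms) |
         rn == "GLY"
  std <- rn %in% c(.standard_resnames, "GLY")
  if (any(!std)) {
    warning(sum(!std), " atoms in nonstandard residues (",
            paste(utils::head(unique(rn[!std]), 3), collapse = ", "),
            "): vdW radius only")
  }
  pick <- function(tab, add_bb = NULL, exclude_pro_bb = FALSE) {
    hit <- rep(FALSE, n)
    for (r in names(tab)) {
      hit <- hit | (rn == r & nm %in% tab[[r]])
    }
    if (!is.null(add_bb)) {
      bb <- nm %in% add_bb
      if (exclude_pro_bb) bb <- bb & !(rn == "PRO" & nm == "N")
      hit <- hit | bb
    }
    hit & std
  }
  acceptor <- pick(.acceptor_atoms, add_bb = c("O", "OXT"))
  donor <- pick(.donor_atoms, add_bb = "N", exclude_pro_bb = TRUE)
  cation <- pick(.cation_atoms)
  anion <- pick(.anion_atoms) | (std & nm == "OXT")
  apolar <- pick(.apolar_atoms)
  vdw <- unname(.vdw_radii[el])
  vdw[is.na(vdw)] <- 1.7
  data.frame(donor = donor, acceptor = acceptor, cation = cation,
             anion = anion, apolar = apolar,
             hydrogen = el == "H", heavy = el != "H", vdw = vdw,
             stringsAsFactors = FALSE)
}

## map each hydrogen to its bonded heavy atom (nearest heavy within
## 1.3 A in the given coordinate set); NA when unbound
.hydrogen_parents <- function(coords, roles) {
  hyd <- which(roles$hydrogen)
  heavy <- which(roles$heavy)
  parent <- rep(NA_integer_, nrow(coords))
  if (!length(hyd) || !length(heavy)) return(parent)
  d2 <- .cross_dist2(coords[hyd, , drop = FALSE],
                     coords[heavy, , drop = FALSE])
  nearest <- max.col(-d2)
  dmin <- d2[cbind(seq_along(hyd), nearest)]
  ok <- dmin <= 1.3^2
  parent[hyd[ok]] <- heavy[nearest[ok]]
  parent
}
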
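## Coarse-graining of Ig domains into beta-strands A..G and the loops
## connecting them (AB..FG). Two routes: packaged canonical residue-range
## maps per domain kind, or a simplified hydrogen-bond ladder detector.

.strand_order <- c("Nterm", "A", "AB", "B", "BC", "C", "CD", "D", "DE",
                   "E", "EF", "F", "FG", "G", "Cterm")

#' Load a canonical element map for a domain kind
#'
#' Packaged residue-range annotations map author-numbered residues of a
#' known domain kind onto the strand/loop elements of the Ig fold.
#' Residues of the selection falling before the first annotated range are
#' labeled Nterm, after the last Cterm.
#'
#' The packaged maps are curated reconstructions of the standard
#' EU/Kabat-numbered topology (see the package vignette); they can be
#' regenerated with [assignStrands()] on a reference structure.
#'
#' @param domain_kind one of "CH3", "CH1", "CL-kappa", "CL-lambda",
#'   "VH", "VL".
#' @param structure a [Structure] or [Trajectory] supplying the residues.
#' @param sel a [DomainSelection] restricting to one domain.
#' @return an [ElementMap].
#' @export
canonicalElements <- function(domain_kind, structure, sel) {
  kinds <- c("CH3" = "ch3", "CH1" = "ch1", "CL-kappa" = "cl_kappa",
             "CL-lambda" = "cl_lambda", "VH" = "vh", "VL" = "vl")
  if (!domain_kind %in% names(kinds))
    stop("unknown domain_kind '", domain_kind, "'; supported: ",
         paste(names(kinds), collapse = ", "))
  path <- system.file("extdata", "elements",
                      paste0(kinds[[domain_kind]], ".yaml"),
                      package = "AbInterface", mustWork = TRUE)
  ann <- yaml::read_yaml(path)$elements
  idx <- selectDomain(structure, sel)
  a <- atoms(structure)[idx, , drop = FALSE]
  keys <- .res_key(a$chain, a$resseq, a$icode)
  first <- !duplicated(keys)
  keys <- keys[first]
  resseq <- a$resseq[first]
  lab <- rep(NA_character_, length(keys))
  for (el in names(ann)) {
    for (rg in ann[[el]]) {
      lab[resseq >= rg[[1]] & resseq <= rg[[2]]] <- el
    }
  }
  lo <- min(unlist(lapply(ann, function(r) r[[1]][[1]])))
  hi <- max(unlist(lapply(ann, function(r) r[[1]][[2]])))
  lab[is.na(lab) & resseq < lo] <- "Nterm"
  lab[is.na(lab) & resseq > hi] <- "Cterm"
  ## residues inside the annotated span but between ranges should not
  ## occur with contiguous annotations; guard anyway
  lab[is.na(lab)] <- "Cterm"
  names(lab) <- keys
  methods::new("ElementMap", domain = sel@label, labels = lab)
}

## DSSP-style backbone H-bond energy (kcal/mol) between the C=O of
## residue i and the N-H of residue j, with the amide H inferred from the
## preceding residue's C and O positions when no hydrogen is present.
.ks_energy <- function(O_i, C_i, N_j, H_j) {
  r <- function(p, q) sqrt(sum((p - q)^2))
  q1q2f <- 0.084 * 332
  q1q2f * (1 / r(O_i, N_j) + 1 / r(C_i, H_j) -
           1 / r(O_i, H_j) - 1 / r(C_i, N_j))
}

#' Detect beta-strands from backbone hydrogen-bond ladders
#'
#' A simplified secondary-structure assignment: backbone C=O to N-H
#' hydrogen bonds are scored with the Kabsch-Sander electrostatic model
#' (partial charges 0.42/0.20 e, bond called at energy < -0.5 kcal/mol),
#' amide hydrogens inferred from the preceding peptide plane when absent.
#' Residues hydrogen-bonded to a sequence-distant partner (>= 3 residues
#' away) form strand segments, labeled A.. in sequence order; intervening
#' residues are labeled by their flanking strands, tails Nterm/Cterm.
#'
#' @param structure a [Structure] with backbone N, CA, C, O atoms.
#' @param sel a [DomainSelection].
#' @param energy_cutoff H-bond energy threshold, kcal/mol (default -0.5).
#' @param min_strand minimum strand length in residues (default 2).
#' @return an [ElementMap].
#' @export
assignStrands <- function(structure, sel, energy_cutoff = -0.5,
                          min_strand = 2L) {
  idx <- selectDomain(structure, sel)
  a <- atoms(structure)[idx, , drop = FALSE]
  xyz <- coords(structure)[idx, , drop = FALSE]
  keys <- .res_key(a$chain, a$resseq, a$icode)
  ukeys <- unique(keys)
  nres <- length(ukeys)
  get_atom <- function(k, nm) {
    i <- which(keys == k & a$name == nm)
    if (!length(i)) return(NULL)
    xyz[i[1], ]
  }
  N <- lapply(ukeys, get_atom, "N")
  CA <- lapply(ukeys, get_atom, "CA")
  C <- lapply(ukeys, get_atom, "C")
  O <- lapply(ukeys, get_atom, "O")
  ok <- !vapply(N, is.null, TRUE) & !vapply(CA, is.null, TRUE) &
        !vapply(C, is.null, TRUE) & !vapply(O, is.null, TRUE)
  if (sum(ok) < 4) stop("backbone N, CA, C, O atoms required")
  ## inferred amide H: N + unit(C_prev - O_prev); first residue has none
  H <- vector("list", nres)
  for (i in 2:nres) {
    if (ok[i] && ok[i - 1]) {
      H[[i]] <- N[[i]] + .unit(C[[i - 1]] - O[[i - 1]])
    }
  }
  bonded <- rep(FALSE, nres)
  for (i in which(ok)) {
    for (j in which(ok)) {
      if (abs(i - j) < 3 || is.null(H[[j]])) next
      if (sqrt(sum((O[[i]] - N[[j]])^2)) > 5.0) next
      if (.ks_energy(O[[i]], C[[i]], N[[j]], H[[j]]) < energy_cutoff) {
        bonded[i] <- TRUE
        bonded[j] <- TRUE
      }
    }
  }
  ## strand segments: maximal runs of ladder residues (1-residue gaps kept)
  filled <- bonded
  for (i in 2:(nres - 1)) {
    if (!bonded[i] && bonded[i - 1] && bonded[i + 1]) filled[i] <- TRUE
  }
  rl <- rle(filled)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  seg <- which(rl$values & rl$lengths >= min_strand)
  if (length(seg) < 2)
    stop("fewer than 2 beta-strands detected; not a sheet domain")
  if (length(seg) > 7)
    stop(length(seg), " strands detected (> 7); supply a manual ",
         "element annotation for this domain")
  lab <- rep(NA_character_, nres)
  letters7 <- c("A", "B", "C", "D", "E", "F", "G")
  for (s in seq_along(seg)) {
    lab[starts[seg[s]]:ends[seg[s]]] <- letters7[s]
  }
  ## loops labeled by flanking strands; tails Nterm/Cterm
  firsts <- starts[seg]
  lasts <- ends[seg]
  if (firsts[1] > 1) lab[1:(firsts[1] - 1)] <- "Nterm"
  nseg <- length(seg)
  if (lasts[nseg] < nres) lab[(lasts[nseg] + 1):nres] <- "Cterm"
  for (s in seq_len(nseg - 1)) {
    gap <- (lasts[s] + 1):(firsts[s + 1] - 1)
    if (length(gap) && gap[1] <= gap[length(gap)])
      lab[gap] <- paste0(letters7[s], letters7[s + 1])
  }
  names(lab) <- ukeys
  methods::new("ElementMap", domain = sel@label, labels = lab)
}

#' Look up element labels for residues
#'
#' @param map an [ElementMap].
#' @param keys residue keys ("chain:resseq[:icode]").
#' @return character vector of element labels (NA when unmapped).
#' @export
elementOf <- function(map, keys) {
  unname(map@labels[keys])
}
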
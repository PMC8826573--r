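## Interdomain electrostatic interaction energies: per-frame pairwise
## Coulomb sums between the two domain selections, the electrostatic
## half of a linear-interaction-energy style analysis.

.coulomb_k <- 332.0636  # kcal*A/(mol*e^2)

#' Interdomain Coulomb energy of one frame
#'
#' E = k * sum over pairs (i in a, j in b, r_ij <= cutoff) of
#' q_i q_j / (dielectric * r_ij), with k = 332.0636 kcal*A/(mol*e^2).
#'
#' @param xyz N x 3 coordinates, Angstrom.
#' @param charges per-atom charges, e (full structure indexing).
#' @param sel_a,sel_b atom index vectors.
#' @param cutoff pair distance cutoff in Angstrom, or Inf for none
#'   (default 12).
#' @param dielectric relative dielectric constant (default 1).
#' @return energy in kcal/mol.
#' @export
coulombEnergy <- function(xyz, charges, sel_a, sel_b, cutoff = 12,
                          dielectric = 1) {
  if (!is.infinite(cutoff) && cutoff <= 0) stop("cutoff must be positive")
  qa <- charges[sel_a]
  qb <- charges[sel_b]
  if (anyNA(qa) || anyNA(qb)) {
    bad <- c(sel_a[is.na(qa)], sel_b[is.na(qb)])[1]
    stop("atom without charge: index ", bad)
  }
  d2 <- .cross_dist2(xyz[sel_a, , drop = FALSE],
                     xyz[sel_b, , drop = FALSE])
  if (any(d2 < 0.25))
    stop("interdomain atom pair closer than 0.5 A: clash or corrupt input")
  r <- sqrt(d2)
  inv <- 1 / r
  if (!is.infinite(cutoff)) inv[r > cutoff] <- 0
  .coulomb_k / dielectric * sum(outer(qa, qb) * inv)
}

#' Electrostatic energy series over a trajectory
#'
#' Per-frame interdomain Coulomb energies plus the simulation mean and
#' sample standard deviation.
#'
#' @param traj a [Trajectory].
#' @param charges per-atom charges, e; defaults to the topology's charge
#'   column (e.g. from [readPQR()]).
#' @param sel_a,sel_b atom index vectors.
#' @param cutoff,dielectric as in [coulombEnergy()].
#' @return an [EnergySeries].
#' @export
energySeries <- function(traj, sel_a, sel_b,
                         charges = atoms(traj)$charge,
                         cutoff = 12, dielectric = 1) {
  nf <- nFrames(traj)
  e <- vapply(seq_len(nf), function(f)
    coulombEnergy(traj@frames[, , f], charges, sel_a, sel_b,
                  cutoff, dielectric), 0)
  methods::new("EnergySeries", energy = e, mean = mean(e),
               sd = if (nf > 1) stats::sd(e) else 0,
               cutoff = cutoff, dielectric = dielectric)
}

#' Residue-level fallback charges for test and demonstration use
#'
#' Assigns +1 e to Lys NZ and Arg CZ, -0.5 e to each carboxylate oxygen
#' of Asp/Glu, and 0 elsewhere -- a coarse charge model sufficient to
#' exercise the electrostatics analysis when no PQR charges are
#' available. Not a force field.
#'
#' @param structure a [Structure] or [Trajectory].
#' @return numeric charge vector, e.
#' @export
coarseCharges <- function(structure) {
  a <- atoms(structure)
  rn <- .canon_resname(a$resname)
  q <- numeric(nrow(a))
  q[rn == "LYS" & a$name == "NZ"] <- 1
  q[rn == "ARG" & a$name == "CZ"] <- 1
  q[rn == "ASP" & a$name %in% c("OD1", "OD2")] <- -0.5
  q[rn == "GLU" & a$name %in% c("OE1", "OE2")] <- -0.5
  q
}

#' Write an energy series as tab-separated text
#'
#' Rows of (frame, E_elec) followed by no summary row; the mean/sd are
#' in the returned object and the run manifest.
#'
#' @param series an [EnergySeries].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEnergyTSV <- function(series, path) {
  utils::write.table(
    data.frame(frame = seq_along(series@energy), E_elec = series@energy),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
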
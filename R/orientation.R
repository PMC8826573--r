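## Interdomain orientation coordinate system. A reference frame is built
## once from a reference structure: each domain is aligned to the world
## frame (first principal axis of inertia on +z, the interdomain center
## axis pulled as close as possible to +x). Mapping the references onto a
## sample frame by Kabsch alignment and transforming the unit vectors
## yields six measures: torsion AB, tilts AC1/AC2/BC1/BC2 and the
## center-of-mass distance dC.

#' First principal axis of inertia
#'
#' Unit eigenvector of the inertia tensor (about the center of mass) for
#' the smallest eigenvalue -- the long axis of the mass distribution.
#' The +/- ambiguity is resolved by requiring a positive dot product with
#' the vector from the first to the last alignment atom.
#'
#' @param xyz N x 3 coordinates.
#' @param masses atom masses (default: unit).
#' @param orient_vec vector used to fix the sign (default: first -> last
#'   coordinate row).
#' @return unit 3-vector.
#' @export
inertiaAxis <- function(xyz, masses = NULL, orient_vec = NULL) {
  if (nrow(xyz) < 3) stop("need at least 3 points")
  if (is.null(masses)) masses <- rep(1, nrow(xyz))
  com <- colSums(xyz * masses) / sum(masses)
  r <- sweep(xyz, 2, com)
  x <- r[, 1]; y <- r[, 2]; z <- r[, 3]
  I <- matrix(c(
    sum(masses * (y^2 + z^2)), -sum(masses * x * y), -sum(masses * x * z),
    -sum(masses * x * y), sum(masses * (x^2 + z^2)), -sum(masses * y * z),
    -sum(masses * x * z), -sum(masses * y * z), sum(masses * (x^2 + y^2))),
    3, 3)
  e <- eigen(I, symmetric = TRUE)
  vals <- e$values  # decreasing
  if (abs(vals[2] - vals[3]) <= 1e-6 * max(abs(vals)))
    stop("degenerate inertia spectrum: principal axis ill-defined; ",
         "use a larger atom selection")
  ax <- e$vectors[, 3]
  if (is.null(orient_vec)) orient_vec <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(ax * orient_vec) < 0) ax <- -ax
  .unit(ax)
}

## mass-weighted center
.wcenter <- function(xyz, w) colSums(xyz * w) / sum(w)

## align one domain: principal axis -> +z, center axis toward +x.
## Returns the rotation applied (coords %*% R after centering).
.align_domain <- function(xyz, w, center_axis, fit_rows) {
  com <- .wcenter(xyz, w)
  centered <- sweep(xyz, 2, com)
  ov <- centered[fit_rows[length(fit_rows)], ] - centered[fit_rows[1], ]
  p <- inertiaAxis(centered, w, orient_vec = ov)
  ang <- .vec_angle(p, center_axis)
  if (ang < 1 || ang > 179)
    stop("center axis nearly parallel to principal axis (", round(ang, 2),
         " deg): x-alignment undefined")
  R1 <- .rot_between(p, c(0, 0, 1))
  c1 <- as.vector(center_axis %*% R1)
  ## Gram-Schmidt: component of the center axis orthogonal to z, then
  ## spin about z to put it on +x
  cp <- c(c1[1], c1[2], 0)
  phi <- .deg(atan2(cp[2], cp[1]))
  R2 <- .rot_about(c(0, 0, 1), -phi)
  list(coords = centered %*% R1 %*% R2, R = R1 %*% R2)
}

#' Build an orientation reference from a structure
#'
#' Aligns each domain of a reference complex to the world frame: the
#' first principal axis of inertia goes to +z, then the domain spins
#' about z until the interdomain center axis (a-center to b-center) has
#' its maximal component on +x. Centers and inertia tensors use
#' mass-weighted heavy atoms by default; Kabsch alignment atoms are the
#' domain Calpha.
#'
#' @param structure a [Structure] or [Trajectory] (frame 1 used).
#' @param sel_a,sel_b atom index vectors for the two domains.
#' @param weighting "heavy" (mass-weighted heavy atoms, default) or "CA".
#' @return an [OrientationReference].
#' @export
buildReference <- function(structure, sel_a, sel_b, weighting = "heavy") {
  xyz <- coords(structure)
  a <- atoms(structure)
  pick <- function(sel) {
    if (weighting == "CA") {
      sel[a$name[sel] == "CA"]
    } else {
      sel[a$element[sel] != "H"]
    }
  }
  ia <- pick(sel_a); ib <- pick(sel_b)
  wa <- a$mass[ia]; wb <- a$mass[ib]
  wa[is.na(wa)] <- 12; wb[is.na(wb)] <- 12
  if (weighting == "CA") { wa[] <- 1; wb[] <- 1 }
  ca <- .wcenter(xyz[ia, , drop = FALSE], wa)
  cb <- .wcenter(xyz[ib, , drop = FALSE], wb)
  axis <- cb - ca
  fit_a <- which(a$name[ia] == "CA")
  fit_b <- which(a$name[ib] == "CA")
  if (length(fit_a) < 3 || length(fit_b) < 3)
    stop("need >= 3 Calpha atoms per domain for alignment")
  al_a <- .align_domain(xyz[ia, , drop = FALSE], wa, axis, fit_a)
  al_b <- .align_domain(xyz[ib, , drop = FALSE], wb, axis, fit_b)
  methods::new("OrientationReference",
               ref_a = al_a$coords, ref_b = al_b$coords,
               fit_a = as.integer(fit_a), fit_b = as.integer(fit_b),
               idx_a = as.integer(ia), idx_b = as.integer(ib),
               w_a = wa, w_b = wb, axes = diag(3))
}

#' Six orientation measures for one frame
#'
#' Each domain reference is Kabsch-aligned (over Calpha) onto the frame;
#' the alignment rotations applied to the world unit vectors give
#' A1 = R_a z, A2 = R_a y, B1 = R_b z, B2 = R_b y. With C the a-to-b
#' center axis: AC1 = angle(A1, C), AC2 = angle(A2, C), BC1 =
#' angle(B1, -C), BC2 = angle(B2, -C), dC = |C|, and AB the signed
#' torsion from A1 to B1 about C (right-handed, (-180, 180]).
#'
#' @param reference an [OrientationReference].
#' @param xyz N x 3 frame coordinates (full structure indexing).
#' @param rmsd_warn warn when either domain fits worse than this RMSD
#'   (default 5 A), indicating a reference mismatch.
#' @return named numeric vector (AB, AC1, AC2, BC1, BC2, dC).
#' @export
measureFrame <- function(reference, xyz, rmsd_warn = 5) {
  r <- reference
  sa <- xyz[r@idx_a, , drop = FALSE]
  sb <- xyz[r@idx_b, , drop = FALSE]
  ka <- .kabsch(r@ref_a[r@fit_a, , drop = FALSE],
                sa[r@fit_a, , drop = FALSE])
  kb <- .kabsch(r@ref_b[r@fit_b, , drop = FALSE],
                sb[r@fit_b, , drop = FALSE])
  if (ka$rmsd > rmsd_warn || kb$rmsd > rmsd_warn)
    warning(sprintf("reference mismatch: fit RMSD %.2f / %.2f A",
                    ka$rmsd, kb$rmsd))
  ## unit vectors transform by the rotation only
  A1 <- as.vector(c(0, 0, 1) %*% ka$R)
  A2 <- as.vector(c(0, 1, 0) %*% ka$R)
  B1 <- as.vector(c(0, 0, 1) %*% kb$R)
  B2 <- as.vector(c(0, 1, 0) %*% kb$R)
  ca <- .wcenter(sa, r@w_a)
  cb <- .wcenter(sb, r@w_b)
  C <- cb - ca
  dC <- sqrt(sum(C^2))
  Ch <- C / dC
  c(AB = .torsion_about(A1, B1, Ch),
    AC1 = .vec_angle(A1, Ch), AC2 = .vec_angle(A2, Ch),
    BC1 = .vec_angle(B1, -Ch), BC2 = .vec_angle(B2, -Ch),
    dC = dC)
}

#' Orientation measures over a trajectory
#'
#' @param traj a [Trajectory].
#' @param reference an [OrientationReference].
#' @param aliases optional measure-name aliases: "Fv" renames
#'   (AB, AC1, AC2, BC1, BC2) to (HL, LC1, LC2, HC1, HC2), "CH1-CL" to
#'   the c-prefixed constant-domain names.
#' @return data.frame with one row per frame: frame plus the six measures.
#' @export
measureTrajectory <- function(traj, reference, aliases = NULL) {
  nf <- nFrames(traj)
  out <- matrix(NA_real_, nf, 6)
  for (f in seq_len(nf)) {
    out[f, ] <- measureFrame(reference, traj@frames[, , f])
  }
  nm <- c("AB", "AC1", "AC2", "BC1", "BC2", "dC")
  if (!is.null(aliases)) {
    nm <- switch(aliases,
      "Fv" = c("HL", "LC1", "LC2", "HC1", "HC2", "dC"),
      "CH1-CL" = c("cHL", "cLC1", "cLC2", "cHC1", "cHC2", "dC"),
      nm)
  }
  df <- data.frame(frame = seq_len(nf), out)
  names(df) <- c("frame", nm)
  df
}

#' Gaussian kernel density estimate of an angle distribution
#'
#' Gaussian KDE on a 0.1-degree grid spanning the samples +/- 4
#' bandwidths. The bandwidth defaults to Silverman's rule of thumb.
#'
#' @param samples numeric vector, degrees.
#' @param bandwidth kernel bandwidth in degrees (default: Silverman).
#' @return list with grid, density, bandwidth; the trapezoidal integral
#'   of density over grid is 1 within 1e-3.
#' @export
kdeDensity <- function(samples, bandwidth = NULL) {
  if (length(samples) < 2) stop("need at least 2 samples")
  if (stats::sd(samples) == 0 && is.null(bandwidth))
    stop("zero-variance samples: supply an explicit bandwidth")
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(samples) else bandwidth
  lo <- min(samples) - 4 * bw
  hi <- max(samples) + 4 * bw
  n <- max(2L, as.integer(round((hi - lo) / 0.1)) + 1L)
  d <- stats::density(samples, bw = bw, kernel = "gaussian",
                      from = lo, to = hi, n = n)
  list(grid = d$x, density = d$y, bandwidth = bw)
}

#' Optimal superposition and RMSD of two coordinate sets
#'
#' Least-squares Kabsch superposition with a proper rotation enforced
#' (determinant correction; a reflection is never returned).
#'
#' @param mobile,target N x 3 coordinate matrices, rows paired.
#' @return list with rotation (3 x 3), translation (length 3; apply as
#'   mobile %*% rotation + translation), and rmsd in Angstrom.
#' @export
superpose <- function(mobile, target) {
  k <- .kabsch(mobile, target)
  list(rotation = k$R, translation = k$t, rmsd = k$rmsd)
}

#' Root-mean-square fluctuation per residue
#'
#' Superposes every frame onto the reference frame over the selection's
#' Calpha atoms, then computes for each residue the RMS displacement of
#' its Calpha from its time-average position.
#'
#' @param traj a [Trajectory].
#' @param sel atom index vector (the fit and the report use its Calpha).
#' @param ref_frame frame used as superposition target (default 1).
#' @return named numeric vector, Angstrom, over residues with a Calpha.
#' @export
computeRMSF <- function(traj, sel, ref_frame = 1L) {
  nf <- nFrames(traj)
  if (nf < 2) stop("need at least 2 frames for RMSF")
  a <- atoms(traj)
  ca <- sel[a$name[sel] == "CA"]
  skip <- unique(.res_key(a$chain[sel], a$resseq[sel], a$icode[sel]))
  have <- .res_key(a$chain[ca], a$resseq[ca], a$icode[ca])
  if (length(setdiff(skip, have)))
    warning(length(setdiff(skip, have)),
            " residues without Calpha skipped")
  target <- traj@frames[ca, , ref_frame]
  fitted <- array(NA_real_, c(length(ca), 3, nf))
  for (f in seq_len(nf)) {
    x <- traj@frames[ca, , f]
    k <- .kabsch(x, target)
    fitted[, , f] <- sweep(x %*% k$R, 2, k$t, "+")
  }
  mpos <- apply(fitted, c(1, 2), mean)
  disp2 <- vapply(seq_len(nf), function(f)
    rowSums((fitted[, , f] - mpos)^2), numeric(length(ca)))
  if (length(ca) == 1) disp2 <- matrix(disp2, nrow = 1)
  stats::setNames(sqrt(rowMeans(disp2)), have)
}

#' Write an orientation series as tab-separated text
#'
#' @param series data.frame from [measureTrajectory()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeOrientationTSV <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
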
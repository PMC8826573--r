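## Synthetic two-domain complexes with known orientation and planted
## contact lifetimes: idealized antiparallel beta-sheet "domains"
## assembled at a requested torsion/tilt/distance, plus pseudo-trajectory
## generation with Gaussian coordinate noise and Bernoulli contact
## planting. The generator is the ground-truth stand-in for MD frame
## ensembles in all validation tests.

.run_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## side-chain templates: offsets from CA, z pointing away from the sheet
## plane (the eventual interface side); bond geometry is idealized
.sidechain_z <- list(
  ALA = list(CB = c(0, 0, -1.5)),
  LEU = list(CB = c(0, 0, -1.5), CG = c(0, 0, -2.9),
             CD1 = c(0.9, 0, -4.1), CD2 = c(-0.9, 0, -4.1)),
  LYS = list(CB = c(0, 0, -1.5), CG = c(0, 0, -2.9), CD = c(0, 0, -4.3),
             CE = c(0, 0, -5.7), NZ = c(0, 0, -7.0)),
  GLU = list(CB = c(0, 0, -1.5), CG = c(0, 0, -2.9), CD = c(0, 0, -4.3),
             OE1 = c(0.9, 0, -5.3), OE2 = c(-0.9, 0, -5.3)),
  ASN = list(CB = c(0, 0, -1.5), CG = c(0, 0, -2.9),
             OD1 = c(0.9, 0, -3.9), ND2 = c(-0.9, 0, -3.9)))

#' Build an idealized beta-sheet toy domain
#'
#' Constructs a poly-alanine antiparallel beta-sheet with ideal backbone
#' geometry: 3.5 A Calpha rise along each strand, 4.8 A strand spacing,
#' carbonyl oxygens alternating across the sheet so that the
#' Kabsch-Sander ladder criterion recovers every strand; strands are
#' joined by 3-residue out-of-plane loops. Selected residues can be
#' mutated to Lys/Glu/Leu/Asn (side chains extended toward -z, the
#' interface side) to support each contact kind. Purely deterministic.
#'
#' @param n_strands number of strands (>= 2; constant Ig domains have 7).
#' @param residues_per_strand residues per strand (even, >= 4).
#' @param chain chain identifier.
#' @param mutations named character vector: residue number -> resname
#'   ("LYS", "GLU", "LEU", "ASN").
#' @param seed accepted for interface uniformity; the builder is
#'   deterministic and does not consume randomness.
#' @return a [Structure].
#' @export
buildToyDomain <- function(n_strands = 7, residues_per_strand = 6,
                           chain = "A", mutations = NULL, seed = 1) {
  if (n_strands < 2) stop("need at least 2 strands")
  if (residues_per_strand < 4 || residues_per_strand %% 2 != 0)
    stop("residues_per_strand must be even and >= 4")
  L <- residues_per_strand
  rows <- list()
  resno <- 0
  add_res <- function(resname, bb, sc) {
    resno <<- resno + 1
    nm <- c(names(bb), names(sc))
    xyz <- rbind(do.call(rbind, bb), do.call(rbind, sc))
    list(resno = resno, resname = resname, names = nm, xyz = xyz)
  }
  for (s in seq_len(n_strands) - 1) {
    d <- if (s %% 2 == 0) 1 else -1
    y <- 4.8 * s
    for (i in seq_len(L) - 1) {
      cax <- if (d == 1) 3.5 * i else 3.5 * (L - 1 - i)
      ca <- c(cax, y, 0)
      oy <- if (i %% 2 == 0) 1 else -1
      bb <- list(N = ca - c(d * 1.2, 0, 0),
                 CA = ca,
                 C = ca + c(d * 1.2, 0, 0),
                 O = ca + c(d * 1.2, oy * 1.23, 0))
      rn <- "ALA"
      if (!is.null(mutations)) {
        hit <- mutations[names(mutations) == as.character(resno + 1)]
        if (length(hit)) rn <- hit[[1]]
      }
      sc <- lapply(.sidechain_z[[rn]], function(off) ca + off)
      rows[[length(rows) + 1]] <- add_res(rn, bb, sc)
    }
    ## connecting loop, 3 residues out of the sheet plane
    if (s < n_strands - 1) {
      x_end <- if (d == 1) 3.5 * (L - 1) else 0
      for (k in 1:3) {
        ca <- c(x_end + d * 1.0 * (k %% 2), y + 4.8 * k / 4, 3.5 + 0.5 * k)
        bb <- list(N = ca - c(0, 0.6, 0.9), CA = ca,
                   C = ca + c(0, 0.6, 0.9),
                   O = ca + c(0, 0.6, 2.1))
        sc <- lapply(.sidechain_z$ALA, function(off) ca + off)
        rows[[length(rows) + 1]] <- add_res("ALA", bb, sc)
      }
    }
  }
  nat <- sum(vapply(rows, function(r) length(r$names), 0L))
  name <- character(nat); resname <- character(nat)
  resseq <- integer(nat); xyz <- matrix(0, nat, 3)
  k <- 0
  for (r in rows) {
    n <- length(r$names)
    name[k + seq_len(n)] <- r$names
    resname[k + seq_len(n)] <- r$resname
    resseq[k + seq_len(n)] <- r$resno
    xyz[k + seq_len(n), ] <- r$xyz
    k <- k + n
  }
  element <- .infer_element(name, "")
  atoms <- data.frame(
    serial = seq_len(nat), name = name, altloc = "",
    resname = resname, chain = chain, resseq = as.integer(resseq),
    icode = "",
    element = element, occupancy = 1, bfactor = 0, charge = NA_real_,
    mass = unname(.element_masses[element]), stringsAsFactors = FALSE)
  methods::new("Structure", atoms = atoms, coords = xyz)
}

#' Assemble two toy domains at a requested relative orientation
#'
#' Places domain b relative to domain a so that the orientation measures
#' of the assembled complex (against its own reference, see
#' [buildReference()]) equal the request: torsion AB, tilt AC1 of the
#' a principal axis against the center axis, tilt BC1 of the b principal
#' axis against the reversed center axis, and center distance dC. The
#' remaining tilts AC2/BC2 are 90 degrees by construction for a complex
#' that serves as its own reference.
#'
#' @param dom_a,dom_b [Structure]s (see [buildToyDomain()]); chains are
#'   relabeled "A"/"B".
#' @param torsion AB torsion, degrees in (-180, 180].
#' @param tilt_a,tilt_b AC1 / BC1 tilt angles, degrees in (1, 179).
#' @param dC center-of-mass distance, Angstrom.
#' @return list with structure ([Structure]), sel_a, sel_b (atom index
#'   vectors) and truth (named measures as constructed).
#' @export
assembleComplex <- function(dom_a, dom_b, torsion = 90, tilt_a = 40,
                            tilt_b = 40, dC = 30) {
  if (tilt_a <= 1 || tilt_a >= 179 || tilt_b <= 1 || tilt_b >= 179)
    stop("tilts must lie in (1, 179) degrees")
  place <- function(dom) {
    a <- atoms(dom)
    xyz <- coords(dom)
    heavy <- a$element != "H"
    w <- a$mass; w[is.na(w)] <- 12
    com <- .wcenter(xyz[heavy, , drop = FALSE], w[heavy])
    centered <- sweep(xyz, 2, com)
    cas <- which(a$name == "CA")
    ov <- centered[cas[length(cas)], ] - centered[cas[1], ]
    p <- inertiaAxis(centered[heavy, , drop = FALSE], w[heavy],
                     orient_vec = ov)
    centered %*% .rot_between(p, c(0, 0, 1))
  }
  xa <- place(dom_a)
  xb0 <- place(dom_b)
  ch <- sin(.rad(tilt_a)) * c(1, 0, 0) + cos(.rad(tilt_a)) * c(0, 0, 1)
  e1 <- .unit(c(0, 0, 1) - cos(.rad(tilt_a)) * ch)
  e2 <- .cross3(ch, e1)
  b1 <- -cos(.rad(tilt_b)) * ch +
    sin(.rad(tilt_b)) * (cos(.rad(torsion)) * e1 +
                         sin(.rad(torsion)) * e2)
  xb <- xb0 %*% .rot_between(c(0, 0, 1), b1)
  xb <- sweep(xb, 2, dC * ch, "+")
  ## merge
  aa <- atoms(dom_a); ab <- atoms(dom_b)
  aa$chain <- "A"; ab$chain <- "B"
  merged <- rbind(aa, ab)
  merged$serial <- seq_len(nrow(merged))
  rownames(merged) <- NULL
  xyz <- rbind(xa, xb)
  dimnames(xyz) <- NULL
  sel_a <- seq_len(nrow(aa))
  sel_b <- nrow(aa) + seq_len(nrow(ab))
  hm <- merged$element != "H"
  mind <- sqrt(min(.cross_dist2(xyz[intersect(sel_a, which(hm)), ],
                                xyz[intersect(sel_b, which(hm)), ])))
  if (mind < 2)
    stop(sprintf("interdomain clash: closest approach %.2f A < 2 A", mind))
  st <- methods::new("Structure", atoms = merged, coords = xyz)
  list(structure = st, sel_a = sel_a, sel_b = sel_b,
       truth = c(AB = torsion, AC1 = tilt_a, AC2 = 90,
                 BC1 = tilt_b, BC2 = 90, dC = dC))
}

## per-kind tip atoms used for contact planting; the a tip stays fixed,
## the b side chain is translated rigidly
.plant_atoms <- function(atoms, residue_key, kind, side) {
  keys <- .res_key(atoms$chain, atoms$resseq, atoms$icode)
  in_res <- which(keys == residue_key)
  if (!length(in_res)) stop("planted residue not found: ", residue_key)
  rn <- .canon_resname(atoms$resname[in_res[1]])
  nm <- atoms$name[in_res]
  tip_names <- switch(kind,
    saltbridge = if (rn == "LYS") "NZ" else c("OE1", "OE2"),
    ## uncharged amide pair so the salt-bridge channel cannot claim it
    hbond = if (side == "a") "OD1" else "ND2",
    hydrophobic = c("CD1", "CD2"),
    vdw = if (side == "a") "O" else "CB",
    stop("unknown contact kind: ", kind))
  tips <- in_res[nm %in% tip_names]
  if (!length(tips))
    stop(sprintf("residue %s lacks %s tip atoms for a %s plant",
                 residue_key, paste(tip_names, collapse = "/"), kind))
  movable <- in_res[!nm %in% c("N", "CA", "C", "O")]
  list(tips = tips, movable = movable, resname = rn)
}

## thresholds per kind under the default criteria; planting places the
## tip pair at threshold - 0.8 ("in") or threshold + 1.0 ("out")
.plant_threshold <- function(kind, criteria) {
  switch(kind,
    saltbridge = criteria@saltbridge_max,
    hbond = criteria@hbond_da_max,
    hydrophobic = criteria@hydrophobic_max,
    vdw = 1.52 + 1.70 + criteria@vdw_slack)
}

#' Generate a pseudo-trajectory with noise and planted contacts
#'
#' Per frame: optionally rotate domain b rigidly about the interdomain
#' center axis to a planted torsion; add isotropic Gaussian coordinate
#' noise to every atom; then, for each planted contact, with probability
#' `target_ratio` translate the b-side side chain so the contact's tip
#' atoms sit below the detection threshold for its kind, otherwise
#' beyond the threshold + 1 A. All Bernoulli draws come from one
#' generator seeded once and are recorded in the ground truth.
#'
#' A planted "hbond" adds an amide-like hydrogen on the donor tip,
#' repositioned along the donor-acceptor line every frame so the
#' D-H...A angle criterion is met in contact frames.
#'
#' @param complex result of [assembleComplex()].
#' @param n_frames number of frames (the study-scale ensembles use
#'   10,000).
#' @param noise_sigma isotropic Gaussian coordinate noise, A (default
#'   0.1).
#' @param planted list of plants: list(residue_a=, residue_b=, kind=,
#'   target_ratio=) with residue keys like "A:10".
#' @param torsion_series optional per-frame AB torsion values, degrees.
#' @param criteria [ContactCriteria] defining the thresholds planted
#'   against.
#' @param seed integer seed.
#' @return list with traj ([Trajectory]), truth (data.frame frame x
#'   plant presence draws) and torsion (per-frame true AB).
#' @export
synthTrajectory <- function(complex, n_frames = 10000, noise_sigma = 0.1,
                            planted = list(), torsion_series = NULL,
                            criteria = contactCriteria(), seed = 1) {
  st <- complex$structure
  a <- atoms(st)
  base <- coords(st)
  n <- nrow(base)
  if (!is.null(torsion_series) && length(torsion_series) != n_frames)
    stop("torsion_series must have one value per frame")
  ## plant bookkeeping (and duplicate-residue-pair guard)
  pk <- vapply(planted, function(p) paste(p$residue_a, p$residue_b), "")
  if (anyDuplicated(pk))
    stop("contradictory plants: residue pair listed twice")
  plants <- lapply(planted, function(p) {
    pa <- .plant_atoms(a, p$residue_a, p$kind, "a")
    pb <- .plant_atoms(a, p$residue_b, p$kind, "b")
    stopifnot(p$target_ratio >= 0, p$target_ratio <= 1)
    list(kind = p$kind, ratio = p$target_ratio, tips_a = pa$tips,
         tips_b = pb$tips, movable = pb$movable,
         thr = .plant_threshold(p$kind, criteria))
  })
  ## donor hydrogens for hbond plants become extra atoms
  hb_plants <- which(vapply(plants, function(p) p$kind == "hbond", TRUE))
  h_extra <- length(hb_plants)
  if (h_extra) {
    hrows <- a[rep(1, h_extra), , drop = FALSE]
    for (k in seq_len(h_extra)) {
      don <- plants[[hb_plants[k]]]$tips_b[1]
      hrows$serial[k] <- n + k
      hrows$name[k] <- "HZ1"
      hrows$resname[k] <- a$resname[don]
      hrows$chain[k] <- a$chain[don]
      hrows$resseq[k] <- a$resseq[don]
      hrows$icode[k] <- a$icode[don]
      hrows$element[k] <- "H"
      hrows$mass[k] <- .element_masses[["H"]]
      plants[[hb_plants[k]]]$hydrogen <- n + k
      plants[[hb_plants[k]]]$movable <-
        c(plants[[hb_plants[k]]]$movable, n + k)
    }
    a <- rbind(a, hrows)
    rownames(a) <- NULL
    base <- rbind(base, base[vapply(seq_len(h_extra), function(k)
      plants[[hb_plants[k]]]$tips_b[1], 0L), , drop = FALSE] +
        matrix(rep(c(0, 0, 1), each = h_extra), ncol = 3))
    n <- nrow(base)
  }
  ## center-axis geometry for torsion planting
  heavy <- a$element != "H"
  w <- a$mass; w[is.na(w)] <- 12
  ha <- intersect(complex$sel_a, which(heavy))
  hb <- intersect(complex$sel_b, which(heavy))
  com_a <- .wcenter(base[ha, , drop = FALSE], w[ha])
  com_b <- .wcenter(base[hb, , drop = FALSE], w[hb])
  ch <- .unit(com_b - com_a)
  base_tors <- complex$truth[["AB"]]
  sel_b_all <- union(complex$sel_b,
                     if (h_extra) (nrow(coords(complex$structure)) +
                                     seq_len(h_extra)) else integer(0))
  frames <- array(NA_real_, c(n, 3, n_frames))
  truth <- matrix(NA, n_frames, length(plants))
  tors <- numeric(n_frames)
  .run_seeded(seed, {
    for (f in seq_len(n_frames)) {
      x <- base
      tt <- if (is.null(torsion_series)) base_tors else torsion_series[f]
      tors[f] <- tt
      if (abs(tt - base_tors) > 1e-12) {
        R <- .rot_about(ch, tt - base_tors)
        xb <- sweep(x[sel_b_all, , drop = FALSE], 2, com_a)
        x[sel_b_all, ] <- sweep(xb %*% R, 2, com_a, "+")
      }
      if (noise_sigma > 0)
        x <- x + matrix(stats::rnorm(n * 3, 0, noise_sigma), n, 3)
      for (p in seq_along(plants)) {
        pl <- plants[[p]]
        present <- stats::runif(1) < pl$ratio
        truth[f, p] <- present
        target <- if (present) pl$thr - 0.8 else pl$thr + 1.0
        for (it in 1:6) {
          d2 <- .cross_dist2(x[pl$tips_a, , drop = FALSE],
                             x[pl$tips_b, , drop = FALSE])
          mi <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
          ta <- x[pl$tips_a[mi[1]], ]
          tb <- x[pl$tips_b[mi[2]], ]
          u <- .unit(tb - ta)
          delta <- (target - sqrt(min(d2))) * u
          x[pl$movable, ] <- sweep(x[pl$movable, , drop = FALSE], 2,
                                   delta, "+")
          dmin <- sqrt(min(.cross_dist2(x[pl$tips_a, , drop = FALSE],
                                        x[pl$tips_b, , drop = FALSE])))
          if (abs(dmin - target) < 1e-9) break
        }
        if (!is.null(pl$hydrogen)) {
          ## hydrogen 1.0 A from the donor toward the closest acceptor tip
          d2 <- .cross_dist2(x[pl$tips_b[1], , drop = FALSE],
                             x[pl$tips_a, , drop = FALSE])
          acc <- x[pl$tips_a[which.min(d2)], ]
          don <- x[pl$tips_b[1], ]
          x[pl$hydrogen, ] <- don + .unit(acc - don)
        }
      }
      frames[, , f] <- x
    }
  })
  topo <- methods::new("Structure", atoms = a, coords = frames[, , 1])
  traj <- methods::new("Trajectory", topology = topo, frames = frames)
  colnames(truth) <- if (length(plants)) pk else character(0)
  list(traj = traj, truth = as.data.frame(truth), torsion = tors,
       sel_a = complex$sel_a, sel_b = sel_b_all)
}

#' Write a structure or trajectory as a (multi-model) PDB file
#'
#' Trajectories are written as MODEL/ENDMDL blocks in frame order, the
#' dialect read back by [readTrajectory()].
#'
#' @param x a [Structure] or [Trajectory].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePDB <- function(x, path) {
  a <- atoms(x)
  xyz <- if (methods::is(x, "Trajectory")) {
    t(apply(x@frames, 3, function(m) as.vector(t(m))))
  } else {
    matrix(as.vector(t(coords(x))), nrow = 1)
  }
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(a)), eleno = a$serial,
                   elety = a$name, resid = a$resname, chain = a$chain,
                   resno = a$resseq, insert = a$icode,
                   o = a$occupancy, b = a$bfactor, elesy = a$element)
  invisible(path)
}
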
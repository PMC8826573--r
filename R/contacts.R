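## Interdomain contact detection. Four channels -- hydrogen bond, salt
## bridge, hydrophobic, van der Waals -- each a geometric predicate over
## typed atoms, evaluated per frame between two disjoint domain
## selections. Kind precedence on the same atom pair:
## saltbridge > hbond > hydrophobic > vdw (channels never double-count).

.contact_kinds <- c("saltbridge", "hbond", "hydrophobic", "vdw")

#' Construct contact criteria
#'
#' Defaults mirror the widely used GetContacts-style geometric criteria:
#' hydrogen bond donor-acceptor distance <= 3.5 A with D-H...A angle
#' >= 110 degrees, salt bridge cation-N to anion-O <= 4.0 A, hydrophobic
#' carbon pair <= 4.5 A, van der Waals within the radius sum + 0.5 A.
#' When `heavy_atom_fallback` is TRUE (appropriate for X-ray structures
#' without hydrogens) the hydrogen-bond angle test is skipped. The
#' fallback also engages automatically when a structure carries no
#' hydrogens at all.
#'
#' @param hbond_da_max,hbond_angle_min,saltbridge_max,hydrophobic_max,vdw_slack
#'   geometric thresholds, Angstrom / degrees.
#' @param heavy_atom_fallback logical.
#' @return a [ContactCriteria].
#' @export
contactCriteria <- function(hbond_da_max = 3.5, hbond_angle_min = 110,
                            saltbridge_max = 4.0, hydrophobic_max = 4.5,
                            vdw_slack = 0.5, heavy_atom_fallback = TRUE) {
  methods::new("ContactCriteria",
               hbond_da_max = hbond_da_max,
               hbond_angle_min = hbond_angle_min,
               saltbridge_max = saltbridge_max,
               hydrophobic_max = hydrophobic_max,
               vdw_slack = vdw_slack,
               heavy_atom_fallback = heavy_atom_fallback)
}

## precomputed detection context: role index sets relative to the two
## selections, vdW radii, hydrogen bookkeeping
.contact_context <- function(structure, roles, sel_a, sel_b, criteria) {
  if (length(intersect(sel_a, sel_b)))
    stop("domain selections a and b must be disjoint")
  a <- atoms(structure)
  ia <- sel_a[roles$heavy[sel_a]]
  ib <- sel_b[roles$heavy[sel_b]]
  sub <- function(idx, what) idx[roles[[what]][idx]]
  backbone <- a$name %in% c("N", "CA", "C", "O", "OXT")
  fallback <- criteria@heavy_atom_fallback || !any(roles$hydrogen)
  list(
    atoms = a,
    ia = ia, ib = ib,
    don_a = sub(ia, "donor"), acc_a = sub(ia, "acceptor"),
    don_b = sub(ib, "donor"), acc_b = sub(ib, "acceptor"),
    cat_a = sub(ia, "cation"), ani_a = sub(ia, "anion"),
    cat_b = sub(ib, "cation"), ani_b = sub(ib, "anion"),
    apo_a = sub(ia, "apolar"), apo_b = sub(ib, "apolar"),
    vdw = roles$vdw,
    backbone = backbone,
    fallback = fallback,
    criteria = criteria)
}

## all (i, j) index pairs from the given sets with distance <= cutoff
.pairs_within <- function(xyz, I, J, cutoff) {
  if (!length(I) || !length(J))
    return(cbind(i = integer(0), j = integer(0)))
  d2 <- .cross_dist2(xyz[I, , drop = FALSE], xyz[J, , drop = FALSE])
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  cbind(i = I[hit[, 1]], j = J[hit[, 2]])
}

## D-H...A angle test: TRUE if some hydrogen bonded to donor d makes an
## angle >= amin degrees with acceptor acc
.hbond_angle_ok <- function(xyz, hparent, d, acc, amin) {
  hs <- which(hparent == d)
  if (!length(hs)) return(FALSE)
  for (h in hs) {
    v1 <- xyz[d, ] - xyz[h, ]
    v2 <- xyz[acc, ] - xyz[h, ]
    if (.vec_angle(v1, v2) >= amin) return(TRUE)
  }
  FALSE
}

#' Detect interdomain contacts in a single frame
#'
#' Evaluates the four contact predicates between domains a and b on one
#' coordinate set. A hydrogen bond requires donor-acceptor distance
#' within the cutoff and, when hydrogens are present and the heavy-atom
#' fallback is off, a D-H...A angle above the minimum. A salt bridge is a
#' cation-N / anion-O pair within its cutoff; hydrophobic an apolar
#' carbon pair; van der Waals any heavy-atom pair within the radius sum
#' plus slack not already claimed by a more specific channel.
#'
#' @param structure a [Structure] or [Trajectory] (topology).
#' @param xyz N x 3 coordinates of the frame.
#' @param roles role table from [assignChemRoles()].
#' @param sel_a,sel_b disjoint atom index vectors.
#' @param criteria a [ContactCriteria].
#' @param frame frame index stored in the output (default 1).
#' @return data.frame with columns frame, kind, subtype, ia, ib, atom_a,
#'   atom_b, residue_a, residue_b; zero rows when no contacts exist.
#' @export
detectContactsFrame <- function(structure, xyz, roles, sel_a, sel_b,
                                criteria = contactCriteria(),
                                frame = 1L) {
  ctx <- .contact_context(structure, roles, sel_a, sel_b, criteria)
  .detect_frame(ctx, xyz, frame)
}

.detect_frame <- function(ctx, xyz, frame, hparent = NULL) {
  cr <- ctx$criteria
  ## salt bridges (both polarities)
  sb <- rbind(.pairs_within(xyz, ctx$cat_a, ctx$ani_b, cr@saltbridge_max),
              .pairs_within(xyz, ctx$ani_a, ctx$cat_b, cr@saltbridge_max))
  ## hydrogen bonds (donor on either side)
  hb <- rbind(.pairs_within(xyz, ctx$don_a, ctx$acc_b, cr@hbond_da_max),
              .pairs_within(xyz, ctx$acc_a, ctx$don_b, cr@hbond_da_max))
  if (nrow(hb) && !ctx$fallback) {
    if (is.null(hparent)) hparent <- .hydrogen_parents(xyz, .ctx_roles(ctx))
    donors_a <- hb[, 1] %in% ctx$don_a
    keep <- vapply(seq_len(nrow(hb)), function(r) {
      d <- if (donors_a[r]) hb[r, 1] else hb[r, 2]
      acc <- if (donors_a[r]) hb[r, 2] else hb[r, 1]
      .hbond_angle_ok(xyz, hparent, d, acc, cr@hbond_angle_min)
    }, TRUE)
    hb <- hb[keep, , drop = FALSE]
  }
  ## hydrophobic
  hp <- .pairs_within(xyz, ctx$apo_a, ctx$apo_b, cr@hydrophobic_max)
  ## van der Waals: radius-sum criterion over all heavy pairs
  vw <- cbind(i = integer(0), j = integer(0))
  if (length(ctx$ia) && length(ctx$ib)) {
    d2 <- .cross_dist2(xyz[ctx$ia, , drop = FALSE],
                       xyz[ctx$ib, , drop = FALSE])
    lim <- outer(ctx$vdw[ctx$ia], ctx$vdw[ctx$ib], "+") + cr@vdw_slack
    hit <- which(d2 <= lim^2, arr.ind = TRUE)
    vw <- cbind(i = ctx$ia[hit[, 1]], j = ctx$ib[hit[, 2]])
  }
  ## precedence dedup on atom pairs
  pk <- function(m) paste(m[, 1], m[, 2])
  sbk <- pk(sb); hbk <- pk(hb); hpk <- pk(hp)
  hb <- hb[!hbk %in% sbk, , drop = FALSE]
  vw <- vw[!pk(vw) %in% c(sbk, pk(hb), hpk), , drop = FALSE]
  out <- rbind(
    .pair_records(ctx, sb, "saltbridge", frame),
    .pair_records(ctx, hb, "hbond", frame),
    .pair_records(ctx, hp, "hydrophobic", frame),
    .pair_records(ctx, vw, "vdw", frame))
  if (!nrow(out)) return(out)
  out[order(match(out$kind, .contact_kinds), out$ia, out$ib), ,
      drop = FALSE]
}

## reconstruct a roles-like frame for hydrogen parent lookup
.ctx_roles <- function(ctx) {
  n <- nrow(ctx$atoms)
  heavy <- ctx$atoms$element != "H"
  data.frame(hydrogen = !heavy, heavy = heavy)
}

.pair_records <- function(ctx, pairs, kind, frame) {
  a <- ctx$atoms
  if (!nrow(pairs)) {
    return(data.frame(frame = integer(0), kind = character(0),
                      subtype = character(0), ia = integer(0),
                      ib = integer(0), atom_a = character(0),
                      atom_b = character(0), residue_a = character(0),
                      residue_b = character(0),
                      stringsAsFactors = FALSE))
  }
  i <- pairs[, 1]; j <- pairs[, 2]
  atom_id <- function(k) {
    sprintf("%s:%d:%s", a$chain[k], a$resseq[k], a$name[k])
  }
  res_id <- function(k) .res_key(a$chain[k], a$resseq[k], a$icode[k])
  subtype <- rep(NA_character_, length(i))
  if (kind == "hbond") {
    cls <- function(k) ifelse(ctx$backbone[k], "bb", "sc")
    subtype <- paste0(cls(i), "-", cls(j))
  }
  data.frame(frame = as.integer(frame), kind = kind, subtype = subtype,
             ia = as.integer(i), ib = as.integer(j),
             atom_a = atom_id(i), atom_b = atom_id(j),
             residue_a = res_id(i), residue_b = res_id(j),
             stringsAsFactors = FALSE)
}

#' Detect contacts over all frames of a trajectory
#'
#' Runs [detectContactsFrame()] on every frame and concatenates the
#' per-frame records, ordered by (frame, kind, atom indices). For
#' trajectories the heavy-atom fallback defaults to off when hydrogens
#' are present (MD frames carry hydrogens; X-ray inputs do not).
#'
#' @param traj a [Trajectory].
#' @param sel_a,sel_b disjoint atom index vectors for the two domains.
#' @param criteria a [ContactCriteria]; the default switches the
#'   heavy-atom fallback off, which matters only when hydrogens exist.
#' @param roles optional precomputed role table.
#' @return a contact record data.frame (see [detectContactsFrame()]),
#'   with attribute `frame_count`.
#' @export
trajectoryContacts <- function(traj, sel_a, sel_b,
                               criteria = contactCriteria(
                                 heavy_atom_fallback = FALSE),
                               roles = NULL) {
  if (is.null(roles)) roles <- assignChemRoles(traj)
  ctx <- .contact_context(traj, roles, sel_a, sel_b, criteria)
  nf <- nFrames(traj)
  use_h <- !ctx$fallback
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- traj@frames[, , f]
    hp <- if (use_h) .hydrogen_parents(xyz, roles) else NULL
    out[[f]] <- .detect_frame(ctx, xyz, f, hparent = hp)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "frame_count") <- nf
  tab
}

#' Occurrence ratio of a contact over a trajectory
#'
#' The fraction of frames in which a given residue pair (optionally
#' restricted to one interaction kind) is in contact through at least
#' one atom pair. Multiple atom pairs joining the same residues within a
#' frame count once.
#'
#' @param table contact records from [trajectoryContacts()].
#' @param residue_a,residue_b residue keys ("chain:resseq[:icode]").
#' @param kind optional kind filter.
#' @param frame_count total number of frames (defaults to the table's
#'   `frame_count` attribute).
#' @return a fraction in [0, 1].
#' @export
contactRatio <- function(table, residue_a, residue_b, kind = NULL,
                         frame_count = attr(table, "frame_count")) {
  if (is.null(frame_count) || frame_count < 1)
    stop("frame_count must be >= 1")
  hit <- table$residue_a == residue_a & table$residue_b == residue_b
  if (!is.null(kind)) hit <- hit & table$kind == kind
  length(unique(table$frame[hit])) / frame_count
}

#' Write a contact table as tab-separated text
#'
#' One row per contact: frame, kind, subtype and the two partners as
#' chain:resseq:atom identifiers.
#'
#' @param table contact records.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeContactTable <- function(table, path) {
  utils::write.table(
    table[, c("frame", "kind", "subtype", "atom_a", "atom_b",
              "residue_a", "residue_b")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
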
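## Structure, trajectory and charge I/O. PDB parsing itself is delegated
## to bio3d; this layer resolves altlocs, infers elements and masses,
## enforces the multi-model trajectory dialect and resolves domain
## selections. Author residue numbering is preserved throughout.

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, SE = 78.971)

## element from PDB columns 77-78 when present, else from the atom name
.infer_element <- function(name, elesy) {
  if (length(elesy) == 1) elesy <- rep(elesy, length(name))
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    nm <- toupper(gsub("[^A-Z]", "", name[miss]))
    guess <- substr(nm, 1, 1)
    # two-letter elements that occur in proteins
    guess[substr(nm, 1, 2) == "SE"] <- "SE"
    # digit-led hydrogen names like 1HB1 reduce to H via the gsub above
    el[miss] <- guess
  }
  el
}

.atoms_from_bio3d <- function(at) {
  element <- .infer_element(at$elety, at$elesy)
  data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resseq = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", at$insert),
    element = element,
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    bfactor = ifelse(is.na(at$b), 0, as.numeric(at$b)),
    charge = NA_real_,
    mass = unname(.element_masses[element]),
    record = at$type,
    stringsAsFactors = FALSE)
}

## keep, per (residue, atom name), the altloc with highest occupancy;
## ties broken by lexicographically first altloc id
.resolve_altloc <- function(atoms, xyz, policy = c("highest-occupancy", "all")) {
  policy <- match.arg(policy)
  if (policy == "all" || !any(atoms$altloc != "")) {
    return(list(atoms = atoms, xyz = xyz))
  }
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)
  list(atoms = atoms[keep, , drop = FALSE], xyz = xyz[keep, , drop = FALSE])
}

#' Read a PDB structure
#'
#' Parses an ATOM/HETATM PDB file into a [Structure]. Alternate locations
#' are resolved per `altloc_policy` (default: keep the highest-occupancy
#' altloc, ties broken by the lexicographically first id). Elements come
#' from PDB columns 77-78 when present, otherwise from the atom name. For
#' multi-model files only the first model is read, with a message; use
#' [readTrajectory()] for frame ensembles.
#'
#' @param path path to a PDB file.
#' @param altloc_policy "highest-occupancy" (default) or "all".
#' @param keep_hetatm keep HETATM records (default FALSE: waters and
#'   ligands are stripped, as interface analysis concerns protein atoms).
#' @return a [Structure].
#' @export
readPDB <- function(path, altloc_policy = "highest-occupancy",
                    keep_hetatm = FALSE) {
  .check_pdb_file(path)
  lines <- readLines(path, warn = FALSE)
  if (sum(grepl("^MODEL ", lines)) > 1)
    message("multi-model file: reading first model only (see readTrajectory)")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  atoms <- .atoms_from_bio3d(pdb$atom)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  if (!keep_hetatm) {
    keep <- atoms$record == "ATOM"
    atoms <- atoms[keep, , drop = FALSE]
    xyz <- xyz[keep, , drop = FALSE]
  }
  if (!nrow(atoms)) stop("no ATOM records retained from ", path)
  r <- .resolve_altloc(atoms, xyz, altloc_policy)
  r$atoms$record <- NULL
  rownames(r$atoms) <- NULL
  dimnames(r$xyz) <- NULL
  methods::new("Structure", atoms = r$atoms, coords = r$xyz)
}

## sanity scan with line-numbered diagnostics for malformed records
.check_pdb_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad))
    stop(sprintf("malformed fixed-width record at line %d of %s (too short)",
                 bad[1], path))
  num <- lines[rec]
  xs <- suppressWarnings(as.numeric(substr(num, 31, 38)))
  if (anyNA(xs))
    stop(sprintf("malformed coordinate field at line %d of %s",
                 which(rec)[which(is.na(xs))[1]], path))
  invisible(TRUE)
}

#' Read a multi-model PDB as a trajectory
#'
#' Interprets MODEL/ENDMDL blocks as trajectory frames, ordered by MODEL
#' number. The topology (atom records) comes from model 1; every model
#' must contain the same number of atoms.
#'
#' @param path path to a (possibly multi-model) PDB file.
#' @param keep_hetatm keep HETATM records (default FALSE).
#' @return a [Trajectory].
#' @export
readTrajectory <- function(path, keep_hetatm = FALSE) {
  .check_pdb_file(path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL ", lines)
  if (length(starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts))
      stop("unterminated MODEL block in ", path)
    counts <- mapply(function(s, e)
      sum(grepl("^(ATOM  |HETATM)", lines[s:e])), starts, ends)
    if (length(unique(counts)) > 1) {
      off <- which(counts != counts[1])[1]
      stop(sprintf(
        "atom-count mismatch: model %d has %d atoms, model 1 has %d",
        off, counts[off], counts[1]))
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                          rm.alt = FALSE, verbose = FALSE))
  atoms <- .atoms_from_bio3d(pdb$atom)
  nf <- nrow(pdb$xyz)
  n <- nrow(atoms)
  keep <- if (keep_hetatm) rep(TRUE, n) else atoms$record == "ATOM"
  if (any(atoms$altloc != ""))
    stop("altloc records are not supported in trajectory frames")
  frames <- array(NA_real_, dim = c(sum(keep), 3, nf))
  for (f in seq_len(nf)) {
    xyz <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    frames[, , f] <- xyz[keep, , drop = FALSE]
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$record <- NULL
  rownames(atoms) <- NULL
  topo <- methods::new("Structure", atoms = atoms,
                       coords = matrix(frames[, , 1], ncol = 3))
  methods::new("Trajectory", topology = topo, frames = frames)
}

#' Read a PQR file and attach charges to a structure
#'
#' PQR records carry per-atom partial charges (e) and radii (Angstrom) in
#' whitespace-delimited columns. Atoms are matched to the structure by
#' (chain, resseq, atom name); unmatched PQR atoms are ignored with a
#' warning reporting the count.
#'
#' @param path path to a PQR file.
#' @param structure optional [Structure]; when given, a copy with the
#'   charge (and mass-alongside radius attribute) filled in is returned.
#' @return if `structure` is NULL, a data.frame (chain, resseq, icode,
#'   name, charge, radius); otherwise the structure with charges attached.
#' @export
readPQR <- function(path, structure = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(lines)) stop("no ATOM records in PQR ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nt <- lengths(toks)
  ## standard PQR: record serial name resname [chain] resseq x y z q r
  has_chain <- nt >= 11
  get <- function(tk, i) tk[i]
  tab <- data.frame(
    name = vapply(toks, get, "", 3),
    resname = vapply(toks, get, "", 4),
    chain = ifelse(has_chain, vapply(toks, get, "", 5), " "),
    resseq = suppressWarnings(as.integer(ifelse(
      has_chain, vapply(toks, get, "", 6), vapply(toks, get, "", 5)))),
    charge = suppressWarnings(as.numeric(ifelse(
      has_chain, vapply(toks, get, "", 10), vapply(toks, get, "", 9)))),
    radius = suppressWarnings(as.numeric(ifelse(
      has_chain, vapply(toks, get, "", 11), vapply(toks, get, "", 10)))),
    stringsAsFactors = FALSE)
  if (anyNA(tab$charge)) {
    bad <- which(is.na(tab$charge))[1]
    stop(sprintf("non-numeric charge in PQR record %d of %s", bad, path))
  }
  tab$icode <- ""
  tab <- tab[, c("chain", "resseq", "icode", "name", "resname",
                 "charge", "radius")]
  if (is.null(structure)) return(tab)
  a <- atoms(structure)
  skey <- paste(a$chain, a$resseq, a$name)
  qkey <- paste(tab$chain, tab$resseq, tab$name)
  m <- match(skey, qkey)
  extra <- sum(!qkey %in% skey)
  if (extra > 0)
    warning(sprintf("%d PQR atoms not present in structure; ignored", extra))
  a$charge <- tab$charge[m]
  structure@atoms <- a
  structure
}

#' Construct a domain selection
#'
#' @param label "a" or "b".
#' @param ... one or more members, each either "CHAIN:FROM-TO" strings or
#'   lists with fields chain, from, to.
#' @return a [DomainSelection].
#' @examples
#' domainSelection("a", "A:341-447")
#' @export
domainSelection <- function(label, ...) {
  raw <- list(...)
  members <- lapply(raw, function(m) {
    if (is.character(m)) {
      mm <- regmatches(m, regexec("^(.+?):(-?[0-9]+)-(-?[0-9]+)$", m))[[1]]
      if (length(mm) != 4) stop("cannot parse range spec: ", m)
      list(chain = mm[2], from = as.integer(mm[3]), to = as.integer(mm[4]))
    } else m
  })
  methods::new("DomainSelection", label = label, members = members)
}

#' Resolve a domain selection to atom indices
#'
#' Returns the indices of all ATOM-record atoms falling in the listed
#' (chain, residue-range) members, preserving input atom order. Every
#' member range must select at least one existing residue.
#'
#' @param structure a [Structure] or [Trajectory].
#' @param sel a [DomainSelection].
#' @return integer vector of atom indices.
#' @export
selectDomain <- function(structure, sel) {
  a <- atoms(structure)
  keep <- rep(FALSE, nrow(a))
  for (m in sel@members) {
    hit <- a$chain == m$chain & a$resseq >= m$from & a$resseq <= m$to
    if (!any(hit))
      stop(sprintf("no residues found for %s:%d-%d", m$chain, m$from, m$to))
    ## every requested residue number present in the structure's chain span?
    present <- unique(a$resseq[a$chain == m$chain])
    missing <- setdiff(seq(m$from, m$to), present)
    if (length(missing))
      stop(sprintf("missing residue (%s, %d) in selection", m$chain,
                   missing[1]))
    keep <- keep | hit
  }
  which(keep)
}

#' Write a PDB with per-residue scores in the B-factor column
#'
#' Produces a copy of the structure with the B-factor of every atom set
#' to the score of its residue (0.00 for unscored residues), for use with
#' molecular viewers that color by B-factor, e.g. the open-book interface
#' rendering where each residue is shaded by its duration-weighted
#' interdomain contact count.
#'
#' @param structure a [Structure].
#' @param scores named numeric vector; names are residue keys
#'   ("chain:resseq[:icode]") as produced by [residueKeys()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeBfactorPDB <- function(structure, scores, path) {
  a <- atoms(structure)
  keys <- residueKeys(structure)
  if (length(scores)) {
    unknown <- setdiff(names(scores), unique(keys))
    if (length(unknown))
      stop("scores refer to residues absent from structure: ",
           paste(utils::head(unknown, 3), collapse = ", "))
  }
  b <- unname(scores[keys])
  b[is.na(b)] <- 0
  clip <- b > 999.99 | b < -99.99
  if (any(clip)) {
    warning(sum(clip), " scores not representable in %6.2f; clipped")
    b <- pmax(-99.99, pmin(999.99, b))
  }
  xyz <- coords(structure)
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)),
                   type = rep("ATOM", nrow(a)), eleno = a$serial,
                   elety = a$name, resid = a$resname, chain = a$chain,
                   resno = a$resseq, insert = a$icode,
                   o = a$occupancy, b = b, elesy = a$element)
  invisible(path)
}
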
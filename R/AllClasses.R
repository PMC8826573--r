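#' @import methods
NULL

#' Structure: a molecular structure with one coordinate set
#'
#' Container for a parsed PDB structure. Atoms are stored as a data.frame
#' with one row per atom (serial, name, altloc, resname, chain, resseq,
#' icode, element, occupancy, bfactor, charge, mass) and coordinates as an
#' N x 3 matrix in Angstrom. Author residue numbering is preserved
#' end-to-end; no renumbering is ever applied.
#'
#' @slot atoms data.frame of per-atom records.
#' @slot coords numeric N x 3 matrix, Angstrom.
#'
#' @exportClass Structure
setClass("Structure",
  representation(atoms = "data.frame", coords = "matrix"))

setValidity("Structure", function(object) {
  a <- object@atoms
  msg <- character()
  need <- c("serial", "name", "resname", "chain", "resseq", "icode",
            "element", "occupancy", "bfactor", "charge", "mass")
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("atoms lacks columns:",
                        paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) != nrow(object@coords) || ncol(object@coords) != 3)
    msg <- c(msg, "coords must be an N x 3 matrix matching atoms")
  if (nrow(object@coords) && !all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Trajectory: a frame ensemble over a fixed topology
#'
#' Frames of a multi-model PDB (the stand-in for an MD trajectory) over a
#' fixed atom topology. Coordinates are stored as an N x 3 x F array.
#'
#' @slot topology a [Structure] giving the atom records (frame 1 coords).
#' @slot frames numeric N x 3 x F array, Angstrom.
#'
#' @exportClass Trajectory
setClass("Trajectory",
  representation(topology = "Structure", frames = "array"))

setValidity("Trajectory", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3 || d[2] != 3)
    return("frames must be an N x 3 x F array")
  if (d[1] != nrow(object@topology@atoms))
    return("frame atom count differs from topology")
  if (d[3] < 1) return("at least one frame required")
  TRUE
})

#' DomainSelection: one domain of a paired-domain interface
#'
#' Names one of the two interacting domains ("a" or "b") as a set of
#' (chain, residue-range) members. The "a"/"b" convention mirrors common
#' usage for constant-domain dimers: the CL domain and one CH3 copy are
#' "a", the CH1 domain and the other CH3 copy are "b".
#'
#' @slot label "a" or "b".
#' @slot members list of lists with fields chain, from, to (author numbers).
#'
#' @exportClass DomainSelection
setClass("DomainSelection",
  representation(label = "character", members = "list"))

setValidity("DomainSelection", function(object) {
  if (!object@label %in% c("a", "b")) return("label must be 'a' or 'b'")
  if (!length(object@members)) return("selection must not be empty")
  for (m in object@members) {
    if (!all(c("chain", "from", "to") %in% names(m)))
      return("each member needs chain, from, to")
    if (m$from > m$to) return("member range is empty (from > to)")
  }
  # ranges within one chain must not overlap
  byc <- split(object@members, vapply(object@members, `[[`, "", "chain"))
  for (ms in byc) {
    if (length(ms) < 2) next
    iv <- do.call(rbind, lapply(ms, function(m) c(m$from, m$to)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      return("overlapping residue ranges within one chain")
  }
  TRUE
})

#' ElementMap: residue-to-element labels for one domain
#'
#' Maps each residue of a domain to a coarse-graining unit of the Ig fold:
#' beta-strands A..G (single letters) and connecting loops named by their
#' flanking strands (AB, BC, ..., FG), plus Nterm/Cterm for tails.
#'
#' @slot domain "a" or "b".
#' @slot labels named character vector; names are residue keys
#'   ("chain:resseq[:icode]"), values element labels.
#'
#' @exportClass ElementMap
setClass("ElementMap",
  representation(domain = "character", labels = "character"))

.element_label_set <- c("A", "B", "C", "D", "E", "F", "G",
                        "AB", "BC", "CD", "DE", "EF", "FG",
                        "Nterm", "Cterm")

setValidity("ElementMap", function(object) {
  if (!object@domain %in% c("a", "b")) return("domain must be 'a' or 'b'")
  bad <- setdiff(unique(object@labels), .element_label_set)
  if (length(bad))
    return(paste("unknown element labels:", paste(bad, collapse = ", ")))
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    return("labels must be uniquely named by residue key")
  TRUE
})

#' ContactCriteria: geometric thresholds for contact detection
#'
#' Distance/angle cutoffs for the four interaction channels. Defaults
#' mirror the commonly used GetContacts-style criteria; all values are
#' configuration, not constants.
#'
#' @slot hbond_da_max donor-acceptor heavy-atom cutoff, Angstrom.
#' @slot hbond_angle_min minimum D-H...A angle, degrees.
#' @slot saltbridge_max cation-N to anion-O cutoff, Angstrom.
#' @slot hydrophobic_max apolar carbon pair cutoff, Angstrom.
#' @slot vdw_slack added to the sum of vdW radii, Angstrom.
#' @slot heavy_atom_fallback if TRUE, hydrogen bonds use the distance
#'   criterion only (for X-ray inputs that lack hydrogens).
#'
#' @exportClass ContactCriteria
setClass("ContactCriteria",
  representation(hbond_da_max = "numeric", hbond_angle_min = "numeric",
                 saltbridge_max = "numeric", hydrophobic_max = "numeric",
                 vdw_slack = "numeric", heavy_atom_fallback = "logical"))

setValidity("ContactCriteria", function(object) {
  d <- c(object@hbond_da_max, object@saltbridge_max,
         object@hydrophobic_max, object@vdw_slack)
  if (any(!is.finite(d)) || any(d[1:3] <= 0) || object@vdw_slack < 0)
    return("distance thresholds must be positive and finite")
  if (object@hbond_angle_min < 0 || object@hbond_angle_min > 180)
    return("hbond_angle_min must lie in [0, 180]")
  TRUE
})

#' ContactFrequencyTable: element-pair occurrence ratios for one system
#'
#' For one system and one interaction kind, the fraction of frames in
#' which at least one contact of that kind joins an a-domain element to a
#' b-domain element.
#'
#' @slot system system identifier.
#' @slot kind one of "hbond", "saltbridge", "hydrophobic", "vdw".
#' @slot ratios numeric matrix, rows = a elements, cols = b elements,
#'   entries in [0, 1].
#'
#' @exportClass ContactFrequencyTable
setClass("ContactFrequencyTable",
  representation(system = "character", kind = "character",
                 ratios = "matrix"))

setValidity("ContactFrequencyTable", function(object) {
  r <- object@ratios
  if (any(r < -1e-12 | r > 1 + 1e-12)) return("ratios must lie in [0, 1]")
  if (is.null(rownames(r)) || is.null(colnames(r)))
    return("ratio matrix must carry element dimnames")
  if (!object@kind %in% c("hbond", "saltbridge", "hydrophobic", "vdw"))
    return("unknown contact kind")
  TRUE
})

#' ClassSummary: per element-pair mean ratio and SEM over an interface class
#'
#' @slot class_id class identifier (e.g. "CH3-CH3", "CH1-CL").
#' @slot kind interaction kind shared by the member systems.
#' @slot mean numeric matrix of mean occurrence ratios.
#' @slot sem numeric matrix of standard errors of the mean (n-1 sd / sqrt(n)).
#' @slot n_systems number of member systems.
#'
#' @exportClass ClassSummary
setClass("ClassSummary",
  representation(class_id = "character", kind = "character",
                 mean = "matrix", sem = "matrix", n_systems = "integer"))

setValidity("ClassSummary", function(object) {
  if (!identical(dim(object@mean), dim(object@sem)))
    return("mean and sem matrices must agree in shape")
  if (any(object@sem < -1e-12)) return("SEM must be nonnegative")
  if (any(object@mean < -1e-12 | object@mean > 1 + 1e-12))
    return("means must lie in [0, 1]")
  if (object@n_systems < 1L) return("n_systems must be >= 1")
  TRUE
})

#' DifferenceMap: normalized signed difference between two class summaries
#'
#' Entries are (mean1 - mean2) / max(mean over both classes), hence lie in
#' [-1, 1] and are antisymmetric under swapping the classes. The colorbar
#' of the corresponding figure is normalized to the most frequent contact
#' in either class.
#'
#' @slot kind interaction kind.
#' @slot delta numeric matrix of normalized signed differences.
#' @slot normalizer the maximum mean ratio over both classes.
#' @slot classes the two class identifiers, in order (class1 - class2).
#'
#' @exportClass DifferenceMap
setClass("DifferenceMap",
  representation(kind = "character", delta = "matrix",
                 normalizer = "numeric", classes = "character"))

setValidity("DifferenceMap", function(object) {
  if (object@normalizer <= 0) return("normalizer must be positive")
  if (any(abs(object@delta) > 1 + 1e-9))
    return("difference entries must lie in [-1, 1]")
  TRUE
})

#' OrientationReference: reference frames for the six orientation measures
#'
#' Holds the per-domain reference coordinates after alignment to the world
#' frame (principal inertia axis on +z, the interdomain center axis pulled
#' as close as possible to +x), the alignment atom indices, and weights.
#'
#' @slot ref_a,ref_b numeric matrices of aligned reference coordinates.
#' @slot fit_a,fit_b integer indices (into ref rows) of Kabsch alignment
#'   atoms (Calpha).
#' @slot idx_a,idx_b integer atom indices of the two domains in the source
#'   structure.
#' @slot w_a,w_b numeric mass weights used for centers and inertia.
#' @slot axes 3 x 3 identity basis (x, y, z world unit vectors), kept
#'   explicit for clarity of the measure definitions.
#'
#' @exportClass OrientationReference
setClass("OrientationReference",
  representation(ref_a = "matrix", ref_b = "matrix",
                 fit_a = "integer", fit_b = "integer",
                 idx_a = "integer", idx_b = "integer",
                 w_a = "numeric", w_b = "numeric",
                 axes = "matrix"))

#' EnergySeries: per-frame interdomain electrostatic energies
#'
#' @slot energy numeric vector, kcal/mol, one value per frame.
#' @slot mean arithmetic mean of the series.
#' @slot sd sample standard deviation (n-1), 0 for a single frame.
#' @slot cutoff,dielectric the settings used.
#'
#' @exportClass EnergySeries
setClass("EnergySeries",
  representation(energy = "numeric", mean = "numeric", sd = "numeric",
                 cutoff = "numeric", dielectric = "numeric"))

setValidity("EnergySeries", function(object) {
  if (length(object@energy) &&
      abs(object@mean - mean(object@energy)) > 1e-8 * max(1, abs(object@mean)))
    return("mean slot inconsistent with energy series")
  TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  nres <- length(unique(residueKeys(object)))
  cat(sprintf("Structure: %d atoms, %d residues, chains %s\n",
              nrow(a), nres, paste(unique(a$chain), collapse = " ")))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Trajectory: %d frames x %d atoms\n", d[3], d[1]))
})

setMethod("show", "DomainSelection", function(object) {
  rng <- vapply(object@members, function(m)
    sprintf("%s:%d-%d", m$chain, m$from, m$to), "")
  cat(sprintf("DomainSelection '%s': %s\n", object@label,
              paste(rng, collapse = ", ")))
})

setMethod("show", "ElementMap", function(object) {
  tab <- table(factor(object@labels, levels = .element_label_set))
  tab <- tab[tab > 0]
  cat(sprintf("ElementMap (domain %s): %d residues; %s\n", object@domain,
              length(object@labels),
              paste(sprintf("%s:%d", names(tab), tab), collapse = " ")))
})

setMethod("show", "ContactFrequencyTable", function(object) {
  nz <- sum(object@ratios > 0)
  cat(sprintf("ContactFrequencyTable [%s, %s]: %d x %d elements, %d nonzero\n",
              object@system, object@kind, nrow(object@ratios),
              ncol(object@ratios), nz))
})

setMethod("show", "ClassSummary", function(object) {
  cat(sprintf("ClassSummary [%s, %s]: n = %d systems, max mean ratio %.3f\n",
              object@class_id, object@kind, object@n_systems,
              if (length(object@mean)) max(object@mean) else NA_real_))
})

setMethod("show", "DifferenceMap", function(object) {
  cat(sprintf("DifferenceMap [%s]: %s - %s, normalizer %.3f\n",
              object@kind, object@classes[1], object@classes[2],
              object@normalizer))
})

setMethod("show", "EnergySeries", function(object) {
  cat(sprintf("EnergySeries: %d frames, mean %.2f +/- %.2f kcal/mol\n",
              length(object@energy), object@mean, object@sd))
})

setMethod("show", "ContactCriteria", function(object) {
  cat(sprintf(paste0("ContactCriteria: hbond <= %.2f A (angle >= %.0f deg),",
                     " saltbridge <= %.2f A, hydrophobic <= %.2f A,",
                     " vdw slack %.2f A, heavy-atom fallback %s\n"),
              object@hbond_da_max, object@hbond_angle_min,
              object@saltbridge_max, object@hydrophobic_max,
              object@vdw_slack, object@heavy_atom_fallback))
})

setMethod("show", "OrientationReference", function(object) {
  cat(sprintf("OrientationReference: %d + %d atoms (fit on %d + %d Calpha)\n",
              nrow(object@ref_a), nrow(object@ref_b),
              length(object@fit_a), length(object@fit_b)))
})
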
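#' Accessors for structure and trajectory objects
#'
#' `atoms()` returns the per-atom data.frame; `coords()` the N x 3
#' coordinate matrix (for a trajectory, of a given frame); `nFrames()` the
#' frame count; `residueKeys()` the per-atom residue keys
#' ("chain:resseq[:icode]").
#'
#' @param x a [Structure] or [Trajectory].
#' @param frame frame index (trajectories only).
#' @return see individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, frame = 1L) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' @rdname accessors
setMethod("atoms", "Structure", function(x) x@atoms)

#' @rdname accessors
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' @rdname accessors
setMethod("coords", "Structure", function(x, frame = 1L) x@coords)

#' @rdname accessors
setMethod("coords", "Trajectory", function(x, frame = 1L) {
  matrix(x@frames[, , frame], ncol = 3)
})

#' @rdname accessors
setMethod("nFrames", "Structure", function(x) 1L)

#' @rdname accessors
setMethod("nFrames", "Trajectory", function(x) dim(x@frames)[3])

#' @rdname accessors
setMethod("residueKeys", "Structure", function(x) {
  a <- x@atoms
  .res_key(a$chain, a$resseq, a$icode)
})

#' @rdname accessors
setMethod("residueKeys", "Trajectory", function(x) residueKeys(x@topology))

## residue key helper: "chain:resseq" or "chain:resseq:icode"
.res_key <- function(chain, resseq, icode) {
  ic <- ifelse(is.na(icode) | icode == "", "", paste0(":", icode))
  paste0(chain, ":", resseq, ic)
}
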
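#' @include AllClasses.R
NULL

#' Accessors for structure and pair objects
#'
#' Small accessor layer over the S4 containers: slot access stays internal.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return The corresponding component: a data.frame of atom records, a list
#'   of \linkS4class{LigandInstance} objects, etc.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x, ...) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("pdbID", function(x) standardGeneric("pdbID"))

#' @rdname accessors
#' @export
setGeneric("crystalResolution", function(x) standardGeneric("crystalResolution"))

#' @rdname accessors
#' @export
setGeneric("ligandInstances", function(x, ...) standardGeneric("ligandInstances"))

#' @rdname accessors
#' @export
setGeneric("hetCode", function(x) standardGeneric("hetCode"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setGeneric("reasonCodes", function(x) standardGeneric("reasonCodes"))

#' @rdname accessors
#' @export
setGeneric("bindingSite", function(x) standardGeneric("bindingSite"))

#' @rdname accessors
#' @export
setGeneric("residueCorrespondence", function(x) standardGeneric("residueCorrespondence"))

#' @rdname accessors
#' @export
setGeneric("pairMetrics", function(x) standardGeneric("pairMetrics"))

setMethod("atomTable", "StructureModel", function(x, ...) x@atoms)
setMethod("atomTable", "LigandInstance", function(x, ...) x@atoms)
setMethod("pdbID", "StructureModel", function(x) x@pdbID)
setMethod("crystalResolution", "StructureModel", function(x) x@resolution)
setMethod("hetCode", "LigandInstance", function(x) x@hetCode)
setMethod("verdict", "ApoHoloPair", function(x) x@verdict)
setMethod("reasonCodes", "ApoHoloPair", function(x) x@reasons)
setMethod("bindingSite", "ApoHoloPair", function(x) x@site)
setMethod("residueCorrespondence", "ApoHoloPair", function(x) x@correspondence)
setMethod("pairMetrics", "ApoHoloPair", function(x) x@metrics)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel", object@pdbID,
      if (!is.na(object@resolution))
        sprintf("(%.2f A)", object@resolution) else "(resolution unknown)",
      "\n")
  cat(sprintf("  %d protein atoms in %d residues; %d ligand atoms; %d waters\n",
              sum(a$category == "protein"),
              length(unique(resKey(a[a$category == "protein", ]))),
              sum(a$category == "ligand"),
              sum(a$category == "water")))
})

setMethod("show", "ApoHoloPair", function(object) {
  cat("ApoHoloPair", object@pairID, "-", object@verdict, "\n")
  cat("  ligand:", object@ligand@hetCode,
      " site residues:", length(object@site), "\n")
  if (length(object@reasons))
    cat("  reasons:", paste(object@reasons, collapse = ", "), "\n")
})

setMethod("show", "WallScore", function(object) {
  cat(sprintf("WallScore: total %.3f over %d residues (%d clashing pairs)\n",
              object@total, length(object@perResidue), nrow(object@clashes)))
})
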
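#' @include AllClasses.R
NULL

#' @rdname ProteinGroupSet-class
#' @param x,object a `ProteinGroupSet`, `PeptideMap` or `ModuleSet`.
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @rdname ProteinGroupSet-class
#' @export
setGeneric("seedAccessions", function(x) standardGeneric("seedAccessions"))

#' @rdname ProteinGroupSet-class
#' @export
setGeneric("groupMembers", function(x) standardGeneric("groupMembers"))

#' @rdname ProteinGroupSet-class
#' @export
setGeneric("database", function(x) standardGeneric("database"))

#' @rdname PeptideMap-class
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname PeptideMap-class
#' @export
setGeneric("peptideGroups", function(x) standardGeneric("peptideGroups"))

#' @rdname PeptideMap-class
#' @export
setGeneric("isUnique", function(x) standardGeneric("isUnique"))

#' @rdname PeptideMap-class
#' @export
setGeneric("unmappedPeptides", function(x) standardGeneric("unmappedPeptides"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleIds", function(x) standardGeneric("moduleIds"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleNames", function(x) standardGeneric("moduleNames"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleSteps", function(x) standardGeneric("moduleSteps"))


## ---- ProteinGroupSet methods -------------------------------------------

#' @rdname ProteinGroupSet-class
#' @export
setMethod("groupIds", "ProteinGroupSet", function(x) x@groupId)

#' @rdname ProteinGroupSet-class
#' @export
setMethod("seedAccessions", "ProteinGroupSet", function(x) x@seedAccession)

#' @rdname ProteinGroupSet-class
#' @export
setMethod("groupMembers", "ProteinGroupSet", function(x) {
    out <- x@members
    names(out) <- x@groupId
    out
})

#' @rdname ProteinGroupSet-class
#' @export
setMethod("database", "ProteinGroupSet", function(x) x@database)

#' @rdname ProteinGroupSet-class
#' @export
setMethod("length", "ProteinGroupSet", function(x) length(x@groupId))

setMethod("show", "ProteinGroupSet", function(object) {
    cat("ProteinGroupSet with", length(object), "groups over",
        length(object@database), "sequences\n")
    cat("  identity threshold:", object@threshold, "\n")
    sz <- lengths(object@members)
    if (length(sz))
        cat("  group sizes: min", min(sz), "/ median", stats::median(sz),
            "/ max", max(sz), "\n")
})

## ---- PeptideMap methods ------------------------------------------------

#' @rdname PeptideMap-class
#' @export
setMethod("peptides", "PeptideMap", function(x) x@peptide)

#' @rdname PeptideMap-class
#' @export
setMethod("peptideGroups", "PeptideMap", function(x) {
    out <- x@groups
    names(out) <- x@peptide
    out
})

#' @rdname PeptideMap-class
#' @export
setMethod("isUnique", "PeptideMap", function(x) {
    out <- lengths(x@groups) == 1L
    names(out) <- x@peptide
    out
})

#' @rdname PeptideMap-class
#' @export
setMethod("unmappedPeptides", "PeptideMap", function(x) x@unmapped)

#' @rdname PeptideMap-class
#' @export
setMethod("length", "PeptideMap", function(x) length(x@peptide))

setMethod("show", "PeptideMap", function(object) {
    nu <- sum(lengths(object@groups) == 1L)
    cat("PeptideMap:", length(object), "mapped peptides (",
        nu, "unique /", length(object) - nu, "shared ),",
        length(object@unmapped), "unmapped\n")
})

## ---- ModuleSet methods -------------------------------------------------

#' @rdname ModuleSet-class
#' @export
setMethod("moduleIds", "ModuleSet", function(x) x@moduleId)

#' @rdname ModuleSet-class
#' @export
setMethod("moduleNames", "ModuleSet", function(x) {
    out <- x@moduleName
    names(out) <- x@moduleId
    out
})

#' @rdname ModuleSet-class
#' @export
setMethod("moduleSteps", "ModuleSet", function(x) {
    out <- x@steps
    names(out) <- x@moduleId
    out
})

#' @rdname ModuleSet-class
#' @export
setMethod("length", "ModuleSet", function(x) length(x@moduleId))

#' @rdname ModuleSet-class
#' @param i index or module id.
#' @export
setMethod("[[", "ModuleSet", function(x, i) {
    if (is.character(i)) i <- match(i, x@moduleId)
    list(module_id = x@moduleId[i], name = x@moduleName[i],
         steps = x@steps[[i]])
})

setMethod("show", "ModuleSet", function(object) {
    cat("ModuleSet with", length(object), "modules\n")
    if (length(object)) {
        ns <- vapply(object@steps, length, integer(1))
        cat("  steps per module: min", min(ns), "/ max", max(ns), "\n")
    }
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:\n")
    cat(sprintf("  %d individuals x %d time points, depth %d spectra\n",
                object@nIndividuals, object@nTimepoints, object@depth))
    cat(sprintf("  ~%d proteins/individual, %d KO terms, %d phyla\n",
                object@proteinsPerIndividual, object@nKoTerms,
                length(object@phyla)))
    cat(sprintf("  redundancy %.2f, turnover %.2f, KO preservation %.2f\n",
                object@koPhylumRedundancy, object@turnover,
                object@koPreservation))
    cat(sprintf("  individual effect %.2f, human fraction %.2f, seed %d\n",
                object@individualEffect, object@humanFraction,
                object@rngSeed))
})
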
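#' @include AllClasses.R
NULL

#' Accessors for ConformR objects
#'
#' Small accessor generics used across the package: alignment dimensions and
#' content, ensemble dimensions, frame extraction, and pLDDT matrices.
#'
#' @param x an object.
#' @param i frame index or id (for \code{getFrame}).
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @rdname accessors
#' @export
setGeneric("targetId", function(x) standardGeneric("targetId"))

#' @rdname accessors
#' @export
setGeneric("msaIds", function(x) standardGeneric("msaIds"))

#' @rdname accessors
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))

#' @rdname accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("frameIds", function(x) standardGeneric("frameIds"))

#' @rdname accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))

#' @rdname accessors
#' @export
setGeneric("caCoords", function(x, ...) standardGeneric("caCoords"))

#' @rdname accessors
#' @export
setGeneric("plddt", function(x) standardGeneric("plddt"))

#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname accessors
#' @export
setGeneric("centersMSA", function(x) standardGeneric("centersMSA"))

#' @rdname accessors
#' @export
setGeneric("extrasMSA", function(x) standardGeneric("extrasMSA"))

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

## ---- accessor methods -----------------------------------------------------

#' @rdname accessors
setMethod("nColumns", "MSA", function(x) nchar(x@rows[[1L]]))

#' @rdname accessors
setMethod("targetId", "MSA", function(x) x@targetId)

#' @rdname accessors
setMethod("msaIds", "MSA", function(x) x@ids)

#' @rdname accessors
setMethod("msaRows", "MSA", function(x) x@rows)

#' @rdname accessors
setMethod("nSequences", "MSA", function(x) length(x@rows))

#' @rdname accessors
setMethod("nFrames", "Ensemble", function(x) dim(x@coords)[3L])

#' @rdname accessors
setMethod("nResidues", "Ensemble", function(x) dim(x@coords)[1L])

#' @rdname accessors
setMethod("nResidues", "StructureFrame", function(x) nrow(x@coords))

#' @rdname accessors
setMethod("frameIds", "Ensemble", function(x) x@frameIds)

#' @rdname accessors
setMethod("residueNumbers", "Ensemble", function(x) x@residueNumbers)

#' @rdname accessors
setMethod("residueNumbers", "StructureFrame", function(x) x@residueNumbers)

#' @rdname accessors
setMethod("residueNumbers", "FlexProfile", function(x) x@residueNumbers)

#' @rdname accessors
#' @param ... for \code{caCoords,Ensemble}: \code{frame}, a frame index.
setMethod("caCoords", "StructureFrame", function(x, ...) x@coords)

#' @rdname accessors
setMethod("caCoords", "Ensemble", function(x, frame = NULL) {
    if (is.null(frame)) x@coords else x@coords[, , frame, drop = TRUE]
})

#' @rdname accessors
setMethod("plddt", "StructureFrame", function(x) x@plddt)

#' @rdname accessors
setMethod("plddt", "Ensemble", function(x) x@plddt)

#' @rdname accessors
setMethod("getFrame", "Ensemble", function(x, i) {
    if (is.character(i)) i <- match(i, x@frameIds)
    stopifnot(!is.na(i), i >= 1L, i <= nFrames(x))
    new("StructureFrame", frameId = x@frameIds[[i]],
        coords = x@coords[, , i, drop = TRUE],
        residueNumbers = x@residueNumbers,
        residueNames = x@residueNames,
        plddt = x@plddt[, i])
})

#' @rdname accessors
setMethod("centersMSA", "SubsampledMSA", function(x) x@centers)

#' @rdname accessors
setMethod("extrasMSA", "SubsampledMSA", function(x) {
    if (length(x@extras)) x@extras[[1L]] else NULL
})

#' @rdname accessors
setMethod("populations", "StateModel", function(x) x@populations)

#' @rdname accessors
setMethod("stateLabels", "StateModel", function(x) x@labels)

#' @rdname accessors
setMethod("centroids", "StateModel", function(x) x@centroids)

## ---- show methods ---------------------------------------------------------

setMethod("show", "MSA", function(object) {
    cat(sprintf("MSA: %d sequences x %d columns (target '%s')\n",
                nSequences(object), nColumns(object), targetId(object)))
})

setMethod("show", "SubsampleParams", function(object) {
    cat(sprintf("SubsampleParams: max_seq=%d, extra_seq=%d, %d seed(s)\n",
                object@maxSeq, object@extraSeq, length(object@seeds)))
})

setMethod("show", "SubsampledMSA", function(object) {
    ex <- extrasMSA(object)
    cat(sprintf(
        "SubsampledMSA %d:%d (seed %d): %d centers, %d extras\n",
        object@maxSeq, object@extraSeq, object@seed,
        nSequences(object@centers), if (is.null(ex)) 0L else nSequences(ex)))
})

setMethod("show", "Ensemble", function(object) {
    cat(sprintf("Ensemble: %d frames x %d residues (%d-%d)\n",
                nFrames(object), nResidues(object),
                min(object@residueNumbers), max(object@residueNumbers)))
})

setMethod("show", "StructureFrame", function(object) {
    cat(sprintf("StructureFrame '%s': %d CA atoms, mean pLDDT %.1f\n",
                object@frameId, nResidues(object), mean(object@plddt)))
})

setMethod("show", "Superposition", function(object) {
    cat(sprintf("Superposition: rmsd = %.4f A\n", object@rmsd))
})

setMethod("show", "FlexProfile", function(object) {
    cat(sprintf("FlexProfile: %d residues, RMSF %.2f-%.2f A, mean pLDDT %.1f\n",
                length(object@rmsf), min(object@rmsf), max(object@rmsf),
                mean(object@meanPlddt)))
})

setMethod("show", "StateModel", function(object) {
    cat(sprintf("StateModel: k=%d, populations %s%%, score %.2f\n",
                object@k, paste(sprintf("%.1f", object@populations),
                                collapse = "/"),
                object@score))
})

setMethod("show", "ToyWorld", function(object) {
    cat(sprintf("ToyWorld: %d conformations x %d residues, sigma=%.2f A\n",
                length(object@conformations),
                nrow(object@conformations[[1L]]), object@noiseSigma))
})
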
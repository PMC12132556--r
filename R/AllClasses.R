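#' @import methods
NULL

#' Multiple sequence alignment over a rectangular column space
#'
#' An \code{MSA} holds a query (target) sequence plus aligned homologs in a
#' shared column space.  Rows are stored as uppercase strings over
#' \code{A..Z} and \code{-}; A3M lowercase insertion characters are removed
#' at read time so every row spans exactly \code{nColumns(x)} columns.  By
#' convention record 1 is the target sequence and \code{targetId(x)} is its
#' identifier.
#'
#' @slot targetId identifier of the first record.
#' @slot ids character vector of record identifiers (unique).
#' @slot rows character vector of aligned rows, same length as \code{ids}.
#' @aliases MSA
#' @exportClass MSA
setClass("MSA", representation(
    targetId = "character",
    ids      = "character",
    rows     = "character"
))

setValidity("MSA", function(object) {
    msg <- character()
    if (length(object@ids) != length(object@rows))
        msg <- c(msg, "ids and rows must have equal length")
    if (length(object@rows) == 0L)
        msg <- c(msg, "an MSA must contain at least one sequence")
    else {
        w <- nchar(object@rows)
        if (length(unique(w)) != 1L)
            msg <- c(msg, sprintf("ragged alignment: rows have widths %s",
                                  paste(unique(w), collapse = ", ")))
        if (!identical(object@targetId, object@ids[[1L]]))
            msg <- c(msg, "targetId must equal the id of the first record")
        if (anyDuplicated(object@ids))
            msg <- c(msg, "record ids must be unique")
        if (any(grepl("[^A-Z-]", object@rows)))
            msg <- c(msg, "rows must contain only uppercase letters and '-'")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an MSA from ids and aligned rows
#'
#' @param ids character vector of record identifiers.
#' @param rows character vector of aligned rows (uppercase, gaps as '-').
#' @return An [MSA-class] object whose target is the first record.
#' @examples
#' msa <- MSA(c("q", "h1"), c("ACDE", "AC-E"))
#' nColumns(msa)
#' @export
MSA <- function(ids, rows) {
    ids <- make.unique(as.character(ids), sep = "_dup")
    new("MSA", targetId = ids[[1L]], ids = ids, rows = toupper(as.character(rows)))
}

#' Subsampling parameters: max_seq, extra_seq and seeds
#'
#' The two knobs of alignment subsampling: \code{maxSeq} (N, the number of
#' Hamming cluster centres, the target always being one) and \code{extraSeq}
#' (M, the number of additional sequences sampled from around the centres),
#' plus the list of random seeds over which predictions are repeated.
#'
#' @slot maxSeq positive integer, number of cluster centres (N).
#' @slot extraSeq non-negative integer, extra-sequence sample size (M).
#' @slot seeds non-empty vector of non-negative integer seeds.
#' @exportClass SubsampleParams
setClass("SubsampleParams", representation(
    maxSeq   = "integer",
    extraSeq = "integer",
    seeds    = "integer"
))

setValidity("SubsampleParams", function(object) {
    msg <- character()
    if (length(object@maxSeq) != 1L || is.na(object@maxSeq) || object@maxSeq < 1L)
        msg <- c(msg, "maxSeq must be a single integer >= 1")
    if (length(object@extraSeq) != 1L || is.na(object@extraSeq) || object@extraSeq < 0L)
        msg <- c(msg, "extraSeq must be a single integer >= 0")
    if (length(object@seeds) < 1L || anyNA(object@seeds) || any(object@seeds < 0L))
        msg <- c(msg, "seeds must be a non-empty vector of non-negative integers")
    if (length(msg)) msg else TRUE
})

#' @rdname SubsampleParams-class
#' @param maxSeq number of cluster centres (N).
#' @param extraSeq extra-sequence sample size (M).
#' @param seeds vector of non-negative integer seeds (default 0).
#' @return A \code{SubsampleParams} object.
#' @export
SubsampleParams <- function(maxSeq, extraSeq, seeds = 0L) {
    new("SubsampleParams", maxSeq = as.integer(maxSeq),
        extraSeq = as.integer(extraSeq), seeds = as.integer(seeds))
}

#' Hamming cluster assignment of alignment rows
#'
#' @slot centerIndices integer row indices of the cluster centres in the
#'   source alignment; the target row (index 1) is always first.
#' @slot membership integer vector, one entry per source row, giving the
#'   position in \code{centerIndices} of the row's nearest centre (centres
#'   map to themselves).
#' @exportClass ClusterAssignment
setClass("ClusterAssignment", representation(
    centerIndices = "integer",
    membership    = "integer"
))

setValidity("ClusterAssignment", function(object) {
    msg <- character()
    if (anyDuplicated(object@centerIndices))
        msg <- c(msg, "centre indices must be distinct")
    if (length(object@centerIndices) == 0L || object@centerIndices[[1L]] != 1L)
        msg <- c(msg, "the target row (index 1) must be the first centre")
    k <- length(object@centerIndices)
    if (length(object@membership) &&
        (anyNA(object@membership) || any(object@membership < 1L | object@membership > k)))
        msg <- c(msg, "membership entries must point into centerIndices")
    if (length(msg)) msg else TRUE
})

#' A subsampled alignment pair: centres plus extra sequences
#'
#' @slot centers [MSA-class] of the cluster-centre rows, target first.
#' @slot extras [MSA-class] of the sampled extra rows (possibly empty,
#'   stored as a zero-row placeholder), disjoint from the centres.
#' @slot maxSeq,extraSeq,seed the parameters that produced the pair.
#' @exportClass SubsampledMSA
setClass("SubsampledMSA", representation(
    centers  = "MSA",
    extras   = "list",   # list() when no extras survive clamping, else list(MSA)
    maxSeq   = "integer",
    extraSeq = "integer",
    seed     = "integer"
))

setValidity("SubsampledMSA", function(object) {
    msg <- character()
    if (length(object@extras) > 1L ||
        (length(object@extras) == 1L && !is(object@extras[[1L]], "MSA")))
        msg <- c(msg, "extras must be list() or a list of one MSA")
    if (length(object@extras) == 1L) {
        if (length(intersect(object@centers@rows, object@extras[[1L]]@rows)))
            msg <- c(msg, "centers and extras must be disjoint by row identity")
    }
    if (length(msg)) msg else TRUE
})

#' A single predicted structure frame (CA trace + pLDDT)
#'
#' @slot frameId source filename stem.
#' @slot coords n x 3 matrix of CA coordinates in Angstrom.
#' @slot residueNumbers strictly increasing integer residue numbers.
#' @slot residueNames three-letter residue names (may be empty).
#' @slot plddt per-residue confidence in [0, 100] (AlphaFold convention,
#'   stored in the PDB B-factor field).
#' @exportClass StructureFrame
setClass("StructureFrame", representation(
    frameId        = "character",
    coords         = "matrix",
    residueNumbers = "integer",
    residueNames   = "character",
    plddt          = "numeric"
))

setValidity("StructureFrame", function(object) {
    msg <- character()
    n <- nrow(object@coords)
    if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be an n x 3 matrix")
    if (length(object@residueNumbers) != n || length(object@plddt) != n)
        msg <- c(msg, "coords, residueNumbers and plddt must agree in length")
    if (n > 1L && any(diff(object@residueNumbers) <= 0L))
        msg <- c(msg, "residue numbers must be strictly increasing")
    if (length(object@plddt) && (anyNA(object@plddt) ||
        any(object@plddt < 0 | object@plddt > 100)))
        msg <- c(msg, "pLDDT values must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' An ensemble of same-sequence predicted structures
#'
#' All frames share one residue numbering; analyses (RMSF, RMSD, TM-score)
#' use the CA coordinates and the per-residue pLDDT stored with each frame.
#'
#' @slot frameIds frame identifiers, in sorted-filename order.
#' @slot coords numeric array [n_residues, 3, n_frames].
#' @slot residueNumbers shared strictly increasing residue numbers.
#' @slot residueNames three-letter residue names of the shared sequence.
#' @slot plddt matrix [n_residues, n_frames] of pLDDT values.
#' @exportClass Ensemble
setClass("Ensemble", representation(
    frameIds       = "character",
    coords         = "array",
    residueNumbers = "integer",
    residueNames   = "character",
    plddt          = "matrix"
))

setValidity("Ensemble", function(object) {
    msg <- character()
    d <- dim(object@coords)
    if (length(d) != 3L || d[2L] != 3L)
        msg <- c(msg, "coords must be an [n, 3, frames] array")
    else {
        if (d[3L] < 1L) msg <- c(msg, "an ensemble needs at least one frame")
        if (length(object@frameIds) != d[3L])
            msg <- c(msg, "frameIds must match the number of frames")
        if (length(object@residueNumbers) != d[1L])
            msg <- c(msg, "residueNumbers must match the number of residues")
        if (!all(dim(object@plddt) == d[c(1L, 3L)]))
            msg <- c(msg, "plddt must be an [n, frames] matrix")
    }
    if (length(object@residueNumbers) > 1L && any(diff(object@residueNumbers) <= 0L))
        msg <- c(msg, "residue numbers must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Optimal rigid-body superposition
#'
#' Result of the Kabsch least-squares fit.  The transform maps mobile
#' coordinates (rows) as \code{x \%*\% rotation + translation}.
#'
#' @slot rotation 3 x 3 proper rotation matrix (det = +1).
#' @slot translation length-3 translation vector (Angstrom).
#' @slot rmsd minimised root-mean-square deviation (Angstrom).
#' @exportClass Superposition
setClass("Superposition", representation(
    rotation    = "matrix",
    translation = "numeric",
    rmsd        = "numeric"
))

setValidity("Superposition", function(object) {
    msg <- character()
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L)))
        msg <- c(msg, "rotation must be 3 x 3")
    else {
        if (max(abs(crossprod(R) - diag(3))) > 1e-8)
            msg <- c(msg, "rotation must be orthonormal")
        if (abs(det(R) - 1) > 1e-8)
            msg <- c(msg, "rotation must be proper (det = +1)")
    }
    if (length(object@translation) != 3L)
        msg <- c(msg, "translation must have length 3")
    if (object@rmsd < 0) msg <- c(msg, "rmsd must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Per-residue flexibility profile (RMSF + mean pLDDT)
#'
#' @slot residueNumbers residue numbers (PDB numbering).
#' @slot rmsf per-residue root-mean-square fluctuation (Angstrom) about the
#'   iterative mean structure.
#' @slot meanPlddt per-residue pLDDT averaged over frames.
#' @exportClass FlexProfile
setClass("FlexProfile", representation(
    residueNumbers = "integer",
    rmsf           = "numeric",
    meanPlddt      = "numeric"
))

setValidity("FlexProfile", function(object) {
    msg <- character()
    n <- length(object@residueNumbers)
    if (length(object@rmsf) != n || length(object@meanPlddt) != n)
        msg <- c(msg, "residueNumbers, rmsf and meanPlddt must agree in length")
    if (any(object@rmsf < 0)) msg <- c(msg, "rmsf must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Conformational-state model in RMSD space
#'
#' Clustering of ensemble frames in the space of RMSDs to one or two
#' reference conformations.  Cluster 0 is the most populated state.
#'
#' @slot labels named integer vector (frame id -> 0-based cluster index).
#' @slot centroids k x d matrix of cluster centroids in RMSD space
#'   (d = 1 or 2, columns named after the RMSD axes).
#' @slot populations percentages per cluster, summing to 100.
#' @slot k number of clusters.
#' @slot score ensemble variability score: mean pairwise centroid distance
#'   divided by the mean within-cluster spread (this package's definition;
#'   NA when degenerate, 0 when k = 1).
#' @exportClass StateModel
setClass("StateModel", representation(
    labels      = "integer",
    centroids   = "matrix",
    populations = "numeric",
    k           = "integer",
    score       = "numeric"
))

setValidity("StateModel", function(object) {
    msg <- character()
    if (abs(sum(object@populations) - 100) > 1e-9)
        msg <- c(msg, "populations must sum to 100")
    if (nrow(object@centroids) != object@k ||
        length(object@populations) != object@k)
        msg <- c(msg, "centroids and populations must have k entries")
    if (length(object@labels) &&
        (min(object@labels) < 0L || max(object@labels) != object@k - 1L))
        msg <- c(msg, "labels must cover 0 .. k-1")
    if (length(msg)) msg else TRUE
})

#' Planted-truth world for synthetic ensembles
#'
#' Defines the generative model behind synthetic CA-trace ensembles: a set
#' of planted conformations sampled with given weights, isotropic Gaussian
#' coordinate noise (tripled inside a planted flexible segment), a planted
#' per-residue pLDDT profile, and a seed.
#'
#' @slot conformations list of n x 3 coordinate matrices sharing one length.
#' @slot weights sampling probabilities, summing to 1.
#' @slot noiseSigma coordinate noise SD in Angstrom.
#' @slot flexibleSegment integer residue indices with 3x noise.
#' @slot plddtProfile planted per-residue pLDDT means.
#' @slot seed default RNG seed for sampling.
#' @exportClass ToyWorld
setClass("ToyWorld", representation(
    conformations   = "list",
    weights         = "numeric",
    noiseSigma      = "numeric",
    flexibleSegment = "integer",
    plddtProfile    = "numeric",
    seed            = "integer"
))

setValidity("ToyWorld", function(object) {
    msg <- character()
    if (length(object@conformations) < 1L)
        msg <- c(msg, "at least one conformation is required")
    n <- vapply(object@conformations, nrow, integer(1))
    if (length(unique(n)) != 1L)
        msg <- c(msg, "conformations must share one length")
    if (length(object@weights) != length(object@conformations))
        msg <- c(msg, "one weight per conformation is required")
    if (abs(sum(object@weights) - 1) > 1e-9)
        msg <- c(msg, "weights must sum to 1")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (length(object@plddtProfile) != n[[1L]])
        msg <- c(msg, "plddtProfile must have one value per residue")
    if (length(object@flexibleSegment) &&
        (min(object@flexibleSegment) < 1L || max(object@flexibleSegment) > n[[1L]]))
        msg <- c(msg, "flexibleSegment must index residues of the conformations")
    if (length(msg)) msg else TRUE
})
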
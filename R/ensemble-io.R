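# PDB records are parsed with bio3d; this file only enforces the ensemble
# contract (CA-only, one chain, shared residue numbering, pLDDT in B-factor).

readStructureFrameAtoms <- function(path, chain = NULL) {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e) stop("cannot parse PDB '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
    atoms <- pdb$atom
    atoms <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
    if (nrow(atoms) == 0L) stop("no CA ATOM records in '", path, "'")
    if (is.null(chain)) chain <- atoms$chain[[1L]]
    atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
    if (nrow(atoms) == 0L)
        stop("no CA atoms on chain '", chain, "' in '", path, "'")
    ins <- atoms$insert
    if (any(!is.na(ins) & ins != ""))
        stop("insertion codes are not supported (file '", path, "')")
    # altloc: keep the highest-occupancy CA per residue
    if (anyDuplicated(atoms$resno)) {
        o <- ifelse(is.na(atoms$o), 1, atoms$o)
        keep <- unlist(lapply(split(seq_len(nrow(atoms)), atoms$resno),
                              function(i) i[which.max(o[i])]))
        atoms <- atoms[sort(keep), , drop = FALSE]
    }
    atoms
}

#' Read one predicted structure (CA trace + pLDDT) from a PDB file
#'
#' Extracts the CA atoms of one chain, with the per-residue pLDDT taken
#' from the B-factor column (the convention used by AlphaFold-family
#' predictors, 0-100 scale).
#'
#' @param path PDB file.
#' @param chain chain identifier; default: the first chain in the file.
#' @return A [StructureFrame-class].
#' @export
readStructureFrame <- function(path, chain = NULL) {
    atoms <- readStructureFrameAtoms(path, chain)
    b <- atoms$b
    if (anyNA(b) || any(b < 0 | b > 100))
        stop("B-factor (pLDDT) values outside [0, 100] in '", path, "'")
    new("StructureFrame",
        frameId = tools::file_path_sans_ext(basename(path)),
        coords = cbind(x = atoms$x, y = atoms$y, z = atoms$z),
        residueNumbers = as.integer(atoms$resno),
        residueNames = as.character(atoms$resid),
        plddt = as.numeric(b))
}

#' Read a directory (or list) of predicted PDB structures as an ensemble
#'
#' One frame per file, ordered by sorted filename so the frame order never
#' depends on directory enumeration.  All frames must share the residue
#' numbering of the first frame; a file that does not is reported by name.
#'
#' @param paths a directory containing \code{.pdb} files, or a character
#'   vector of PDB paths.
#' @param chain chain to analyse (default: first chain of each file).
#' @return An [Ensemble-class].
#' @examples
#' world <- toyWorld(nRes = 30, seed = 1)
#' dir <- tempfile(); dir.create(dir)
#' writeEnsemblePDB(sampleToyEnsemble(world, 3)$ensemble, dir)
#' ens <- readEnsemble(dir)
#' ens
#' @export
readEnsemble <- function(paths, chain = NULL) {
    if (length(paths) == 1L && dir.exists(paths))
        paths <- list.files(paths, pattern = "\\.pdb$", full.names = TRUE)
    if (length(paths) < 1L || !all(file.exists(paths)))
        stop("no PDB files to read")
    paths <- paths[order(basename(paths))]
    frames <- lapply(paths, readStructureFrame, chain = chain)
    ref <- frames[[1L]]
    for (i in seq_along(frames)[-1L])
        if (!identical(frames[[i]]@residueNumbers, ref@residueNumbers))
            stop("ensemble mismatch: '", basename(paths[[i]]),
                 "' has a different residue set than '",
                 basename(paths[[1L]]), "'")
    n <- nResidues(ref)
    coords <- array(NA_real_, c(n, 3L, length(frames)))
    pl <- matrix(NA_real_, n, length(frames))
    for (i in seq_along(frames)) {
        coords[, , i] <- frames[[i]]@coords
        pl[, i] <- frames[[i]]@plddt
    }
    new("Ensemble",
        frameIds = vapply(frames, function(f) f@frameId, character(1)),
        coords = coords, residueNumbers = ref@residueNumbers,
        residueNames = ref@residueNames, plddt = pl)
}

#' Load a reference structure aligned to an ensemble's residues
#'
#' Reads a PDB reference (for example a known active or inactive state) and
#' restricts it to the ensemble's residue numbers so frame-vs-reference
#' RMSDs compare like with like.  References with extra terminal residues
#' load over the shared range via \code{selection}; a reference whose
#' sequence differs at shared positions loads with a warning.
#'
#' @param path reference PDB file.
#' @param ensemble the [Ensemble-class] it will be compared against.
#' @param chain chain to read.
#' @param selection optional integer vector of residue numbers restricting
#'   the comparison range.
#' @return A [StructureFrame-class] whose residues exactly match
#'   (the selected subset of) the ensemble's.
#' @export
loadReference <- function(path, ensemble, chain = NULL, selection = NULL) {
    stopifnot(is(ensemble, "Ensemble"))
    ref <- readStructureFrame(path, chain)
    want <- ensemble@residueNumbers
    if (!is.null(selection)) want <- intersect(want, as.integer(selection))
    if (length(want) == 0L)
        stop("residue selection does not intersect the ensemble")
    missing <- setdiff(want, ref@residueNumbers)
    if (length(missing))
        stop("reference '", basename(path), "' lacks ", length(missing),
             " ensemble residue(s), e.g. ", missing[[1L]],
             "; restrict with 'selection'")
    idx <- match(want, ref@residueNumbers)
    out <- new("StructureFrame", frameId = ref@frameId,
               coords = ref@coords[idx, , drop = FALSE],
               residueNumbers = ref@residueNumbers[idx],
               residueNames = ref@residueNames[idx],
               plddt = ref@plddt[idx])
    ensNames <- ensemble@residueNames[match(want, ensemble@residueNumbers)]
    if (length(ensNames) && length(out@residueNames) &&
        any(ensNames != out@residueNames))
        warning("reference sequence differs from the ensemble at ",
                sum(ensNames != out@residueNames), " position(s)")
    out
}

#' Write a CA-trace frame or ensemble as PDB files
#'
#' Writes CA-only PDB files with the pLDDT in the B-factor column, the
#' format the ensemble readers consume.  Coordinates are stored at the PDB
#' fixed-column precision of 0.001 Angstrom.
#'
#' @param frame a [StructureFrame-class].
#' @param path output PDB path.
#' @return The path(s) written, invisibly.
#' @export
writeFramePDB <- function(frame, path) {
    stopifnot(is(frame, "StructureFrame"))
    n <- nResidues(frame)
    resid <- if (length(frame@residueNames) == n) frame@residueNames
             else rep("ALA", n)
    bio3d::write.pdb(file = path, xyz = as.vector(t(frame@coords)),
                     resno = frame@residueNumbers, resid = resid,
                     eleno = seq_len(n), elety = rep("CA", n),
                     chain = rep("A", n), o = rep(1, n), b = frame@plddt)
    invisible(path)
}

#' @rdname writeFramePDB
#' @param ensemble an [Ensemble-class].
#' @param dir output directory (created if needed); one file per frame,
#'   named \code{<frameId>.pdb}.
#' @export
writeEnsemblePDB <- function(ensemble, dir) {
    stopifnot(is(ensemble, "Ensemble"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, paste0(ensemble@frameIds, ".pdb"))
    for (i in seq_len(nFrames(ensemble)))
        writeFramePDB(getFrame(ensemble, i), paths[[i]])
    invisible(paths)
}
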
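#' Optimal rigid superposition of two CA coordinate sets (Kabsch)
#'
#' Computes the proper rotation and translation that minimise the RMSD of
#' \code{mobile} onto \code{reference}, via the SVD of the cross-covariance
#' of the centred point sets with the usual sign correction to exclude
#' reflections.
#'
#' @param mobile,reference n x 3 coordinate matrices (or
#'   [StructureFrame-class] objects) with matched rows, n >= 3.
#' @return A [Superposition-class]; the transform maps mobile rows as
#'   \code{x \%*\% rotation + translation}.
#' @examples
#' x <- matrix(rnorm(18), 6, 3)
#' superpose(x, x)@rmsd        # 0
#' @export
superpose <- function(mobile, reference) {
    mobile <- asCoords(mobile)
    reference <- asCoords(reference)
    n <- nrow(mobile)
    if (n != nrow(reference))
        stop("coordinate sets differ in length (", n, " vs ",
             nrow(reference), ")")
    if (n < 3L) stop("at least 3 points are required for superposition")
    cm <- colMeans(mobile)
    cr <- colMeans(reference)
    X <- sweep(mobile, 2L, cm)
    Y <- sweep(reference, 2L, cr)
    C <- crossprod(X, Y)                    # 3x3 cross-covariance
    sv <- svd(C)
    s <- sign(det(sv$u %*% t(sv$v)))
    R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
    t. <- as.numeric(cr - cm %*% R)
    dev <- X %*% R - Y
    new("Superposition", rotation = R, translation = t.,
        rmsd = sqrt(mean(rowSums(dev * dev))))
}

#' Apply a superposition transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param sp a [Superposition-class].
#' @return Transformed n x 3 matrix.
#' @export
applySuperposition <- function(coords, sp) {
    sweep(asCoords(coords) %*% sp@rotation, 2L, sp@translation, "+")
}

#' Root-mean-square deviation between matched coordinate sets
#'
#' @param coordsA,coordsB n x 3 matrices or [StructureFrame-class] objects.
#' @param superposeFirst superpose optimally before measuring (default
#'   TRUE); with FALSE the deviation is measured in the given frames.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coordsA, coordsB, superposeFirst = TRUE) {
    coordsA <- asCoords(coordsA)
    coordsB <- asCoords(coordsB)
    if (nrow(coordsA) != nrow(coordsB))
        stop("coordinate sets differ in length")
    if (superposeFirst) return(superpose(coordsA, coordsB)@rmsd)
    dev <- coordsA - coordsB
    sqrt(mean(rowSums(dev * dev)))
}

#' Iterative mean structure of an ensemble
#'
#' The common RMSF reference: every frame is superposed onto the current
#' mean and the per-CA mean is recomputed, iterating until the mean moves
#' less than \code{tol} (unsuperposed RMSD between successive means) or
#' \code{maxIter} is reached (warning on non-convergence).
#'
#' @param ensemble an [Ensemble-class] (or [n, 3, frames] array).
#' @param tol convergence threshold in Angstrom (default 1e-3).
#' @param maxIter maximum iterations (default 10).
#' @return An n x 3 matrix of mean CA coordinates.
#' @export
meanStructure <- function(ensemble, tol = 1e-3, maxIter = 10L) {
    coords <- if (is(ensemble, "Ensemble")) ensemble@coords else ensemble
    stopifnot(length(dim(coords)) == 3L)
    nf <- dim(coords)[3L]
    mean. <- coords[, , 1L]
    if (nf == 1L) return(mean.)
    for (iter in seq_len(maxIter)) {
        fitted <- vapply(seq_len(nf), function(i)
            applySuperposition(coords[, , i], superpose(coords[, , i], mean.)),
            mean.)
        newMean <- apply(fitted, c(1L, 2L), mean)
        shift <- rmsd(newMean, mean., superposeFirst = FALSE)
        mean. <- newMean
        if (shift < tol) return(mean.)
    }
    warning(sprintf("mean structure not converged to %g A in %d iterations",
                    tol, maxIter))
    mean.
}

# Accept StructureFrame or matrix everywhere coordinates are expected.
asCoords <- function(x) {
    if (is(x, "StructureFrame")) return(x@coords)
    if (is.matrix(x) && ncol(x) == 3L) return(x)
    stop("expected an n x 3 coordinate matrix or a StructureFrame")
}
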
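#' Template-modelling score between two same-sequence CA traces
#'
#' Native TM-score for matched CA traces: with per-residue deviations
#' \eqn{d_i} under a superposition, the score is
#' \deqn{TM = \frac{1}{L} \sum_i \frac{1}{1 + (d_i/d_0)^2}, \qquad
#'       d_0 = 1.24 (L-15)^{1/3} - 1.8,}
#' normalised by the reference length L (equal to the mobile length here).
#' Because the ensemble shares one sequence, the residue correspondence is
#' fixed and only the superposition is searched: superpositions are seeded
#' from contiguous fragments (full chain, halves, sliding windows of L/4)
#' and each seed is refined by repeatedly re-superposing on the residues
#' within a d0-based distance cutoff until that residue set is stable; the
#' best score over all seeds is returned.  Scores lie in (0, 1], 1 meaning
#' identical structures; values above ~0.5 indicate the same fold.
#'
#' @param mobile,reference matched n x 3 coordinate matrices or
#'   [StructureFrame-class] objects, with L > 15 (the d0 formula is
#'   undefined at shorter lengths).
#' @param maxIter refinement iterations per seed (default 20).
#' @return The TM-score, a number in (0, 1].
#' @seealso [tmScoreFromDistances] for scoring a fixed superposition.
#' @export
tmScore <- function(mobile, reference, maxIter = 20L) {
    mobile <- asCoords(mobile)
    reference <- asCoords(reference)
    L <- nrow(reference)
    if (nrow(mobile) != L) stop("coordinate sets differ in length")
    if (L <= 15L)
        stop("TM-score requires more than 15 residues (d0 undefined)")
    d0 <- tmD0(L)

    seeds <- tmSeedFragments(L)
    best <- 0
    for (seed in seeds) {
        sub <- seed
        for (iter in seq_len(maxIter)) {
            sp <- superpose(mobile[sub, , drop = FALSE],
                            reference[sub, , drop = FALSE])
            d <- sqrt(rowSums((applySuperposition(mobile, sp) - reference)^2))
            best <- max(best, mean(1 / (1 + (d / d0)^2)))
            dcut <- d0
            repeat {
                newSub <- which(d < dcut)
                if (length(newSub) >= 3L) break
                dcut <- dcut + 0.5
            }
            if (identical(newSub, sub)) break
            sub <- newSub
        }
    }
    best
}

#' TM-score of a fixed set of residue deviations
#'
#' Evaluates the TM-score formula directly on per-residue deviations
#' \code{d} under a given (fixed) superposition, without searching over
#' superpositions.  Useful for calibration: residues all sitting exactly at
#' d0 score 0.5 by construction.
#'
#' @param d vector of per-residue deviations (Angstrom).
#' @param L normalisation length (default \code{length(d)}); must exceed 15.
#' @return The score \eqn{(1/L)\sum 1/(1+(d_i/d_0)^2)}.
#' @examples
#' tmScoreFromDistances(rep(tmD0(50), 50))   # exactly 0.5
#' @export
tmScoreFromDistances <- function(d, L = length(d)) {
    if (L <= 15L)
        stop("TM-score requires more than 15 residues (d0 undefined)")
    sum(1 / (1 + (d / tmD0(L))^2)) / L
}

#' @rdname tmScoreFromDistances
#' @export
tmD0 <- function(L) 1.24 * (L - 15)^(1/3) - 1.8

# Contiguous fragment seeds: full chain, halves, sliding windows of L/4.
tmSeedFragments <- function(L) {
    half <- L %/% 2L
    w <- max(L %/% 4L, 4L)
    step <- max(w %/% 2L, 1L)
    starts <- unique(c(seq(1L, L - w + 1L, by = step), L - w + 1L))
    c(list(seq_len(L), seq_len(half), (half + 1L):L),
      lapply(starts, function(s) s:(s + w - 1L)))
}
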
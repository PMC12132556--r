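# Synthetic fixture generator: family-structured alignments and multi-state
# CA ensembles with planted ground truth.  These stand in for homology
# search and structure-prediction inference, so every analysis can be
# tested against a known answer.

#' Idealised two-state CA traces related by a hinge motion
#'
#' Builds a CA trace with exact 3.8 Angstrom consecutive spacing (a coil
#' with helix-like winding, so it is never collinear) and a second
#' conformation in which the C-terminal half is rigidly rotated by
#' \code{hingeAngle} about a pivot at the middle residue -- the classic toy
#' model of a domain hinge motion.  The two conformations are identical up
#' to the hinge residue.
#'
#' @param nRes number of residues (>= 20).
#' @param hingeAngle hinge rotation in degrees.
#' @return list with elements \code{conf1}, \code{conf2} (n x 3 matrices)
#'   and \code{hinge} (the pivot residue index).
#' @export
makeToyConformations <- function(nRes, hingeAngle) {
    if (nRes < 20L) stop("at least 20 residues are required")
    rise <- 1.5
    turn <- 100 * pi / 180
    radius <- sqrt(3.8^2 - rise^2) / (2 * sin(turn / 2))
    i <- seq_len(nRes) - 1L
    conf1 <- cbind(radius * cos(i * turn), radius * sin(i * turn), rise * i)
    hinge <- nRes %/% 2L
    conf2 <- rotateAboutPoint(conf1, hinge, hingeAngle)
    list(conf1 = conf1, conf2 = conf2, hinge = hinge)
}

# Rotate residues beyond `hinge` about the x-axis through CA[hinge].
rotateAboutPoint <- function(coords, hinge, angleDeg) {
    a <- angleDeg * pi / 180
    Rx <- matrix(c(1, 0, 0,
                   0, cos(a), sin(a),
                   0, -sin(a), cos(a)), 3L, 3L)
    out <- coords
    tail <- (hinge + 1L):nrow(coords)
    pivot <- coords[hinge, ]
    out[tail, ] <- sweep(sweep(coords[tail, , drop = FALSE], 2L, pivot) %*% Rx,
                         2L, pivot, "+")
    out
}

#' Construct a planted-truth world for synthetic ensembles
#'
#' Convenience constructor for [ToyWorld-class]: one conformation per hinge
#' angle (all sharing the hinge of [makeToyConformations]), sampling
#' weights, a global coordinate noise level (tripled inside the planted
#' flexible segment), and a planted pLDDT profile that is low (mean 65)
#' inside the flexible segment and high (mean 92) elsewhere -- mirroring
#' the empirical anticorrelation between mobility and prediction
#' confidence.
#'
#' @param nRes number of residues (default 60).
#' @param hingeAngles one hinge angle (degrees) per planted conformation
#'   (default \code{c(0, 30)}).
#' @param weights sampling probabilities (default uniform).
#' @param noiseSigma coordinate noise SD in Angstrom (default 0.2).
#' @param flexibleSegment residue indices of the planted flexible segment
#'   (default: an 11-residue window in the N-terminal half, away from the
#'   hinge).
#' @param seed default RNG seed.
#' @return A [ToyWorld-class].
#' @export
toyWorld <- function(nRes = 60L, hingeAngles = c(0, 30),
                     weights = NULL, noiseSigma = 0.2,
                     flexibleSegment = NULL, seed = 0L) {
    confs <- lapply(hingeAngles, function(a)
        makeToyConformations(nRes, a)$conf2)
    if (is.null(weights)) weights <- rep(1, length(confs)) / length(confs)
    if (is.null(flexibleSegment)) {
        mid <- max(nRes %/% 5L, 3L)
        flexibleSegment <- mid:min(mid + 10L, nRes %/% 2L - 2L)
    }
    plddtProfile <- rep(92, nRes)
    plddtProfile[flexibleSegment] <- 65
    new("ToyWorld", conformations = confs, weights = as.numeric(weights),
        noiseSigma = noiseSigma,
        flexibleSegment = as.integer(flexibleSegment),
        plddtProfile = plddtProfile, seed = as.integer(seed))
}

#' Sample a synthetic ensemble from a planted-truth world
#'
#' Each frame picks a planted conformation by the world's weights, adds
#' i.i.d. Gaussian coordinate noise (SD \code{noiseSigma}, tripled inside
#' the flexible segment), applies a random rigid motion (uniform random
#' rotation plus translation), and carries a pLDDT drawn around the
#' planted profile (SD 2, clamped to [0, 100]).  Deterministic per seed.
#'
#' @param world a [ToyWorld-class].
#' @param nFrames number of frames (>= 1).
#' @param seed RNG seed (default: the world's).
#' @return list with \code{ensemble} (an [Ensemble-class]) and
#'   \code{labels} (planted state index per frame, 1-based).
#' @export
sampleToyEnsemble <- function(world, nFrames, seed = world@seed) {
    stopifnot(is(world, "ToyWorld"))
    if (nFrames < 1L) stop("nFrames must be >= 1")
    n <- nrow(world@conformations[[1L]])
    sigma <- rep(world@noiseSigma, n)
    sigma[world@flexibleSegment] <- 3 * world@noiseSigma
    withSeed(deriveSeed(seed, 37L), {
        labels <- sample.int(length(world@conformations), nFrames,
                             replace = TRUE, prob = world@weights)
        coords <- array(NA_real_, c(n, 3L, nFrames))
        pl <- matrix(NA_real_, n, nFrames)
        for (f in seq_len(nFrames)) {
            x <- world@conformations[[labels[f]]] +
                matrix(stats::rnorm(3L * n, sd = rep(sigma, 3L)), n, 3L)
            R <- randomRotation()
            x <- x %*% R + matrix(stats::runif(3L, -20, 20), n, 3L,
                                  byrow = TRUE)
            coords[, , f] <- round(x, 3L)     # PDB column precision
            pl[, f] <- pmin(100, pmax(0, world@plddtProfile +
                                          stats::rnorm(n, sd = 2)))
        }
        ens <- new("Ensemble",
                   frameIds = sprintf("frame_%04d", seq_len(nFrames)),
                   coords = coords,
                   residueNumbers = seq_len(n),
                   residueNames = rep("ALA", n),
                   plddt = round(pl, 2L))
        list(ensemble = ens, labels = labels)
    })
}

# Uniform random proper rotation via QR of a Gaussian matrix.
randomRotation <- function() {
    qr. <- qr(matrix(stats::rnorm(9L), 3L, 3L))
    Q <- qr.Q(qr.)
    Q <- Q %*% diag(sign(diag(qr.R(qr.))))
    if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
    Q
}

#' Synthetic family-structured alignment with planted family labels
#'
#' Generates an alignment of \code{nFamilies} sequence families: family
#' ancestors differ from each other at the same \code{interFamilyMutations}
#' columns (distinct letters per family, so every ancestor pair is at
#' Hamming distance about \code{interFamilyMutations}), and members mutate
#' their ancestor at up to \code{intraFamilyMutations} random columns.  The
#' target is the family-1 ancestor and is the first row.  Separability
#' requires \code{interFamilyMutations > 2 * intraFamilyMutations}.
#'
#' @param nFamilies number of families.
#' @param membersPerFamily members generated per family (besides the
#'   target).
#' @param length alignment width in columns.
#' @param interFamilyMutations columns at which family ancestors differ.
#' @param intraFamilyMutations maximum mutations per member.
#' @param seed RNG seed.
#' @return list with \code{msa} (an [MSA-class]) and \code{labels}
#'   (planted family index per row, 1-based; the target is family 1).
#' @export
makeSyntheticMSA <- function(nFamilies, membersPerFamily, length,
                             interFamilyMutations, intraFamilyMutations,
                             seed = 0L) {
    if (interFamilyMutations <= 2L * intraFamilyMutations)
        stop("separability requires interFamilyMutations > ",
             "2 * intraFamilyMutations")
    if (interFamilyMutations > length)
        stop("interFamilyMutations cannot exceed the alignment length")
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    withSeed(deriveSeed(seed, 53L), {
        ancestor <- sample(aa, length, replace = TRUE)
        divCols <- sample.int(length, interFamilyMutations)
        ancestors <- vector("list", nFamilies)
        ancestors[[1L]] <- ancestor
        for (f in seq_len(nFamilies)[-1L]) {
            a <- ancestor
            # a distinct letter per family at every divergent column
            a[divCols] <- vapply(divCols, function(col) {
                used <- vapply(ancestors[seq_len(f - 1L)],
                               function(prev) prev[[col]], character(1))
                sample(setdiff(aa, used), 1L)
            }, character(1))
            ancestors[[f]] <- a
        }
        ids <- "target"
        rows <- paste(ancestor, collapse = "")
        labels <- 1L
        for (f in seq_len(nFamilies)) {
            for (m in seq_len(membersPerFamily)) {
                s <- ancestors[[f]]
                nm <- sample.int(intraFamilyMutations + 1L, 1L) - 1L
                if (nm > 0L) {
                    pos <- sample.int(length, nm)
                    s[pos] <- vapply(pos, function(col)
                        sample(setdiff(aa, s[[col]]), 1L), character(1))
                }
                ids <- c(ids, sprintf("fam%d_m%d", f, m))
                rows <- c(rows, paste(s, collapse = ""))
                labels <- c(labels, f)
            }
        }
        list(msa = MSA(ids, rows), labels = labels)
    })
}
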
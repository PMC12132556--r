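#' Hamming distance between two aligned rows
#'
#' Counts positions at which the two rows differ.  The gap character
#' \code{"-"} is treated as an ordinary 21st letter, so a gap aligned
#' against a residue counts as one mismatch.
#'
#' @param rowA,rowB aligned strings of equal length.
#' @return Non-negative integer mismatch count.
#' @examples
#' hammingDistance("AC-G", "ACCG")   # 1
#' @export
hammingDistance <- function(rowA, rowB) {
    if (nchar(rowA) != nchar(rowB))
        stop("rows must have equal length (", nchar(rowA), " vs ",
             nchar(rowB), ")")
    sum(utf8ToInt(rowA) != utf8ToInt(rowB))
}

#' Cluster alignment rows around centre sequences in Hamming space
#'
#' Selects \code{nCenters} rows as cluster centres -- the target (row 1) is
#' always the first centre -- and assigns every remaining row to its
#' nearest centre by Hamming distance, ties broken toward the
#' earlier-selected centre.
#'
#' Two centre-selection strategies are available.  The default,
#' \code{"farthest"}, grows the centre set greedily by always adding the row
#' farthest (in Hamming distance) from the centres chosen so far, which
#' yields maximally diverse, reproducible centres; ties are broken at
#' random from \code{seed}.  \code{"random"} picks the non-target centres
#' uniformly at random.
#'
#' @param msa an [MSA-class] object.
#' @param nCenters requested number of centres (clamped to the number of
#'   rows, with a warning).
#' @param seed integer seed driving tie-breaks / random selection.
#' @param strategy \code{"farthest"} (default) or \code{"random"}.
#' @return A [ClusterAssignment-class].
#' @export
clusterMSA <- function(msa, nCenters, seed = 0L,
                       strategy = c("farthest", "random")) {
    strategy <- match.arg(strategy)
    stopifnot(is(msa, "MSA"), nCenters >= 1L)
    n <- nSequences(msa)
    nCenters <- as.integer(nCenters)
    if (nCenters > n) {
        warning("nCenters (", nCenters, ") exceeds the ", n,
                " available sequences; clamped")
        nCenters <- n
    }
    M <- msaCodeMatrix(msa@rows)
    distToRow <- function(i) colSums(M != M[, i]) # Hamming to every row

    centers <- withSeed(deriveSeed(seed, 7L), {
        if (strategy == "random") {
            if (nCenters > 1L)
                c(1L, sort(sample(seq_len(n)[-1L], nCenters - 1L)))
            else 1L
        } else {
            sel <- 1L
            minDist <- distToRow(1L)
            while (length(sel) < nCenters) {
                cand <- setdiff(seq_len(n), sel)
                best <- cand[minDist[cand] == max(minDist[cand])]
                pick <- if (length(best) > 1L) sample(best, 1L) else best
                sel <- c(sel, pick)
                minDist <- pmin(minDist, distToRow(pick))
            }
            sel
        }
    })

    D <- vapply(centers, distToRow, numeric(n))        # n x k
    membership <- max.col(-D, ties.method = "first")   # nearest, low index wins
    membership[centers] <- seq_along(centers)          # centres own themselves
    new("ClusterAssignment", centerIndices = as.integer(centers),
        membership = as.integer(membership))
}

#' Subsample an alignment into a centres + extras pair
#'
#' Implements the stochastic alignment subsampling behind
#' diversity-controlled structure prediction: the alignment rows are
#' clustered in Hamming space around \code{maxSeq} (N) centres with the
#' target always a centre, then \code{extraSeq} (M) additional sequences
#' are drawn from the non-centre rows around the centres.  Lower N and M
#' weaken the co-evolutionary signal and broaden the predicted ensemble.
#'
#' Extra sequences are allocated round-robin across clusters in descending
#' cluster-size order, sampling uniformly without replacement within each
#' cluster, so every populated cluster contributes before any contributes
#' twice.  The draw is deterministic for a fixed
#' \code{(msa, maxSeq, extraSeq, seed)}: each parameter/seed combination
#' owns a private RNG stream and global RNG state is never touched.
#'
#' @param msa an [MSA-class] object.
#' @param params a [SubsampleParams-class]; alternatively give
#'   \code{maxSeq}/\code{extraSeq} directly.
#' @param seed integer seed for this draw (default: first seed in
#'   \code{params}).
#' @param maxSeq,extraSeq scalar alternatives to \code{params}.
#' @param strategy centre-selection strategy, see [clusterMSA].
#' @param dedup drop duplicate rows before clustering (default TRUE).
#' @return A [SubsampledMSA-class] with disjoint centres and extras.
#' @examples
#' set.seed(1)
#' msa <- makeSyntheticMSA(3, 20, 40, 12, 2, seed = 1)$msa
#' sub <- subsampleMSA(msa, maxSeq = 8, extraSeq = 16, seed = 0)
#' sub
#' @export
subsampleMSA <- function(msa, params = NULL, seed = NULL,
                         maxSeq = NULL, extraSeq = NULL,
                         strategy = c("farthest", "random"), dedup = TRUE) {
    strategy <- match.arg(strategy)
    stopifnot(is(msa, "MSA"))
    if (is.null(params)) {
        stopifnot(!is.null(maxSeq), !is.null(extraSeq))
        params <- SubsampleParams(maxSeq, extraSeq,
                                  if (is.null(seed)) 0L else seed)
    }
    validObject(params)
    if (is.null(seed)) seed <- params@seeds[[1L]]
    seed <- as.integer(seed)
    if (dedup) msa <- dedupMSA(msa)
    n <- nSequences(msa)

    nCenters <- params@maxSeq
    if (nCenters > n) {
        warning("max_seq (", nCenters, ") exceeds the ", n,
                " distinct sequences; clamped")
        nCenters <- n
    }
    stream <- deriveSeed(params@maxSeq, params@extraSeq, seed)
    asg <- clusterMSA(msa, nCenters, seed = stream, strategy = strategy)
    centerIdx <- asg@centerIndices

    # per-cluster non-centre members, visited largest cluster first
    members <- lapply(seq_along(centerIdx), function(j)
        setdiff(which(asg@membership == j), centerIdx))
    sizes <- lengths(members)
    order. <- order(-sizes, seq_along(sizes))
    nExtras <- min(params@extraSeq, n - length(centerIdx))
    if (params@extraSeq > n - length(centerIdx))
        warning("extra_seq (", params@extraSeq,
                ") exceeds the available non-centre sequences; clamped to ",
                nExtras)
    extraIdx <- integer(0)
    if (nExtras > 0L) {
        shuffled <- withSeed(deriveSeed(stream, 11L),
                             lapply(members[order.], function(m)
                                 if (length(m) > 1L) sample(m) else m))
        depth <- max(lengths(shuffled))
        pool <- unlist(lapply(seq_len(depth), function(d)
            unlist(lapply(shuffled, function(m)
                if (length(m) >= d) m[[d]] else NULL))))
        extraIdx <- pool[seq_len(nExtras)]
    }

    centers <- MSA(msa@ids[centerIdx], msa@rows[centerIdx])
    extras <- if (length(extraIdx))
        list(MSA(msa@ids[extraIdx], msa@rows[extraIdx])) else list()
    new("SubsampledMSA", centers = centers, extras = extras,
        maxSeq = params@maxSeq, extraSeq = params@extraSeq, seed = seed)
}

#' Write a grid of subsampled alignments plus a JSON manifest
#'
#' For every parameter pair in \code{grid} and every seed it carries, draws
#' a centres/extras pair with [subsampleMSA] and writes both as A3M files
#' named \code{centers_<N>_<M>_seed<S>.a3m} / \code{extras_...}.  Repeating
#' predictions over several seeds and parameter pairs is how the ensemble's
#' diversity is tuned.
#'
#' @param msa an [MSA-class].
#' @param grid a [SubsampleParams-class] or list of them.
#' @param outDir output directory (created if needed).
#' @param strategy,dedup passed to [subsampleMSA].
#' @return Invisibly, a data.frame manifest (max_seq, extra_seq, seed,
#'   centers_path, extras_path); also written as \code{manifest.json}.
#' @export
emitSubsampleJobs <- function(msa, grid, outDir,
                              strategy = c("farthest", "random"),
                              dedup = TRUE) {
    strategy <- match.arg(strategy)
    if (is(grid, "SubsampleParams")) grid <- list(grid)
    stopifnot(all(vapply(grid, is, logical(1), "SubsampleParams")))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)

    rows <- list()
    for (params in grid) {
        for (seed in params@seeds) {
            sub <- subsampleMSA(msa, params, seed = seed,
                                strategy = strategy, dedup = dedup)
            tag <- sprintf("%d_%d_seed%d", params@maxSeq, params@extraSeq, seed)
            cPath <- file.path(outDir, sprintf("centers_%s.a3m", tag))
            writeMSA(sub@centers, cPath, format = "a3m")
            ex <- extrasMSA(sub)
            ePath <- NA_character_
            if (!is.null(ex)) {
                ePath <- file.path(outDir, sprintf("extras_%s.a3m", tag))
                writeMSA(ex, ePath, format = "a3m")
            }
            rows[[length(rows) + 1L]] <- data.frame(
                max_seq = params@maxSeq, extra_seq = params@extraSeq,
                seed = seed, centers_path = cPath, extras_path = ePath,
                stringsAsFactors = FALSE)
        }
    }
    manifest <- if (length(rows)) do.call(rbind, rows) else
        data.frame(max_seq = integer(), extra_seq = integer(),
                   seed = integer(), centers_path = character(),
                   extras_path = character(), stringsAsFactors = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = FALSE, pretty = TRUE, na = "null")
    invisible(manifest)
}
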
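#' RMSD of every ensemble frame to one or two reference conformations
#'
#' Places each frame in the RMSD space used for conformational-state
#' analysis: its optimal-superposition RMSD to a first reference (for
#' example an active state) and optionally to a second (an inactive
#' state).  Clusters in this space correspond to conformational states.
#'
#' @param ensemble an [Ensemble-class].
#' @param ref1 a [StructureFrame-class] (see [loadReference]) or n x 3
#'   matrix matched to the ensemble residues.
#' @param ref2 optional second reference.
#' @param selection optional residue numbers restricting the comparison.
#' @return data.frame with columns \code{frame_id}, \code{rmsd_ref1} and,
#'   when \code{ref2} is given, \code{rmsd_ref2}.
#' @export
rmsdToReferences <- function(ensemble, ref1, ref2 = NULL, selection = NULL) {
    stopifnot(is(ensemble, "Ensemble"))
    idx <- selectResidues(ensemble@residueNumbers, selection)
    refCoords <- function(ref) {
        xyz <- asCoords(ref)
        if (is(ref, "StructureFrame") && nResidues(ref) == nResidues(ensemble))
            xyz[idx, , drop = FALSE]
        else if (nrow(xyz) == length(idx)) xyz
        else stop("reference is incompatible with the ensemble/selection")
    }
    r1 <- refCoords(ref1)
    r2 <- if (!is.null(ref2)) refCoords(ref2)
    out <- data.frame(
        frame_id = ensemble@frameIds,
        rmsd_ref1 = vapply(seq_len(nFrames(ensemble)), function(i)
            rmsd(ensemble@coords[idx, , i], r1), numeric(1)),
        stringsAsFactors = FALSE)
    if (!is.null(r2))
        out$rmsd_ref2 <- vapply(seq_len(nFrames(ensemble)), function(i)
            rmsd(ensemble@coords[idx, , i], r2), numeric(1))
    out
}

#' Kernel density estimate of an RMSD distribution
#'
#' Gaussian KDE on a regular grid spanning [min - 3bw, max + 3bw]; multiple
#' peaks in the density signal multiple conformational states.
#'
#' @param values numeric vector of RMSDs (>= 2 points).
#' @param bandwidth numeric bandwidth, or \code{"auto"} (Silverman's
#'   rule-of-thumb via [stats::bw.nrd0]).
#' @param n grid size (default 512).
#' @return data.frame with columns \code{grid} and \code{density}; the
#'   trapezoidal integral over the grid is 1 to within 1e-3.
#' @export
rmsdDensity <- function(values, bandwidth = "auto", n = 512L) {
    values <- as.numeric(values)
    if (length(values) < 2L) stop("at least 2 values are required")
    bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(values)
          else as.numeric(bandwidth)
    if (!is.finite(bw) || bw <= 0)            # degenerate spread
        bw <- max(abs(mean(values)) * 1e-3, 1e-3)
    d <- stats::density(values, bw = bw, n = n,
                        from = min(values) - 3 * bw, to = max(values) + 3 * bw)
    data.frame(grid = d$x, density = d$y)
}

#' Cluster ensemble frames into conformational states
#'
#' Partitions the frames in RMSD space (1D or 2D, from
#' [rmsdToReferences]) into k states by k-means, and reports per-state
#' populations as percentages of the ensemble.  Cluster 0 is always the
#' most populated state; ties are ordered by centroid distance to the
#' first reference.  With \code{k = "auto"}, k in 2..5 is chosen by mean
#' silhouette width, falling back to a single state when the best
#' silhouette is below 0.25 or fewer than 4 frames are available.
#'
#' The ensemble variability score reported alongside is this package's
#' definition: the mean pairwise distance between state centroids divided
#' by the mean within-state spread (distance of frames to their own
#' centroid), rounded to 2 decimals; 0 for a single state, NA when the
#' within-state spread is degenerate.
#'
#' @param points data.frame from [rmsdToReferences] (columns
#'   \code{frame_id}, \code{rmsd_ref1}, optionally \code{rmsd_ref2}).
#' @param k number of states, or \code{"auto"}.
#' @param seed integer seed (k-means uses random restarts).
#' @return A [StateModel-class].
#' @export
clusterStates <- function(points, k = "auto", seed = 0L) {
    stopifnot(is.data.frame(points), "rmsd_ref1" %in% names(points))
    axes <- intersect(c("rmsd_ref1", "rmsd_ref2"), names(points))
    X <- as.matrix(points[, axes, drop = FALSE])
    n <- nrow(X)
    auto <- identical(k, "auto")
    if (!auto) {
        k <- as.integer(k)
        if (k > n) stop("k (", k, ") exceeds the ", n, " frames")
    }

    fitK <- function(kk) stats::kmeans(X, centers = kk, nstart = 25L,
                                       iter.max = 100L)
    res <- withSeed(deriveSeed(seed, 23L), {
        if (auto) {
            ks <- 2:min(5L, n - 1L)
            if (n < 4L || nrow(unique(X)) < 2L) {
                list(fit = NULL, k = 1L)
            } else {
                ks <- ks[ks <= nrow(unique(X))]
                fits <- lapply(ks, fitK)
                sil <- vapply(seq_along(ks), function(i) {
                    mean(cluster::silhouette(fits[[i]]$cluster, stats::dist(X))[, 3L])
                }, numeric(1))
                if (!length(sil) || max(sil) < 0.25) list(fit = NULL, k = 1L)
                else list(fit = fits[[which.max(sil)]], k = ks[[which.max(sil)]])
            }
        } else if (k == 1L) {
            list(fit = NULL, k = 1L)
        } else {
            list(fit = fitK(k), k = k)
        }
    })

    if (is.null(res$fit)) {
        labels <- rep(0L, n)
        centers <- matrix(colMeans(X), 1L, length(axes),
                          dimnames = list(NULL, axes))
        sizes <- n
    } else {
        cl <- res$fit$cluster
        centers <- res$fit$centers
        sizes <- as.numeric(table(cl))
        # order: descending population, then centroid distance to ref1
        ord <- order(-sizes, centers[, "rmsd_ref1"])
        relabel <- match(seq_along(sizes), ord)
        labels <- relabel[cl] - 1L
        centers <- centers[ord, , drop = FALSE]
        sizes <- sizes[ord]
    }
    rownames(centers) <- NULL
    popul <- 100 * sizes / n
    kUsed <- res$k

    score <- if (kUsed == 1L) 0 else {
        within <- mean(sqrt(rowSums((X - centers[labels + 1L, , drop = FALSE])^2)))
        pairs <- utils::combn(kUsed, 2L)
        between <- mean(sqrt(colSums(
            (centers[pairs[1L, ], , drop = FALSE] -
             centers[pairs[2L, ], , drop = FALSE])^2)))
        if (within < 1e-9) NA_real_ else round(between / within, 2L)
    }
    new("StateModel",
        labels = stats::setNames(as.integer(labels), points$frame_id),
        centroids = centers, populations = popul, k = as.integer(kUsed),
        score = score)
}

#' Pairwise RMSD or TM-score matrix over an ensemble
#'
#' All-against-all comparison of the frames, giving a 2D map in which
#' blocks of mutually similar frames reveal conformational states.
#'
#' @param ensemble an [Ensemble-class].
#' @param metric \code{"rmsd"} (default) or \code{"tm"}; TM-score is
#'   symmetrised by averaging the two normalisation directions (equal-length
#'   chains make the two orientations nearly, not exactly, identical
#'   because the superposition search is seeded from the mobile chain).
#' @param selection optional residue numbers restricting the comparison.
#' @return N x N symmetric matrix with frame ids as dimnames; diagonal 0
#'   for RMSD, 1 for TM-score.
#' @export
pairwiseMatrix <- function(ensemble, metric = c("rmsd", "tm"),
                           selection = NULL) {
    metric <- match.arg(metric)
    stopifnot(is(ensemble, "Ensemble"))
    idx <- selectResidues(ensemble@residueNumbers, selection)
    nf <- nFrames(ensemble)
    M <- diag(if (metric == "rmsd") 0 else 1, nf)
    if (nf > 1L) {
        for (i in seq_len(nf - 1L)) {
            xi <- ensemble@coords[idx, , i]
            for (j in (i + 1L):nf) {
                xj <- ensemble@coords[idx, , j]
                M[i, j] <- M[j, i] <- if (metric == "rmsd") rmsd(xi, xj)
                    else (tmScore(xi, xj) + tmScore(xj, xi)) / 2
            }
        }
    }
    dimnames(M) <- list(ensemble@frameIds, ensemble@frameIds)
    M
}

#' Peaks in an RMSD-versus-frame series
#'
#' Applies the profile peak detector ([detectPeaks]) to an ordered RMSD
#' series (for example RMSD to a reference across frames) to flag frames
#' of noteworthy deviation, such as excursions into unphysical structures.
#'
#' @param values ordered numeric RMSD series.
#' @param width,height,prominence thresholds, see [detectPeaks].
#' @return data.frame of peak ranges in frame indices.
#' @export
rmsdProfilePeaks <- function(values, width = 3L, height = NULL,
                             prominence = NULL) {
    detectPeaks(as.numeric(values), width = width, height = height,
                prominence = prominence)
}

#' Write the conformational-state report (CSVs, JSON, plots)
#'
#' Writes the labelled RMSD points and the state populations as CSV, a
#' JSON summary (k, centroids, populations, variability score), the RMSD
#' scatter with centroids marked as crosses and an optional least-squares
#' quadratic trend curve (plot-only), per-axis RMSD density plots, and a
#' heatmap per supplied pairwise matrix.  In single-reference mode the
#' scatter is replaced by a 1D strip plus density.
#'
#' @param points data.frame from [rmsdToReferences].
#' @param model a [StateModel-class] from [clusterStates].
#' @param outDir output directory, created if needed.
#' @param matrices optional named list of pairwise matrices from
#'   [pairwiseMatrix]; each is written as CSV and drawn as a heatmap.
#' @param trendCurve draw the quadratic trend on the 2D scatter
#'   (default TRUE).
#' @return Invisibly, the named vector of file paths written.
#' @export
writeStatesReport <- function(points, model, outDir, matrices = NULL,
                              trendCurve = TRUE) {
    stopifnot(is.data.frame(points), is(model, "StateModel"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    twoD <- "rmsd_ref2" %in% names(points)
    labelled <- points
    labelled$cluster <- as.integer(model@labels[points$frame_id])

    paths <- c(points = file.path(outDir, "state_points.csv"),
               populations = file.path(outDir, "state_populations.csv"),
               summary = file.path(outDir, "state_summary.json"),
               scatter = file.path(outDir, "state_scatter.png"),
               density = file.path(outDir, "rmsd_density.png"))
    utils::write.csv(labelled, paths[["points"]], row.names = FALSE)
    utils::write.csv(data.frame(cluster = seq_len(model@k) - 1L,
                                population = model@populations),
                     paths[["populations"]], row.names = FALSE)
    jsonlite::write_json(
        list(k = model@k,
             centroids = as.data.frame(model@centroids),
             populations = model@populations,
             score = model@score,
             score_definition = paste("mean pairwise centroid distance /",
                                      "mean within-cluster spread",
                                      "(ConformR definition)")),
        paths[["summary"]], auto_unbox = TRUE, digits = NA, na = "null",
        pretty = TRUE)

    cols <- grDevices::hcl.colors(max(model@k, 2L), "Dark 3")
    grDevices::png(paths[["scatter"]], width = 700, height = 600)
    if (twoD) {
        plot(labelled$rmsd_ref1, labelled$rmsd_ref2,
             col = cols[labelled$cluster + 1L], pch = 19,
             xlab = "RMSD to Ref1 (A)", ylab = "RMSD to Ref2 (A)")
        if (trendCurve && nrow(labelled) >= 3L &&
            length(unique(labelled$rmsd_ref1)) >= 3L) {
            fit <- stats::lm(rmsd_ref2 ~ stats::poly(rmsd_ref1, 2L),
                             data = labelled)
            xs <- seq(min(labelled$rmsd_ref1), max(labelled$rmsd_ref1),
                      length.out = 100L)
            graphics::lines(xs, stats::predict(fit,
                newdata = data.frame(rmsd_ref1 = xs)), col = "red", lwd = 2)
        }
        graphics::points(model@centroids[, 1L], model@centroids[, 2L],
                         pch = 4L, cex = 2, lwd = 3)
    } else {
        graphics::stripchart(labelled$rmsd_ref1 ~ labelled$cluster,
                             method = "jitter", pch = 19, vertical = FALSE,
                             col = cols, xlab = "RMSD to Ref1 (A)",
                             ylab = "cluster")
        graphics::abline(v = model@centroids[, 1L], lty = 2L)
    }
    grDevices::dev.off()

    grDevices::png(paths[["density"]], width = 700, height = 500)
    dens1 <- rmsdDensity(points$rmsd_ref1)
    plot(dens1$grid, dens1$density, type = "l", lwd = 2,
         xlab = "RMSD (A)", ylab = "density", col = cols[1L])
    if (twoD) {
        dens2 <- rmsdDensity(points$rmsd_ref2)
        graphics::lines(dens2$grid, dens2$density, lwd = 2, col = cols[2L])
        graphics::legend("topright", legend = c("vs Ref1", "vs Ref2"),
                         col = cols[1:2], lwd = 2, bty = "n")
    }
    grDevices::dev.off()

    for (nm in names(matrices)) {
        M <- matrices[[nm]]
        csv <- file.path(outDir, sprintf("matrix_%s.csv", nm))
        utils::write.csv(as.data.frame(M), csv)
        png. <- file.path(outDir, sprintf("matrix_%s.png", nm))
        grDevices::png(png., width = 650, height = 600)
        graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), M,
                        col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                        xlab = "frame", ylab = "frame", main = nm)
        grDevices::dev.off()
        paths[[paste0("matrix_", nm, "_csv")]] <- csv
        paths[[paste0("matrix_", nm, "_png")]] <- png.
    }
    invisible(paths)
}
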
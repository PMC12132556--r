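#' Per-residue RMSF and mean pLDDT of an ensemble
#'
#' Superposes every frame onto the iterative mean structure
#' ([meanStructure]) and measures, per CA, the root-mean-square deviation
#' from that mean across frames; regions of enhanced flexibility appear as
#' peaks.  The per-residue pLDDT is averaged over frames alongside, since
#' highly mobile CAs tend to combine large RMSF with low pLDDT.
#'
#' @param ensemble an [Ensemble-class].
#' @param selection optional residue numbers restricting the analysis.
#' @param tol,maxIter passed to [meanStructure].
#' @return A [FlexProfile-class].  A single-frame ensemble yields an
#'   all-zero profile with a warning.
#' @export
computeRMSF <- function(ensemble, selection = NULL, tol = 1e-3, maxIter = 10L) {
    stopifnot(is(ensemble, "Ensemble"))
    idx <- selectResidues(ensemble@residueNumbers, selection)
    coords <- ensemble@coords[idx, , , drop = FALSE]
    pl <- ensemble@plddt[idx, , drop = FALSE]
    resno <- ensemble@residueNumbers[idx]
    nf <- dim(coords)[3L]
    if (nf < 2L) {
        warning("RMSF of a single-frame ensemble is identically zero")
        return(new("FlexProfile", residueNumbers = resno,
                   rmsf = numeric(length(idx)), meanPlddt = rowMeans(pl)))
    }
    mean. <- meanStructure(coords, tol = tol, maxIter = maxIter)
    sq <- matrix(0, length(idx), nf)
    for (i in seq_len(nf)) {
        fit <- applySuperposition(coords[, , i], superpose(coords[, , i], mean.))
        sq[, i] <- rowSums((fit - mean.)^2)
    }
    new("FlexProfile", residueNumbers = resno,
        rmsf = sqrt(rowMeans(sq)), meanPlddt = rowMeans(pl))
}

#' Detect contiguous peaks in a flexibility (or RMSD) profile
#'
#' Finds local maxima that satisfy all three user thresholds and reports
#' each as a maximal contiguous range: a candidate apex must reach
#' \code{height}, have topographic prominence of at least
#' \code{prominence}, and sit inside a contiguous above-\code{height}
#' region spanning at least \code{width} positions.  Range boundaries are
#' where the profile falls below \code{height} on each side of the apex;
#' apexes sharing one above-threshold region are reported as one range, and
#' dips below the threshold shorter than \code{width} between two
#' above-threshold runs are bridged, so one flexible region interrupted by
#' a brief dip yields one range rather than two.
#'
#' Defaults are scale-free: \code{height} = profile mean + 1 SD and
#' \code{prominence} = 1 SD, so they adapt across proteins.
#'
#' @param profile a [FlexProfile-class] or a numeric vector of values.
#' @param width minimum range width in positions (default 3).
#' @param height minimum value an apex (and the range) must reach.
#' @param prominence minimum topographic prominence of the apex.
#' @param positions positions to report ranges in (default: the profile's
#'   residue numbers, or indices for a bare vector).
#' @return A data.frame with columns \code{start_residue},
#'   \code{end_residue}, \code{max_rmsf}, \code{prominence}; zero rows when
#'   nothing qualifies.
#' @export
detectPeaks <- function(profile, width = 3L, height = NULL,
                        prominence = NULL, positions = NULL) {
    if (is(profile, "FlexProfile")) {
        values <- profile@rmsf
        if (is.null(positions)) positions <- profile@residueNumbers
    } else {
        values <- as.numeric(profile)
        if (is.null(positions)) positions <- seq_along(values)
    }
    if (is.null(height)) height <- mean(values) + stats::sd(values)
    if (is.null(prominence)) prominence <- stats::sd(values)
    if (is.na(height)) height <- Inf
    if (is.na(prominence)) prominence <- Inf
    stopifnot(width > 0, length(values) == length(positions))
    findProfilePeaks(values, positions, as.integer(width), height, prominence)
}

# Core peak scan shared by the RMSF and RMSD profile analyses.
findProfilePeaks <- function(values, positions, width, height, prominence) {
    empty <- data.frame(start_residue = integer(), end_residue = integer(),
                        max_rmsf = numeric(), prominence = numeric())
    n <- length(values)
    if (n < 2L) return(empty)
    # local maxima, plateau-aware: a strictly lower neighbour is required on
    # both sides, so profile edges and constant series never form apexes
    apexes <- which(vapply(seq_len(n), function(i) {
        if (i == 1L || values[i - 1L] >= values[i]) return(FALSE)
        r <- i + 1L
        while (r <= n && values[r] == values[i]) r <- r + 1L
        r <= n && values[r] < values[i]
    }, logical(1)))
    if (!length(apexes)) return(empty)

    prom <- vapply(apexes, function(i) peakProminence(values, i), numeric(1))
    ok <- values[apexes] >= height & prom >= prominence
    apexes <- apexes[ok]; prom <- prom[ok]
    if (!length(apexes)) return(empty)

    above <- values >= height
    # bridge sub-width dips between above-threshold runs so one flexible
    # region interrupted by a brief dip is reported as one range
    gaps <- rle(above)
    gEnds <- cumsum(gaps$lengths)
    gStarts <- gEnds - gaps$lengths + 1L
    for (g in seq_along(gaps$values))
        if (!gaps$values[g] && gaps$lengths[g] < width &&
            g > 1L && g < length(gaps$values))
            above[gStarts[g]:gEnds[g]] <- TRUE
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    seen <- integer(0)
    rows <- list()
    for (j in seq_along(apexes)) {
        run <- which(starts <= apexes[j] & ends >= apexes[j] & runs$values)
        if (length(run) != 1L) next
        k <- match(run, seen)
        if (!is.na(k)) {       # same contiguous region already reported
            rows[[k]]$max_rmsf <- max(rows[[k]]$max_rmsf, values[apexes[j]])
            rows[[k]]$prominence <- max(rows[[k]]$prominence, prom[j])
            next
        }
        if (ends[run] - starts[run] + 1L < width) next
        seen <- c(seen, run)
        rows[[length(rows) + 1L]] <- data.frame(
            start_residue = positions[starts[run]],
            end_residue = positions[ends[run]],
            max_rmsf = values[apexes[j]], prominence = prom[j])
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# Topographic prominence: height above the higher of the two key saddles
# (minima separating the apex from higher terrain, or the profile edge).
peakProminence <- function(values, i) {
    v <- values[i]
    left <- if (i > 1L) {
        higher <- which(values[seq_len(i - 1L)] > v)
        from <- if (length(higher)) max(higher) + 1L else 1L
        min(values[from:(i - 1L)])
    } else v
    n <- length(values)
    right <- if (i < n) {
        higher <- which(values[(i + 1L):n] > v)
        to <- if (length(higher)) i + min(higher) - 1L else n
        min(values[(i + 1L):to])
    } else v
    v - max(left, right)
}

#' Long-format RMSF/pLDDT table across conditions
#'
#' Combines one [FlexProfile-class] per subsampling condition into a
#' long-format table with one row per (condition, residue), ready for the
#' RMSF-vs-pLDDT scatter in which mobile residues separate as
#' high-RMSF/low-pLDDT points.
#'
#' @param profiles a named list of [FlexProfile-class] objects sharing one
#'   residue set (a bare FlexProfile is accepted).
#' @return data.frame with columns \code{condition}, \code{residue},
#'   \code{rmsf}, \code{mean_plddt}.
#' @export
rmsfPlddtTable <- function(profiles) {
    if (is(profiles, "FlexProfile")) profiles <- list(ensemble = profiles)
    stopifnot(length(profiles) >= 1L,
              all(vapply(profiles, is, logical(1), "FlexProfile")))
    if (is.null(names(profiles)) || any(names(profiles) == ""))
        names(profiles) <- paste0("condition", seq_along(profiles))
    ref <- profiles[[1L]]@residueNumbers
    for (nm in names(profiles))
        if (!identical(profiles[[nm]]@residueNumbers, ref))
            stop("profile '", nm, "' has a different residue set")
    do.call(rbind, lapply(names(profiles), function(nm) {
        p <- profiles[[nm]]
        data.frame(condition = nm, residue = p@residueNumbers,
                   rmsf = p@rmsf, mean_plddt = p@meanPlddt,
                   stringsAsFactors = FALSE)
    }))
}

#' Write the flexibility report (CSVs + plots)
#'
#' Writes the long-format profile table and the detected peak ranges as
#' CSV, plus three plots: RMSF per residue, mean pLDDT per residue (one
#' line per condition), and the RMSF-vs-pLDDT scatter coloured by residue
#' index.
#'
#' @param profiles a named list of [FlexProfile-class] objects (or one).
#' @param outDir output directory, created if needed.
#' @param peaks optional precomputed peak table; by default peaks are
#'   detected per condition with [detectPeaks] at the given thresholds.
#' @param width,height,prominence peak thresholds, see [detectPeaks].
#' @return Invisibly, the named vector of file paths written.
#' @export
writeFlexReport <- function(profiles, outDir, peaks = NULL, width = 3L,
                            height = NULL, prominence = NULL) {
    if (is(profiles, "FlexProfile")) profiles <- list(ensemble = profiles)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    tab <- rmsfPlddtTable(profiles)
    if (is.null(peaks)) {
        peaks <- do.call(rbind, lapply(names(profiles), function(nm) {
            p <- detectPeaks(profiles[[nm]], width = width, height = height,
                             prominence = prominence)
            if (nrow(p)) cbind(condition = nm, p) else NULL
        }))
        if (is.null(peaks))
            peaks <- data.frame(condition = character(),
                                start_residue = integer(),
                                end_residue = integer(),
                                max_rmsf = numeric(), prominence = numeric())
    }
    paths <- c(profile = file.path(outDir, "flex_profile.csv"),
               peaks = file.path(outDir, "flex_peaks.csv"),
               rmsf_plot = file.path(outDir, "rmsf_profile.png"),
               plddt_plot = file.path(outDir, "plddt_profile.png"),
               scatter_plot = file.path(outDir, "rmsf_vs_plddt.png"))
    utils::write.csv(tab, paths[["profile"]], row.names = FALSE)
    utils::write.csv(peaks, paths[["peaks"]], row.names = FALSE)

    conds <- names(profiles)
    cols <- grDevices::hcl.colors(max(length(conds), 2L), "Dark 3")
    plotLines <- function(file, field, ylab) {
        grDevices::png(file, width = 900, height = 500)
        on.exit(grDevices::dev.off())
        ylim <- range(unlist(lapply(profiles, slot, field)))
        plot(NA, xlim = range(profiles[[1L]]@residueNumbers), ylim = ylim,
             xlab = "residue", ylab = ylab)
        for (i in seq_along(conds))
            graphics::lines(profiles[[i]]@residueNumbers,
                            slot(profiles[[i]], field), col = cols[i], lwd = 2)
        graphics::legend("topright", legend = conds, col = cols[seq_along(conds)],
                         lwd = 2, bty = "n")
    }
    plotLines(paths[["rmsf_plot"]], "rmsf", "RMSF (A)")
    plotLines(paths[["plddt_plot"]], "meanPlddt", "mean pLDDT")

    grDevices::png(paths[["scatter_plot"]], width = 700, height = 600)
    resRange <- range(tab$residue)
    gradient <- grDevices::hcl.colors(100, "Viridis")
    colIdx <- 1L + floor(99 * (tab$residue - resRange[1L]) /
                         max(resRange[2L] - resRange[1L], 1L))
    plot(tab$rmsf, tab$mean_plddt, col = gradient[colIdx], pch = 19,
         xlab = "RMSF (A)", ylab = "mean pLDDT")
    grDevices::dev.off()
    invisible(paths)
}

selectResidues <- function(residueNumbers, selection) {
    if (is.null(selection)) return(seq_along(residueNumbers))
    idx <- which(residueNumbers %in% as.integer(selection))
    if (!length(idx)) stop("residue selection matches no residues")
    idx
}
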
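threeStateSample <- function(seed, n = 200L) {
    world <- toyWorld(nRes = 60, hingeAngles = c(0, 25, 50),
                      weights = c(0.7, 0.2, 0.1), noiseSigma = 0.2,
                      seed = seed)
    samp <- sampleToyEnsemble(world, n)
    list(world = world, samp = samp,
         points = rmsdToReferences(samp$ensemble, world@conformations[[1]],
                                   world@conformations[[3]]))
}

test_that("frame-vs-reference RMSDs anchor the state space", {
    world <- toyWorld(nRes = 30, hingeAngles = 0, weights = 1, seed = 21)
    samp <- sampleToyEnsemble(world, 5)
    ref1 <- getFrame(samp$ensemble, 1)
    pts <- rmsdToReferences(samp$ensemble, ref1)
    expect_equal(pts$rmsd_ref1[1], 0, tolerance = 1e-9)
    expect_false("rmsd_ref2" %in% names(pts))

    # two planted states separate into two groups in RMSD space
    ts <- threeStateSample(22, n = 60L)
    pts2 <- ts$points
    byState <- split(pts2$rmsd_ref1, ts$samp$labels)
    expect_lt(max(abs(byState[[1]] - mean(byState[[1]]))), 1)
    expect_gt(abs(mean(byState[[1]]) - mean(byState[[3]])), 2)
})

test_that("RMSD density integrates to one and finds planted modes", {
    set.seed(23)
    x <- c(rnorm(200, 2, 0.1), rnorm(100, 6, 0.1))
    d <- rmsdDensity(x)
    expect_equal(sum(d$density) * diff(d$grid[1:2]), 1, tolerance = 1e-3)
    # local maxima of the curve by direct grid scan: 2 well-separated modes
    y <- d$density
    apex <- which(diff(sign(diff(y))) == -2) + 1L
    apex <- apex[y[apex] > max(y) * 0.1]
    expect_identical(length(apex), 2L)
    expect_equal(sort(d$grid[apex]), c(2, 6), tolerance = 0.2)

    # degenerate sample: one narrow peak at the value
    dd <- rmsdDensity(rep(3.5, 10))
    expect_equal(dd$grid[which.max(dd$density)], 3.5, tolerance = 1e-2)
    expect_error(rmsdDensity(1), "at least 2")
})

test_that("state clustering contracts: populations, ordering, determinism", {
    pts <- data.frame(frame_id = sprintf("f%d", 1:10),
                      rmsd_ref1 = rep(1.5, 10), rmsd_ref2 = rep(2.5, 10))
    m <- clusterStates(pts, k = 1)
    expect_identical(m@k, 1L)
    expect_equal(populations(m), 100)
    expect_identical(unname(stateLabels(m)), rep(0L, 10))

    ts <- threeStateSample(24)
    m3 <- clusterStates(ts$points, k = 3, seed = 1)
    expect_equal(sum(populations(m3)), 100, tolerance = 1e-9)
    expect_true(all(diff(populations(m3)) <= 1e-9))   # cluster 0 largest
    expect_identical(m3@labels, clusterStates(ts$points, k = 3, seed = 1)@labels)

    # label permutation-invariance: shuffling rows leaves populations intact
    perm <- sample(nrow(ts$points))
    mP <- clusterStates(ts$points[perm, ], k = 3, seed = 1)
    expect_equal(sort(populations(mP)), sort(populations(m3)),
                 tolerance = 1e-9)
    expect_error(clusterStates(ts$points[1:2, ], k = 3), "exceeds")
})

test_that("planted populations are recovered within 5 points, k by silhouette", {
    for (s in 1:5) {
        ts <- threeStateSample(30 + s)
        planted <- 100 * as.numeric(table(factor(ts$samp$labels, 1:3))) / 200
        m <- clusterStates(ts$points, k = 3, seed = s)
        expect_lt(max(abs(sort(populations(m), decreasing = TRUE) -
                          sort(planted, decreasing = TRUE))), 5)
        auto <- clusterStates(ts$points, k = "auto", seed = s)
        expect_identical(auto@k, 3L)
        expect_gt(auto@score, 1)   # well-separated states score high
    }
})

test_that("pairwise matrices are symmetric with the right diagonal and blocks", {
    world <- toyWorld(nRes = 20, hingeAngles = 0, weights = 1, seed = 41)
    one <- sampleToyEnsemble(world, 1)
    M1 <- pairwiseMatrix(one$ensemble)
    expect_equal(unname(M1), matrix(0, 1, 1))

    ident <- new("Ensemble", frameIds = c("a", "b", "c"),
                 coords = array(rep(world@conformations[[1]], 3), c(20, 3, 3)),
                 residueNumbers = 1:20, residueNames = rep("ALA", 20),
                 plddt = matrix(90, 20, 3))
    expect_equal(max(pairwiseMatrix(ident, "rmsd")), 0, tolerance = 1e-9)

    ts <- threeStateSample(42, n = 12L)
    M <- pairwiseMatrix(ts$samp$ensemble, "rmsd")
    expect_equal(M, t(M), tolerance = 1e-6)
    expect_identical(unname(diag(M)), rep(0, 12))
    same <- outer(ts$samp$labels, ts$samp$labels, "==") & upper.tri(M)
    diff. <- outer(ts$samp$labels, ts$samp$labels, "!=") & upper.tri(M)
    expect_lt(mean(M[same]), mean(M[diff.]))   # 2-block structure

    # triangle inequality on all frame triples
    for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12)
        expect_lte(M[i, k], M[i, j] + M[j, k] + 1e-9)

    # TM variant: unit diagonal, same-state pairs more similar
    Mt <- pairwiseMatrix(ts$samp$ensemble, "tm")
    expect_identical(unname(diag(Mt)), rep(1, 12))
    expect_gt(mean(Mt[same]), mean(Mt[diff.]))
})

test_that("RMSD-series peaks use the shared detector semantics", {
    expect_identical(nrow(rmsdProfilePeaks(rep(1, 30))), 0L)
    series <- c(rep(1, 20), 1.2, 3, 6, 5.5, 2.5, 1.1, rep(1, 20))
    pk <- rmsdProfilePeaks(series, width = 2, height = 2, prominence = 2)
    expect_identical(nrow(pk), 1L)
    expect_true(pk$start_residue >= 21 && pk$end_residue <= 26)
    expect_identical(nrow(rmsdProfilePeaks(series, height = 100)), 0L)
})

test_that("the states report writes consistent CSV/JSON artefacts", {
    ts <- threeStateSample(43, n = 40L)
    m <- clusterStates(ts$points, k = 3, seed = 1)
    out <- tempfile()
    M <- pairwiseMatrix(ts$samp$ensemble, "rmsd")
    paths <- writeStatesReport(ts$points, m, out, matrices = list(rmsd = M))
    expect_true(all(file.exists(paths)))

    pops <- utils::read.csv(paths[["populations"]])
    expect_equal(sum(pops$population), 100, tolerance = 1e-9)
    back <- utils::read.csv(paths[["points"]])
    expect_equal(back$rmsd_ref1, ts$points$rmsd_ref1, tolerance = 1e-12)
    expect_identical(back$cluster, unname(stateLabels(m)[back$frame_id]))
    js <- jsonlite::read_json(paths[["summary"]], simplifyVector = TRUE)
    expect_identical(js$k, m@k)
    expect_equal(js$populations, populations(m), tolerance = 1e-9)
    Mback <- utils::read.csv(file.path(out, "matrix_rmsd.csv"), row.names = 1)
    expect_equal(as.matrix(Mback), M, tolerance = 1e-12, ignore_attr = TRUE)

    # single-reference mode writes the 1D strip variant without error
    pts1 <- ts$points[, c("frame_id", "rmsd_ref1")]
    m1 <- clusterStates(pts1, k = 2, seed = 1)
    paths1 <- writeStatesReport(pts1, m1, tempfile())
    expect_true(file.exists(paths1[["scatter"]]))
})
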
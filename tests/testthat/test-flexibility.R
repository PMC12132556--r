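test_that("RMSF of identical frames is zero; displaced residue matches closed form", {
    conf <- makeToyConformations(30, 0)$conf1
    ens <- new("Ensemble", frameIds = sprintf("f%d", 1:3),
               coords = array(rep(conf, 3), c(30, 3, 3)),
               residueNumbers = 1:30, residueNames = rep("ALA", 30),
               plddt = matrix(90, 30, 3))
    prof <- computeRMSF(ens)
    expect_equal(max(prof@rmsf), 0, tolerance = 1e-9)
    expect_equal(prof@meanPlddt, rep(90, 30))

    # 2 frames, 50 static residues + 1 displaced +/- d perpendicular:
    # closed form rmsf = d (alignment dominated by the static residues)
    d <- 2.0
    base <- makeToyConformations(51, 0)$conf1
    up <- base; up[25, ] <- up[25, ] + c(0, 0, d)
    dn <- base; dn[25, ] <- dn[25, ] - c(0, 0, d)
    ens2 <- new("Ensemble", frameIds = c("up", "dn"),
                coords = array(c(up, dn), c(51, 3, 2)),
                residueNumbers = 1:51, residueNames = rep("ALA", 51),
                plddt = matrix(90, 51, 2))
    prof2 <- computeRMSF(ens2)
    expect_equal(prof2@rmsf[25], d, tolerance = 0.02)
    expect_lt(max(prof2@rmsf[-25]), 0.1)

    # single frame: all-zero profile with a warning
    one <- new("Ensemble", frameIds = "f1",
               coords = array(conf, c(30, 3, 1)), residueNumbers = 1:30,
               residueNames = rep("ALA", 30), plddt = matrix(80, 30, 1))
    expect_warning(p1 <- computeRMSF(one), "single-frame")
    expect_identical(p1@rmsf, rep(0, 30))
})

test_that("RMSF peaks inside the planted flexible segment", {
    world <- toyWorld(hingeAngles = 0, weights = 1, seed = 11)
    samp <- sampleToyEnsemble(world, 25)
    prof <- computeRMSF(samp$ensemble)
    seg <- world@flexibleSegment
    expect_true(which.max(prof@rmsf) %in% seg)
    # planted pLDDT anticorrelation: low confidence inside the segment
    expect_lt(mean(prof@meanPlddt[seg]), mean(prof@meanPlddt[-seg]))
})

test_that("RMSF is invariant under global rigid motions of all frames", {
    world <- toyWorld(nRes = 40, hingeAngles = 0, weights = 1, seed = 12)
    samp <- sampleToyEnsemble(world, 12)
    prof1 <- computeRMSF(samp$ensemble)
    set.seed(13)
    moved <- samp$ensemble
    for (i in seq_len(nFrames(moved)))
        moved@coords[, , i] <- randomRigidMotion(moved@coords[, , i])
    prof2 <- computeRMSF(moved)
    expect_equal(prof1@rmsf, prof2@rmsf, tolerance = 1e-2)
})

test_that("peak detection honours width, height and prominence thresholds", {
    # flat profile: nothing qualifies
    expect_identical(nrow(detectPeaks(rep(0.5, 40), height = 1)), 0L)

    # single Gaussian bump (apex 3 A over 0.2 baseline, half-width 8)
    x <- 1:60
    bump <- 0.2 + 2.8 * exp(-(x - 30)^2 / (2 * 4^2))
    pk <- detectPeaks(bump, width = 4, height = 1, prominence = 1)
    expect_identical(nrow(pk), 1L)
    expect_true(pk$start_residue <= 30 && pk$end_residue >= 30)
    expect_equal(pk$max_rmsf, max(bump), tolerance = 1e-9)
    # boundaries are the height-threshold crossings around the apex
    above <- which(bump >= 1)
    expect_identical(pk$start_residue, min(above))
    expect_identical(pk$end_residue, max(above))

    # two bumps with a deep valley: two disjoint ranges
    two <- 0.2 + 2.8 * exp(-(x - 15)^2 / 8) + 2.2 * exp(-(x - 45)^2 / 8)
    pk2 <- detectPeaks(two, width = 2, height = 1, prominence = 1)
    expect_identical(nrow(pk2), 2L)
    expect_lt(pk2$end_residue[1], pk2$start_residue[2])

    # thresholds above the series maximum: empty
    expect_identical(nrow(detectPeaks(bump, height = 10)), 0L)

    # every reported range satisfies the asked thresholds (direct scan)
    set.seed(14)
    for (r in 1:20) {
        prof <- pmax(0, stats::filter(rnorm(80), rep(1 / 3, 3),
                                      circular = TRUE)) + 0.1
        prof <- as.numeric(prof)
        pk <- detectPeaks(prof, width = 3, height = 0.8, prominence = 0.3)
        if (nrow(pk) == 0) next
        for (i in seq_len(nrow(pk))) {
            seg <- prof[pk$start_residue[i]:pk$end_residue[i]]
            expect_gte(length(seg), 3L)
            # endpoints above threshold; interior dips are bridged only
            # when shorter than the width threshold
            expect_gte(seg[1], 0.8)
            expect_gte(seg[length(seg)], 0.8)
            dips <- rle(seg < 0.8)
            expect_true(all(dips$lengths[dips$values] < 3L))
            expect_gte(pk$max_rmsf[i], 0.8)
            expect_gte(pk$prominence[i], 0.3)
        }
    }
})

test_that("planted flexible segments are recovered at default thresholds", {
    hits <- 0L
    for (s in 1:50) {
        world <- toyWorld(hingeAngles = 0, weights = 1, seed = 100 + s)
        samp <- sampleToyEnsemble(world, 20)
        pk <- detectPeaks(computeRMSF(samp$ensemble))
        seg <- range(world@flexibleSegment)
        if (nrow(pk) == 1L && pk$start_residue <= seg[2] &&
            pk$end_residue >= seg[1]) hits <- hits + 1L
    }
    expect_identical(hits, 50L)
})

test_that("the condition table and flex report round-trip", {
    world <- toyWorld(nRes = 30, hingeAngles = 0, weights = 1, seed = 15)
    profs <- list(`16:32` = computeRMSF(sampleToyEnsemble(world, 8)$ensemble),
                  `64:128` = computeRMSF(sampleToyEnsemble(world, 8,
                                                           seed = 16)$ensemble))
    tab <- rmsfPlddtTable(profs)
    expect_identical(nrow(tab), 60L)            # 2 conditions x 30 residues
    expect_identical(unique(tab$condition), c("16:32", "64:128"))

    bad <- profs
    bad[[2]]@residueNumbers <- bad[[2]]@residueNumbers + 1L
    expect_error(rmsfPlddtTable(bad), "different residue set")

    out <- tempfile()
    paths <- writeFlexReport(profs, out)
    expect_true(all(file.exists(paths)))
    back <- utils::read.csv(paths[["profile"]])
    expect_equal(back$rmsf, tab$rmsf, tolerance = 1e-12)

    # empty peak table still yields a header-only CSV
    flat <- profs[1]
    flat[[1]]@rmsf <- rep(0.5, 30)
    paths2 <- writeFlexReport(flat, tempfile(), height = 10)
    peaks <- utils::read.csv(paths2[["peaks"]])
    expect_identical(nrow(peaks), 0L)
    expect_true("start_residue" %in% names(peaks))
})
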
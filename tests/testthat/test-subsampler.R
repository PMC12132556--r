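test_that("Hamming distance counts mismatches with gap as a character", {
    expect_identical(hammingDistance("AAAA", "AAAA"), 0L)
    expect_identical(hammingDistance("AAAA", "AAAT"), 1L)
    expect_identical(hammingDistance("AC-G", "ACCG"), 1L)
    expect_error(hammingDistance("AA", "AAA"), "equal length")
})

test_that("clustering always centres the target and assigns by nearest centre", {
    msa <- MSA("q", "AAAA")
    asg <- clusterMSA(msa, 1L)
    expect_identical(asg@centerIndices, 1L)

    set.seed(11)
    for (strategy in c("farthest", "random")) {
        msa <- randomMSA(60L, 25L)
        asg <- clusterMSA(msa, 8L, seed = 1, strategy = strategy)
        expect_identical(asg@centerIndices[1], 1L)
        expect_identical(anyDuplicated(asg@centerIndices), 0L)
        # every row maps to its minimum-distance centre, low index on ties
        expect_identical(asg@membership,
                         bruteAssign(msaRows(msa), asg@centerIndices))
    }
    expect_warning(clusterMSA(randomMSA(5L, 10L), 10L), "clamp")
})

test_that("well-separated families are recovered one centre per family", {
    for (s in 1:20) {
        syn <- makeSyntheticMSA(3L, 20L, 60L, 20L, 2L, seed = s)
        asg <- clusterMSA(syn$msa, 3L, seed = s)
        tab <- table(asg@membership, syn$labels)
        # each family holds exactly one centre and maps wholly onto it
        expect_true(all(rowSums(tab > 0) == 1), info = paste("seed", s))
        expect_true(all(colSums(tab > 0) == 1), info = paste("seed", s))
    }
})

test_that("clustering is deterministic for a fixed seed", {
    syn <- makeSyntheticMSA(3L, 10L, 40L, 15L, 2L, seed = 3)
    a <- clusterMSA(syn$msa, 5L, seed = 42)
    b <- clusterMSA(syn$msa, 5L, seed = 42)
    expect_identical(a@centerIndices, b@centerIndices)
    expect_identical(a@membership, b@membership)
})

test_that("subsampling honours the size, disjointness and target contracts", {
    set.seed(21)
    msa <- randomMSA(1000L, 30L)
    sub <- subsampleMSA(msa, maxSeq = 256L, extraSeq = 512L, seed = 0)
    expect_identical(nSequences(centersMSA(sub)), 256L)
    expect_identical(nSequences(extrasMSA(sub)), 512L)
    expect_identical(msaRows(centersMSA(sub))[1], msaRows(msa)[1])
    expect_length(intersect(msaRows(centersMSA(sub)),
                            msaRows(extrasMSA(sub))), 0L)

    # clamping: small alignment absorbs everything into centres
    small <- randomMSA(10L, 20L)
    w <- capture_warnings(sub <- subsampleMSA(small, maxSeq = 64L,
                                              extraSeq = 128L))
    expect_match(w, "clamped", all = TRUE)
    expect_length(w, 2L)    # both max_seq and extra_seq clamp
    expect_identical(nSequences(centersMSA(sub)), 10L)
    expect_null(extrasMSA(sub))
})

test_that("extras differ across seeds but each seed is reproducible", {
    set.seed(31)
    msa <- randomMSA(1000L, 25L)
    subs <- lapply(0:3, function(s)
        subsampleMSA(msa, maxSeq = 16L, extraSeq = 64L, seed = s))
    # same centre-selection policy, extras differ with probability ~ 1
    extras <- lapply(subs, function(s) msaRows(extrasMSA(s)))
    expect_false(identical(extras[[1]], extras[[2]]))
    expect_false(identical(extras[[2]], extras[[3]]))
    again <- subsampleMSA(msa, maxSeq = 16L, extraSeq = 64L, seed = 1)
    expect_identical(msaRows(extrasMSA(subs[[2]])), msaRows(extrasMSA(again)))
    expect_identical(msaRows(centersMSA(subs[[2]])),
                     msaRows(centersMSA(again)))
})

test_that("round-robin extras draw from every populated cluster first", {
    # 3 families, extras = number of clusters: one extra from each
    syn <- makeSyntheticMSA(3L, 20L, 60L, 20L, 2L, seed = 9)
    sub <- subsampleMSA(syn$msa, maxSeq = 3L, extraSeq = 3L, seed = 0)
    asg <- clusterMSA(dedupMSA(syn$msa), 3L,
                      seed = ConformR:::deriveSeed(3L, 3L, 0L))
    dd <- dedupMSA(syn$msa)
    extraIdx <- match(msaRows(extrasMSA(sub)), msaRows(dd))
    expect_identical(sort(unique(asg@membership[extraIdx])), 1:3)
})

test_that("job emission writes parseable files and a manifest", {
    set.seed(41)
    msa <- randomMSA(200L, 20L)
    out <- tempfile()
    grid <- list(SubsampleParams(16L, 32L, seeds = 0:1),
                 SubsampleParams(32L, 64L, seeds = 0:1),
                 SubsampleParams(64L, 96L, seeds = 0:1))
    manifest <- emitSubsampleJobs(msa, grid, out)
    expect_identical(nrow(manifest), 6L)
    files <- c(manifest$centers_path, manifest$extras_path)
    expect_true(all(file.exists(files)))        # 12 A3M files
    for (p in files) expect_s4_class(readMSA(p), "MSA")
    expect_true(file.exists(file.path(out, "manifest.json")))

    # byte-identical determinism for identical inputs and seed
    out2 <- tempfile()
    emitSubsampleJobs(msa, grid, out2)
    for (i in seq_len(nrow(manifest)))
        expect_identical(readLines(manifest$centers_path[i]),
                         readLines(file.path(out2,
                                             basename(manifest$centers_path[i]))))

    # empty grid -> empty manifest, no alignment files
    out3 <- tempfile()
    m3 <- emitSubsampleJobs(msa, list(), out3)
    expect_identical(nrow(m3), 0L)
    expect_identical(list.files(out3, pattern = "a3m"), character(0))
})
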
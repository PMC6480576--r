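test_that("shape statistics match hand-evaluated worked samples", {
    x <- c(1, 2, 3, 4, 10)
    # sum(d^3) = 180, sum(d^2) = 50, n-1 = 4
    expect_equal(sampleSkewness(x), (180 / 4) / (50 / 4)^1.5,
                 tolerance = 1e-12)
    expect_equal(cyhelskySkew(x), 0.4, tolerance = 1e-12)
    expect_equal(pearsonMedianSkew(x), 3 * (4 - 3) / sqrt(50 / 4),
                 tolerance = 1e-12)

    y <- c(1, 2, 3, 4, 5)  # sum(d^4) = 34, sum(d^2) = 10
    expect_equal(sampleKurtosis(y, excess = TRUE), -1.64, tolerance = 1e-12)
    expect_equal(sampleKurtosis(y, excess = FALSE), 1.36, tolerance = 1e-12)
    expect_equal(sampleSkewness(y), 0, tolerance = 1e-12)
    expect_equal(pearsonMedianSkew(y), 0, tolerance = 1e-12)
    expect_equal(cyhelskySkew(rep(4, 10)), 0)
})

test_that("shape statistics have the expected symmetries", {
    set.seed(11)
    x <- rpois(200, 40)
    expect_equal(sampleSkewness(-x), -sampleSkewness(x), tolerance = 1e-12)
    expect_equal(pearsonMedianSkew(-x), -pearsonMedianSkew(x),
                 tolerance = 1e-12)
    # positive affine rescale leaves all four invariant
    y <- 2.5 * x + 7
    expect_equal(sampleSkewness(y), sampleSkewness(x), tolerance = 1e-10)
    expect_equal(sampleKurtosis(y), sampleKurtosis(x), tolerance = 1e-10)
    expect_equal(cyhelskySkew(y), cyhelskySkew(x))
    expect_equal(pearsonMedianSkew(y), pearsonMedianSkew(x),
                 tolerance = 1e-10)
    # normal limit of the non-excess kurtosis
    z <- rnorm(200000)
    expect_equal(sampleKurtosis(z), 3, tolerance = 0.1)
})

test_that("degenerate samples raise moment errors", {
    expect_error(sampleSkewness(c(5, 5, 5)), "constant")
    expect_error(sampleKurtosis(c(5, 5, 5, 5)), "constant")
    expect_error(sampleSkewness(c(1, 2)), "at least 3")
    expect_error(sampleKurtosis(c(1, 2, 3)), "at least 4")
    expect_error(pearsonMedianSkew(rep(2, 10)), "constant")
})

test_that("all four shape statistics agree with the naive oracle", {
    set.seed(21)
    for (i in 1:50) {
        x <- switch(1 + i %% 3,
                    rpois(sample(10:200, 1), sample(5:80, 1)),
                    rnorm(sample(10:200, 1), 50, 10),
                    round(rexp(sample(10:200, 1), 0.1)) + 1)
        if (sd(x) == 0) next
        expect_equal(sampleSkewness(x), naiveSkewness(x),
                     tolerance = 1e-9)
        expect_equal(sampleKurtosis(x), naiveKurtosis(x),
                     tolerance = 1e-9)
        expect_equal(cyhelskySkew(x), naiveCyhelsky(x), tolerance = 1e-12)
        expect_equal(pearsonMedianSkew(x), naiveMES(x), tolerance = 1e-9)
    }
})

test_that("DTAV is slice area times thickness and matches voxel counting", {
    # 10 voxels at 2 x 2 mm in-plane, 4 mm slices -> 160 mm^3
    g <- array(FALSE, c(5, 5, 2))
    g[cbind(c(1:5, 1:5), c(1:5, 5:1), c(rep(1, 5), rep(2, 5)))] <- TRUE
    expect_equal(dtav(VoxelMask(g, c(2, 2, 4))), 160 / 1000,
                 tolerance = 1e-12)

    set.seed(31)
    for (i in 1:10) {
        flags <- array(runif(6 * 6 * 4) < 0.3, c(6, 6, 4))
        if (!any(flags)) next
        sp <- runif(3, 1, 5)
        m <- VoxelMask(flags, sp)
        expect_equal(dtav(m), sum(flags) * prod(sp) / 1000,
                     tolerance = 1e-12)
    }
    expect_error(dtav(VoxelMask(array(FALSE, c(2, 2, 2)))), "empty")
})

test_that("DTAM offers the count and the slice-volume conventions", {
    a <- array(10, c(4, 4, 3))
    a[2, 2, 2] <- 400
    v <- SpectVolume(a, c(2, 2, 4))
    full <- VoxelMask(array(TRUE, c(4, 4, 3)), c(2, 2, 4))
    expect_equal(dtam(v, full), 400)
    single <- array(FALSE, c(4, 4, 3))
    single[3, 1, 1] <- TRUE
    expect_equal(dtam(v, VoxelMask(single, c(2, 2, 4))), 10)

    set.seed(41)
    flags <- array(runif(4 * 4 * 3) < 0.5, c(4, 4, 3))
    flags[1, 1, 1] <- TRUE
    m <- VoxelMask(flags, c(2, 2, 4))
    bySlice <- max(vapply(1:3, function(k) sum(flags[, , k]), 0L))
    expect_equal(dtam(v, m, mode = "max_slice_volume"),
                 bySlice * 2 * 2 * 4 / 1000, tolerance = 1e-12)
    expect_error(dtam(v, VoxelMask(array(FALSE, c(4, 4, 3)), c(2, 2, 4))),
                 "empty")
})

test_that("computeFeatures is deterministic and fails on an empty brain mask", {
    p <- smallParams()
    lv <- generatePhantom("mild", p, seed = 6)
    f1 <- computeFeatures(lv)
    f2 <- computeFeatures(lv)
    expect_identical(f1, f2)
    expect_named(f1, c("SK", "KUR", "CSK", "MES", "DTAV", "DTAM"))
    expect_error(computeFeatures(lv, pipelineConfig(threshold = 1e6)),
                 "1e\\+06|threshold")
})

test_that("flat striatum degenerates to the whole-brain region", {
    p <- smallParams(noise = FALSE, subjectCV = 0, intensityCV = 0,
                     blurSigma = 0, backgroundGradient = 0,
                     backgroundMean = 200, interiorValue = 200,
                     striatalPeak = c(healthy = 200, mild = 200,
                                      severe = 200))
    lv <- generatePhantom("healthy", p, seed = 2)
    region <- growStriatum(lv@volume)
    brain <- thresholdMask(lv@volume, 15)
    expect_equal(dtav(region), maskVolume(brain), tolerance = 1e-12)
})

test_that("extractFeatures assembles a SummarizedExperiment with stage labels", {
    p <- smallParams()
    cohort <- generateCohort(c(2, 2, 2), p, seed = 13)
    se <- extractFeatures(cohort)
    expect_s4_class(se, "SummarizedExperiment")
    expect_equal(dim(se), c(6L, 6L))
    ff <- featureFrame(se)
    expect_equal(levels(ff$stage), c("healthy", "mild", "severe"))
    expect_true(all(c("SK", "KUR", "CSK", "MES", "DTAV", "DTAM") %in%
                    names(ff)))
    expect_true(all(ff$DTAV > 0))

    # manifest-driven extraction gives the same numbers
    d <- withr::local_tempdir()
    man <- simulateToDisk(c(1, 1, 0), p, seed = 13, outDir = d)
    df <- readManifest(man)
    se2 <- extractFeatures(df)
    expect_equal(dim(se2), c(6L, 2L))
    missing <- df
    missing$path[1] <- file.path(d, "gone.nii.gz")
    expect_error(extractFeatures(missing), "missing for subject")
})
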
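test_that("reference model is the normalized per-bin median", {
    ## single normal: reference equals its normalized depths
    d <- c(100, 200, 300, 400)
    ref <- buildReference(d)
    expect_equal(ref$location, d / mean(d))
    ## three normals with constant profiles scaled to mean 1 first;
    ## per-bin median of the normalized columns
    m <- cbind(c(10, 10), c(20, 20), c(90, 90))
    ref3 <- buildReference(m)
    expect_equal(ref3$location, c(1, 1))  # each column normalizes to 1
    ## unequal bins: median across samples after normalization
    m2 <- cbind(c(10, 30), c(20, 20), c(90, 10))
    expect_equal(buildReference(m2)$location[1],
                 median(c(10 / 20, 20 / 20, 90 / 50)))
    ## all-zero bin flagged unreliable
    m3 <- cbind(c(0, 100), c(0, 120))
    expect_true(buildReference(m3)$unreliable[1])
    expect_false(buildReference(m3)$unreliable[2])
    expect_error(buildReference(cbind(c(0, 0))), "all-zero")
})

test_that("log2 ratios are median-centered against the reference", {
    ref <- buildReference(cbind(c(100, 100, 100, 100)))
    expect_equal(log2Ratios(c(50, 50, 50, 50), ref), rep(0, 4))   # identity
    expect_equal(log2Ratios(c(200, 200, 200, 200), ref), rep(0, 4)) # 2x scaled
    ## one bin at 2x against a flat sample reads ~ +1
    lr <- log2Ratios(c(100, 100, 100, 200), ref)
    expect_equal(lr[4] - median(lr[1:3]), 1, tolerance = 1e-9)
    expect_error(log2Ratios(c(1, 2), ref), "different bin grids")
})

test_that("unreliable bins propagate as NA and zero reliable bins error", {
    ref <- buildReference(cbind(c(0, 100, 100)))
    expect_true(is.na(log2Ratios(c(10, 100, 100), ref)[1]))
    ref2 <- list(location = c(0, 1), spread = c(0, 0),
                 unreliable = c(FALSE, FALSE))
    expect_error(log2Ratios(c(10, 10), ref2), "zero reference")
})

test_that("copy-number estimation follows the admixture inversion", {
    expect_identical(estimateCopies(0), 2L)
    expect_identical(estimateCopies(1), 4L)
    expect_identical(estimateCopies(-1, purity = 0.5), 0L)
    ## half-copy boundary rounds away from zero: 2*2^log2(1.25) = 2.5 -> 3
    expect_identical(estimateCopies(log2(1.25)), 3L)
    expect_error(estimateCopies(0, purity = 0), "purity")
    ## purity inversion recovers truth over a grid (log2 floored at -8,
    ## the same clamp the simulator applies to homozygous deletions)
    for (tc in 0:8) for (p in c(0.4, 0.7, 1)) {
        lr <- max(log2(max((p * tc + (1 - p) * 2) / 2, 2^-8)), -8)
        expect_identical(estimateCopies(lr, purity = p), as.integer(tc))
    }
})

test_that("copy states classify and stay monotone", {
    expect_identical(classifyCopyState(c(0L, 1L, 2L, 3L, 4L, 5L, 12L)),
                     c("deep_deletion", "shallow_deletion", "neutral",
                       "gain", "gain", "amplification", "amplification"))
    ord <- match(classifyCopyState(0:20), copyStates())
    expect_true(all(diff(ord) >= 0))
    ## configurable thresholds
    th <- copyStateThresholds(gainMin = 4L, ampMin = 6L)
    expect_identical(classifyCopyState(3L, th), "neutral")
    expect_identical(classifyCopyState(5L, th), "gain")
    expect_error(copyStateThresholds(gainMin = 2L))
})

test_that("segments partition the series and preserve the mean", {
    set.seed(13)
    bins <- panelBins(defaultPanel(), 400L)
    values <- rnorm(length(bins), 0, 0.2) +
        rep(c(0, 1), length.out = length(bins) %/% 40 + 1)[
            ceiling(seq_along(bins) / 40)]
    segs <- segmentCoverage(bins, values, nPerm = 200L, seed = 5)
    m <- S4Vectors::mcols(segs)
    expect_equal(sum(m$nBins), length(bins))
    expect_equal(sum(m$meanLog2 * m$nBins) / sum(m$nBins), mean(values),
                 tolerance = 1e-9)
    ## segments within a chromosome are ordered and non-overlapping
    expect_equal(length(GenomicRanges::findOverlaps(
        segs, drop.self = TRUE, drop.redundant = TRUE)), 0L)
})

test_that("recentering shifts means and is idempotent in auto mode", {
    bins <- panelBins(defaultPanel(), 400L)
    values <- rep(0.3, length(bins))          # whole genome drifted +0.3
    segs <- segmentCoverage(bins, values, nPerm = 100L)
    same <- recenterSegments(segs, shift = 0)
    expect_equal(S4Vectors::mcols(same)$meanLog2,
                 S4Vectors::mcols(segs)$meanLog2)
    auto <- recenterSegments(segs, shift = "auto")
    expect_equal(S4Vectors::mcols(auto)$meanLog2, rep(0, length(segs)))
    expect_true(all(S4Vectors::mcols(auto)$state == "neutral"))
    twice <- recenterSegments(auto, shift = "auto")
    expect_equal(S4Vectors::mcols(twice)$meanLog2,
                 S4Vectors::mcols(auto)$meanLog2)
})

test_that("noise-free synthetic coverage recovers true copy numbers", {
    cfg <- simConfig(nSamples = 2, nPaired = 0, depthDispersion = 0,
                     log2NoiseSd = 0, purityRange = c(1, 1), seed = 31)
    co <- generateCohort(cfg)
    se <- cohortCoverage(co)
    bins <- SummarizedExperiment::rowRanges(se)
    for (i in 1:2) {
        tr <- cohortTruth(co)[[i]]
        segs <- segmentCoverage(bins,
                                SummarizedExperiment::assay(se, "log2ratio")[, i],
                                purity = 1, nPerm = 500L, seed = i)
        got <- geneCopyState(segs, panelTargets(co@panel))
        segsT <- truthSegments(tr)
        want <- S4Vectors::mcols(segsT)$totalCopies[
            match(got$gene, S4Vectors::mcols(segsT)$gene)]
        expect_identical(got$copyNumber, as.integer(want))
    }
})
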
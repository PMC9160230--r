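test_that("expectedVaf evaluates the admixture model and its limits", {
    expect_equal(expectedVaf(1, 2, 1, 1), 0.5)     # balanced heterozygote
    expect_equal(expectedVaf(1, 2, 2, 1), 1.0)     # CN-LOH keeping the alt
    expect_equal(expectedVaf(0.5, 1, 1, 0), 1 / 3) # hemizygous somatic
    ## at purity 0 only the normal compartment is seen
    expect_equal(expectedVaf(0, 4, 3, 0), 0)
    expect_equal(expectedVaf(0, 4, 3, 1), 0.5)
    ## degenerate locus: purity 1, zero copies
    expect_error(expectedVaf(1, 0, 0, 0), "degenerate")
    expect_error(expectedVaf(1, 2, 3, 1))  # multiplicity > totalCopies
})

test_that("expectedVaf is monotone non-decreasing in multiplicity", {
    set.seed(11)
    for (r in 1:50) {
        p <- runif(1); ct <- pick(1:8); g <- pick(0:1)
        v <- expectedVaf(p, ct, 0:ct, g)
        expect_true(all(diff(v) >= -1e-12))
    }
})

test_that("binomial VAF sampling is unbiased at depth 100", {
    set.seed(5)
    draws <- rbinom(10000, 100, expectedVaf(1, 2, 1, 1)) / 100
    se <- sqrt(0.5 * 0.5 / 100) / sqrt(10000)
    expect_lt(abs(mean(draws) - 0.5), 3 * se)
})

test_that("the noise-free limit reproduces truth exactly", {
    cfg <- simConfig(nSamples = 3, nPaired = 1, depthDispersion = 0,
                     log2NoiseSd = 0, purityRange = c(1, 1), seed = 3)
    co <- generateCohort(cfg)
    se <- cohortCoverage(co)
    bins <- SummarizedExperiment::rowRanges(se)
    for (i in 1:3) {
        tr <- cohortTruth(co)[[i]]
        segs <- truthSegments(tr)
        tc <- S4Vectors::mcols(segs)$totalCopies[
            match(S4Vectors::mcols(bins)$gene,
                  S4Vectors::mcols(segs)$gene)]
        expected <- pmax(log2(pmax(tc / 2, 2^-8)), -8)
        expect_equal(unname(SummarizedExperiment::assay(se, "log2ratio")[, i]),
                     expected)
    }
})

test_that("identical seeds give identical cohorts", {
    cfg <- simConfig(nSamples = 3, nPaired = 1, seed = 21)
    a <- generateCohort(cfg); b <- generateCohort(cfg)
    expect_identical(tumorVariants(a), tumorVariants(b))
    expect_identical(normalVariants(a), normalVariants(b))
    expect_identical(SummarizedExperiment::assay(cohortCoverage(a), "depth"),
                     SummarizedExperiment::assay(cohortCoverage(b), "depth"))
    expect_identical(lapply(cohortTruth(a), truthSegments),
                     lapply(cohortTruth(b), truthSegments))
})

test_that("germline het deviations vanish with depth in balanced regions", {
    ## depth 10,000, binomial sampling only (no depth overdispersion)
    cfg <- simConfig(nSamples = 2, nPaired = 0, meanDepth = 10000,
                     depthDispersion = 0, log2NoiseSd = 0.15,
                     purityRange = c(1, 1), seed = 9)
    co <- generateCohort(cfg)
    tv <- tumorVariants(co)
    ta <- truthAlterations(cohortTruth(co))
    for (s in unique(tv$sampleId)) {
        ## balanced diploid genes in this sample only
        bal <- ta$gene[ta$sampleId == s & ta$totalCopies == 2 &
                       ta$minorCopies == 1]
        v <- tv[tv$sampleId == s & tv$gene %in% bal &
                tv$populationAf > 0.001, ]
        expect_lt(mean(abs(v$vaf - 0.5)), 0.01)
    }
})

test_that("noise-free CN-LOH is copy neutral with deviations 0.5 at purity 1", {
    expect_equal(log2((1 * 2 + 0 * 2) / 2), 0)
    expect_equal(abs(expectedVaf(1, 2, 2, 1) - 0.5), 0.5)
    expect_equal(abs(expectedVaf(1, 2, 0, 1) - 0.5), 0.5)
})

test_that("default configuration echoes the cohort design", {
    cfg <- simConfig()
    expect_equal(cfg@nSamples, 48L)
    expect_equal(cfg@nPaired, 13L)
    co <- generateCohort(simConfig(seed = 15))
    expect_length(cohortTruth(co), 48L)
    expect_equal(sum(vapply(cohortTruth(co),
                            function(t) t@hasMatchedNormal, logical(1))),
                 13L)
})

test_that("truth serialization round trips", {
    co <- generateCohort(simConfig(nSamples = 2, nPaired = 1, seed = 4))
    path <- tempfile(fileext = ".json")
    writeTruth(cohortTruth(co), path)
    back <- readTruth(path)
    expect_length(back, 2L)
    for (i in 1:2) {
        expect_equal(purity(back[[i]]), purity(cohortTruth(co)[[i]]))
        expect_equal(truthSegments(back[[i]]),
                     truthSegments(cohortTruth(co)[[i]]))
        expect_equal(truthVariants(back[[i]]),
                     truthVariants(cohortTruth(co)[[i]]))
    }
    ## empty variant list still serializes
    t0 <- cohortTruth(co)[[1]]
    t0@variants <- GenomicRanges::GRanges()
    writeTruth(list(t0), path)
    expect_length(truthVariants(readTruth(path)[[1]]), 0L)
    expect_error(writeTruth(list(), path), "non-empty")
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(nPaired = 10, nSamples = 5), "nPaired")
    expect_error(simConfig(meanDepth = -1))
    expect_error(simConfig(purityRange = c(0.9, 0.6)))
    bad <- defaultDriverTable(); bad$none[1] <- 2
    expect_error(simConfig(driverTable = bad), "sum to 1")
})

test_that("panel bins tile targets without overlap and keep genes", {
    bins <- panelBins(defaultPanel(), 400L)
    expect_s4_class(bins, "GRanges")
    expect_equal(length(GenomicRanges::findOverlaps(
        bins, drop.self = TRUE, drop.redundant = TRUE)), 0L)
    expect_setequal(unique(S4Vectors::mcols(bins)$gene),
                    panelGenes(defaultPanel()))
})
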
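test_that("informative-SNP selection applies the frequency/depth filters", {
    v <- variantTable(
        variantRow(pos = 1100, populationAf = 0.2, depth = 100, altCount = 45),
        variantRow(pos = 1200, populationAf = 0.2, depth = 30, altCount = 14),
        variantRow(pos = 1300, populationAf = 1e-4, depth = 100, altCount = 50),
        variantRow(pos = 1400, populationAf = 0.96, depth = 100, altCount = 50),
        variantRow(pos = 1500, populationAf = 0.2, depth = 100, altCount = 99),
        variantRow(pos = 1600, populationAf = 0.2, depth = 100, altCount = 2))
    kept <- selectInformative(v)
    ## depth must strictly exceed 30; AF bounds and hom cutoffs are open
    expect_identical(kept$pos, 1100L)
    expect_equal(kept$deviation, abs(0.45 - 0.5))
    ## disabling homozygous exclusion keeps the VAF ~ 1 variant
    kept2 <- selectInformative(v, homCutoffs = NULL)
    expect_setequal(kept2$pos, c(1100L, 1500L, 1600L))
})

test_that("deviation is symmetric under allele swap", {
    expect_equal(deviationSeries(0.5), 0)
    expect_equal(deviationSeries(0.2), deviationSeries(0.8))
    expect_equal(deviationSeries(1.0), 0.5)
    set.seed(3); v <- runif(100)
    expect_equal(deviationSeries(v), deviationSeries(1 - v))
})

test_that("segment imbalance follows the 0.15 mean-deviation rule", {
    set.seed(8)
    flat <- data.frame(chrom = "chr1", pos = seq(1000, by = 500, length.out = 40),
                       deviation = abs(rnorm(40, 0.02, 0.005)))
    seg <- callImbalance(flat, nPerm = 200L)
    expect_equal(nrow(seg), 1L)
    expect_false(seg$imbalance)
    high <- flat; high$deviation <- abs(rnorm(40, 0.30, 0.01))
    seg2 <- callImbalance(high, nPerm = 200L)
    expect_equal(nrow(seg2), 1L)
    expect_true(seg2$imbalance)
})

test_that("a noise-free CN-LOH region is recovered at variant resolution", {
    pos <- seq(1000, by = 1000, length.out = 60)
    dev <- c(rep(0, 20), rep(0.5, 20), rep(0, 20))
    hets <- data.frame(chrom = "chr5", pos = pos, deviation = dev)
    seg <- callImbalance(hets, nPerm = 500L)
    expect_equal(nrow(seg), 3L)
    expect_identical(seg$imbalance, c(FALSE, TRUE, FALSE))
    expect_equal(seg$start[2], pos[21])
    expect_equal(seg$end[2], pos[40])
})

test_that("chromosomes with too few variants yield one low-confidence segment", {
    hets <- data.frame(chrom = "chr9", pos = c(100, 200),
                       deviation = c(0.4, 0.45))
    seg <- callImbalance(hets)
    expect_equal(nrow(seg), 1L)
    expect_true(seg$lowConfidence)
})

test_that("paired shifts measure tumor-normal VAF movement", {
    devSeg <- data.frame(chrom = "chr1", start = 1000L, end = 3000L,
                         nVariants = 3L, meanDeviation = 0.4,
                         imbalance = TRUE, lowConfidence = FALSE)
    nv <- variantTable(
        variantRow(pos = 1000, altCount = 50),
        variantRow(pos = 2000, altCount = 50),
        variantRow(pos = 3000, altCount = 50))
    tvSame <- nv
    res <- pairedShift(nv, tvSame, devSeg)
    expect_equal(res$shifts$shift, rep(0, 3))
    expect_false(res$segments$pairedSupport[1])
    tvShift <- variantTable(
        variantRow(pos = 1000, altCount = 90),
        variantRow(pos = 2000, altCount = 90),
        variantRow(pos = 3000, altCount = 90))
    res2 <- pairedShift(nv, tvShift, devSeg)
    expect_equal(res2$shifts$shift, rep(0.4, 3))
    expect_true(res2$segments$pairedSupport[1])
    ## no shared heterozygous loci: support absent
    res3 <- pairedShift(nv[0, ], tvShift, devSeg)
    expect_true(is.na(res3$segments$pairedSupport[1]))
})

test_that("LOH mechanism classification follows the copy-number rule table", {
    dev <- data.frame(chrom = rep("chr1", 4),
                      start = c(1, 1001, 2001, 3001),
                      end = c(1000, 2000, 3000, 4000),
                      nVariants = 10L,
                      meanDeviation = c(0.4, 0.4, 0.4, 0.02),
                      imbalance = c(TRUE, TRUE, TRUE, FALSE),
                      lowConfidence = FALSE)
    cn <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 1001, 2001, 3001), c(1000, 2000, 3000, 4000)),
        nBins = 10L, meanLog2 = 0,
        copyNumber = c(2L, 1L, 4L, 1L), state = "neutral")
    calls <- classifyLoh(dev, cn)
    expect_identical(calls$mechanism,
                     c("cnloh", "deletion_loh", "imbalanced_gain", "none"))
    ## imbalance without copy-number information
    calls2 <- classifyLoh(dev[1, ], cn[0])
    expect_identical(calls2$mechanism, "imbalance_unknown_cn")
})

test_that("paired mode only adds support, never changes imbalance flags", {
    cfg <- simConfig(nSamples = 1, nPaired = 1, seed = 77)
    co <- generateCohort(cfg)
    tv <- tumorVariants(co)
    nv <- normalVariants(co)
    hets <- selectInformative(tv)
    tumorOnly <- callImbalance(hets, nPerm = 300L, seed = 2)
    paired <- pairedShift(nv, tv, tumorOnly)$segments
    expect_identical(tumorOnly$imbalance, paired$imbalance)
    expect_identical(tumorOnly[names(tumorOnly)], paired[names(tumorOnly)])
})

test_that("CN-LOH detectability scales with purity as the model predicts", {
    ## expected deviation at CN-LOH is purity/2; the 0.15 rule needs p >= 0.3
    expect_equal(abs(expectedVaf(0.5, 2, 2, 1) - 0.5), 0.25)
    expect_equal(abs(expectedVaf(0.2, 2, 2, 1) - 0.5), 0.10)
    simulateEvent <- function(p, seed) {
        set.seed(seed)
        n <- 22
        mult <- sample(c(0L, 2L), n, replace = TRUE)
        ev <- expectedVaf(p, 2, mult, 1)
        vaf <- rbinom(n, 150, ev) / 150
        flank <- rbinom(40, 150, 0.5) / 150
        hets <- data.frame(chrom = "chr1",
                           pos = seq(1000, by = 500, length.out = n + 40),
                           deviation = abs(c(flank[1:20], vaf, flank[21:40]) - 0.5))
        seg <- callImbalance(hets, nPerm = 300L, seed = seed)
        any(seg$imbalance & seg$start <= 1000 + 500 * (n + 19) &
            seg$end >= 1000 + 500 * 20)
    }
    det50 <- mean(vapply(1:30, function(s) simulateEvent(0.5, s), logical(1)))
    det20 <- mean(vapply(1:30, function(s) simulateEvent(0.2, s), logical(1)))
    expect_gt(det50, 0.9)
    expect_lt(det20, 0.2)
})
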
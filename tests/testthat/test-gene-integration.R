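test_that("multiplicity inverts the admixture VAF model", {
    expect_equal(multiplicityEstimate(0.5, 2, 1), 1)
    expect_equal(multiplicityEstimate(1.0, 2, 1), 2)
    expect_equal(multiplicityEstimate(0.25, 4, 0.5), 1.5)
    expect_error(multiplicityEstimate(0.5, 2, 0), "purity")
})

test_that("mechanism priority resolves the canonical cases", {
    r <- integrateGeneSample(1, 2L, "neutral", "cnloh", vaf = 0.9, purity = 1)
    expect_identical(r$label, "mutation_plus_cnloh"); expect_true(r$biallelic)
    r <- integrateGeneSample(0, 0L, "deep_deletion")
    expect_identical(r$label, "deep_deletion"); expect_true(r$biallelic)
    r <- integrateGeneSample(2, 2L, "neutral")
    expect_identical(r$label, "multiple_mutations"); expect_true(r$biallelic)
    r <- integrateGeneSample(1, 1L, "shallow_deletion", "deletion_loh",
                             vaf = 0.9, purity = 1)
    expect_identical(r$label, "mutation_plus_deletion"); expect_true(r$biallelic)
    ## vaf 0.9 at CN 3, purity 1 -> multiplicity 2.7 -> amplified mutant allele
    r <- integrateGeneSample(1, 3L, "gain", "none", vaf = 0.9, purity = 1)
    expect_identical(r$label, "mutant_allele_amplified"); expect_true(r$biallelic)
    ## unknown purity downgrades the same call to putative
    r <- integrateGeneSample(1, 3L, "gain", "none", vaf = 0.9)
    expect_identical(r$label, "mutant_allele_amplified"); expect_true(r$putative)
    r <- integrateGeneSample(0, 7L, "amplification")
    expect_identical(r$label, "amplification"); expect_false(r$biallelic)
    r <- integrateGeneSample(1, 2L, "neutral", "none", vaf = 0.4, purity = 1)
    expect_identical(r$label, "single_hit"); expect_false(r$biallelic)
    expect_identical(integrateGeneSample(0, 2L, "neutral")$label, "none")
    ## shallow deletion alone is a copy-only call, not biallelic
    expect_identical(integrateGeneSample(0, 1L, "shallow_deletion")$label,
                     "none")
})

test_that("every input combination yields exactly one valid label", {
    states <- copyStates()
    mechs <- c("none", "cnloh", "deletion_loh", "imbalanced_gain",
               "imbalance_unknown_cn")
    for (nMut in 0:3) for (st in states) for (mech in mechs) {
        cn <- switch(st, deep_deletion = 0L, shallow_deletion = 1L,
                     neutral = 2L, gain = 3L, amplification = 6L)
        r <- integrateGeneSample(nMut, cn, st, mech, vaf = 0.5, purity = 0.8)
        expect_true(r$label %in% mechanismLabels())
        expect_identical(r$biallelic, r$label %in% c(
            "multiple_mutations", "mutation_plus_deletion",
            "mutation_plus_cnloh", "mutant_allele_amplified",
            "deep_deletion"))
    }
})

test_that("removing LOH evidence can only demote labels", {
    rank <- c(none = 0, single_hit = 1, amplification = 1,
              mutant_allele_amplified = 2, mutation_plus_cnloh = 2,
              mutation_plus_deletion = 2, multiple_mutations = 2,
              deep_deletion = 2)
    for (st in copyStates()) for (mech in c("cnloh", "deletion_loh")) {
        cn <- switch(st, deep_deletion = 0L, shallow_deletion = 1L,
                     neutral = 2L, gain = 3L, amplification = 6L)
        with_loh <- integrateGeneSample(1, cn, st, mech, vaf = 0.4,
                                        purity = 0.8)$label
        without <- integrateGeneSample(1, cn, st, "none", vaf = 0.4,
                                       purity = 0.8)$label
        expect_lte(rank[[without]], rank[[with_loh]])
    }
})

test_that("deep deletion with a confident mutation is flagged inconsistent", {
    r <- integrateGeneSample(1, 0L, "deep_deletion", vaf = 0.5, depth = 200)
    expect_identical(r$label, "deep_deletion")
    expect_true(r$inconsistent)
})

test_that("gene copy state takes the bin-weighted majority across segments", {
    genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000),
                                    gene = "G")
    segs <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 7001), c(7000, 10000)),
        nBins = c(18L, 8L), meanLog2 = c(0, -1),
        copyNumber = c(2L, 1L), state = c("neutral", "shallow_deletion"))
    cs <- geneCopyState(segs, genes)
    expect_identical(cs$copyNumber, 2L)  # 7000 bp of CN 2 vs 3000 of CN 1
})

test_that("the cohort matrix tabulates labels and frequencies", {
    alt <- expand.grid(gene = c("TP53", "FAT1"),
                       sampleId = sprintf("S%02d", 1:48),
                       stringsAsFactors = FALSE)
    alt$label <- "none"; alt$biallelic <- FALSE
    alt$label[alt$gene == "TP53" & alt$sampleId %in% sprintf("S%02d", 1:10)] <-
        "multiple_mutations"
    alt$biallelic <- alt$label != "none"
    m <- buildMatrix(alt)
    expect_s4_class(m, "CohortMatrix")
    expect_equal(unname(alterationFrequency(m)["TP53"]), 10 / 48)
    expect_equal(unname(alterationFrequency(m)["FAT1"]), 0)
    expect_error(buildMatrix(alt[0, ]), "empty")
    expect_error(buildMatrix(rbind(alt, alt[1, ])), "duplicate")
})
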
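test_that("exact test evaluates the probability-mass two-sided rule", {
    expect_equal(fisherExactP(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
    expect_equal(fisherExactP(0, 10, 0, 10), 1)
    expect_error(fisherExactP(0, 0, 1, 1), "zero-size cohort")
    ## swapping the cohorts leaves p unchanged
    set.seed(31)
    for (r in 1:40) {
        a <- pick(0:12); b <- pick(1:12); c <- pick(0:12); d <- pick(1:12)
        expect_equal(fisherExactP(a, b, c, d), fisherExactP(c, d, a, b),
                     tolerance = 1e-12)
    }
})

test_that("exact test agrees with enumeration and fisher.test", {
    set.seed(17)
    for (r in 1:150) {
        a <- pick(0:15); b <- pick(0:15); c <- pick(0:15); d <- pick(0:15)
        if (a + b == 0 || c + d == 0) next
        p <- fisherExactP(a, b, c, d)
        expect_equal(p, enumFisherOracle(a, b, c, d), tolerance = 1e-12)
        expect_equal(p, fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                     tolerance = 1e-9)
    }
})

test_that("conditional MLE odds ratio matches its grid-search oracle", {
    expect_equal(conditionalMleOr(0, 5, 3, 2), 0)       # zero first cell
    expect_identical(conditionalMleOr(4, 1, 0, 5), Inf) # zero second cell
    expect_equal(conditionalMleOr(5, 5, 5, 5), 1)       # balanced table
    expect_true(is.na(conditionalMleOr(0, 5, 0, 5)))    # degenerate margins
    set.seed(29)
    for (r in 1:60) {
        a <- pick(0:15); b <- pick(0:15); c <- pick(0:15); d <- pick(0:15)
        if (a + b == 0 || c + d == 0) next
        got <- conditionalMleOr(a, b, c, d)
        want <- gridMleOracle(a, b, c, d)
        if (is.na(want)) expect_true(is.na(got))
        else if (!is.finite(want)) expect_identical(got, want)
        else expect_equal(got, want, tolerance = 1e-6)
    }
})

test_that("exact CI inverts the tail tests and brackets the MLE", {
    set.seed(37)
    for (r in 1:60) {
        a <- pick(0:15); b <- pick(0:15); c <- pick(0:15); d <- pick(0:15)
        if (a + b == 0 || c + d == 0) next
        ci <- exactCiOr(a, b, c, d)
        want <- bisectCiOracle(a, b, c, d)
        for (k in 1:2) {
            if (!is.finite(want[k])) expect_identical(ci[k], want[k])
            else expect_equal(ci[k], want[k],
                              tolerance = max(1e-6, 1e-6 * abs(want[k])))
        }
        or <- conditionalMleOr(a, b, c, d)
        if (!is.na(or)) {
            expect_lte(ci[1], or + 1e-12)
            expect_gte(ci[2], or - 1e-12)
        }
    }
    ## zero-cell conventions: 0 lower bound, as for absent mutations
    expect_equal(exactCiOr(0, 10, 4, 6)[1], 0)
    expect_identical(exactCiOr(6, 0, 4, 6)[2], Inf)
})

test_that("cohort swap inverts the odds ratio and mirrors the CI", {
    set.seed(41)
    for (r in 1:30) {
        a <- pick(1:12); b <- pick(1:12); c <- pick(1:12); d <- pick(1:12)
        or1 <- conditionalMleOr(a, b, c, d)
        or2 <- conditionalMleOr(c, d, a, b)
        expect_equal(or1, 1 / or2, tolerance = 1e-8)
        ci1 <- exactCiOr(a, b, c, d); ci2 <- exactCiOr(c, d, a, b)
        expect_equal(ci1, rev(1 / ci2), tolerance = 1e-6)
    }
})

test_that("cohort comparison assembles sorted, BH-adjusted results", {
    c1 <- data.frame(gene = c("CASP8", "HRAS", "TP53"),
                     mutated = c(0L, 0L, 30L), total = 67L)
    c2 <- data.frame(gene = c("CASP8", "HRAS", "TP53", "EXTRA"),
                     mutated = c(55L, 30L, 270L, 5L),
                     total = c(595L, 595L, 595L, 100L))
    c1 <- c1[c1$gene != "EXTRA", ]
    expect_warning(res <- compareCohorts(c1, c2,
                                         genes = c("CASP8", "HRAS", "TP53",
                                                   "EXTRA")),
                   "dropped: EXTRA")
    expect_equal(nrow(res), 3L)
    expect_true(!is.unsorted(res$pValue))
    expect_true(all(res$adjustedP >= res$pValue - 1e-15))
    ## genes absent in cohort 1 have conditional-MLE OR 0 and CI from 0
    expect_equal(res$oddsRatio[res$gene == "CASP8"], 0)
    expect_equal(res$ciLow[res$gene == "CASP8"], 0)
    ## identical cohorts give p = 1 everywhere
    same <- compareCohorts(c1, c1)
    expect_true(all(same$pValue == 1))
    expect_error(compareCohorts(c1, data.frame(gene = "ZZZ", mutated = 0L,
                                               total = 10L)),
                 "empty gene intersection")
})

test_that("comparison accepts cohort matrices and counts mutations only", {
    alt <- expand.grid(gene = c("TP53", "CCND1"),
                       sampleId = sprintf("S%d", 1:10),
                       stringsAsFactors = FALSE)
    alt$label <- "none"; alt$biallelic <- FALSE
    alt$label[alt$gene == "TP53" & alt$sampleId %in% sprintf("S%d", 1:4)] <-
        "single_hit"
    ## copy-only amplifications never count as mutated
    alt$label[alt$gene == "CCND1"] <- "amplification"
    m <- buildMatrix(alt)
    counts <- geneMutationCounts(m)
    expect_equal(counts$mutated[counts$gene == "TP53"], 4L)
    expect_equal(counts$mutated[counts$gene == "CCND1"], 0L)
    res <- compareCohorts(m, m)
    expect_true(all(res$pValue == 1))
})
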
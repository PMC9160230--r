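## Two-cohort per-gene mutation-frequency comparison: exact hypergeometric
## test, conditional-MLE odds ratio, exact confidence interval and
## Benjamini-Hochberg adjustment.

.tableMargins <- function(a, b, c, d) {
    stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
    n1 <- a + b; n2 <- c + d; k <- a + c
    if (n1 == 0 || n2 == 0) stop("zero-size cohort")
    list(n1 = n1, n2 = n2, k = k,
         lo = max(0, k - n2), hi = min(k, n1))
}

#' Two-sided exact test for a 2x2 table
#'
#' Conditional on both margins, the p-value is the sum of hypergeometric
#' probabilities of all tables whose probability does not exceed that of
#' the observed table (the probability-mass two-sided rule used by standard
#' exact-test software).
#'
#' @param a,b,c,d Cell counts: mutated/unmutated in cohort 1, then cohort 2.
#' @return Two-sided p-value in (0, 1\].
#' @examples
#' fisherExactP(3, 1, 1, 3)  # 34/70
#' @export
fisherExactP <- function(a, b, c, d) {
    m <- .tableMargins(a, b, c, d)
    x <- m$lo:m$hi
    px <- dhyper(x, m$n1, m$n2, m$k)
    pobs <- px[match(a, x)]
    p <- min(1, sum(px[px <= pobs * (1 + 1e-7)]))
    if (p > 1 - 1e-12) p <- 1
    p
}

## normalized noncentral hypergeometric weights at log-odds t
.nchgWeights <- function(m, t) {
    x <- m$lo:m$hi
    lw <- lchoose(m$n1, x) + lchoose(m$n2, m$k - x) + x * t
    w <- exp(lw - max(lw))
    list(x = x, w = w / sum(w))
}

#' Conditional maximum-likelihood odds ratio
#'
#' The odds ratio maximizing the noncentral hypergeometric likelihood of
#' the observed table conditional on its margins, i.e. the value whose
#' conditional expectation of the first cell equals the observed count.  At
#' the support boundary the estimate degenerates: `a` at its minimum gives
#' 0, at its maximum gives `Inf`.  Degenerate margins (no mutated or no
#' unmutated samples overall) are not estimable and give `NA`.
#'
#' @inheritParams fisherExactP
#' @return The conditional MLE odds ratio.
#' @export
conditionalMleOr <- function(a, b, c, d) {
    m <- .tableMargins(a, b, c, d)
    if (m$lo == m$hi) return(NA_real_)
    if (a == m$lo) return(0)
    if (a == m$hi) return(Inf)
    f <- function(t) sum(.nchgWeights(m, t)$w * (m$lo:m$hi)) - a
    exp(uniroot(f, c(-60, 60), tol = 1e-12)$root)
}

#' Exact confidence interval for the odds ratio
#'
#' Endpoints invert the one-sided noncentral hypergeometric tail tests at
#' `(1 - level) / 2` each: the lower endpoint solves
#' `P(X >= a; psi) = (1 - level) / 2`, the upper solves
#' `P(X <= a; psi) = (1 - level) / 2`, with 0 and `Inf` at the support
#' boundaries.  The interval always contains the conditional MLE.
#'
#' @inheritParams fisherExactP
#' @param level Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
exactCiOr <- function(a, b, c, d, level = 0.95) {
    m <- .tableMargins(a, b, c, d)
    alpha2 <- (1 - level) / 2
    if (m$lo == m$hi) return(c(0, Inf))
    upperTail <- function(t) {     # P(X >= a; t), increasing in t
        nw <- .nchgWeights(m, t)
        sum(nw$w[nw$x >= a])
    }
    lowerTail <- function(t) {     # P(X <= a; t), decreasing in t
        nw <- .nchgWeights(m, t)
        sum(nw$w[nw$x <= a])
    }
    lower <- if (a == m$lo) 0 else
        exp(uniroot(function(t) upperTail(t) - alpha2, c(-80, 80),
                    tol = 1e-12)$root)
    upper <- if (a == m$hi) Inf else
        exp(uniroot(function(t) lowerTail(t) - alpha2, c(-80, 80),
                    tol = 1e-12)$root)
    c(lower, upper)
}

#' Per-gene mutation counts from a cohort matrix
#'
#' A sample counts as mutated in a gene when its integrated label implies at
#' least one non-benign small-scale mutation (copy-only labels --
#' `deep_deletion`, `amplification`, `none` -- do not).
#'
#' @param x A [CohortMatrix-class].
#' @return data.frame: `gene`, `mutated`, `total`.
#' @export
geneMutationCounts <- function(x) {
    stopifnot(is(x, "CohortMatrix"))
    mutLabels <- c("multiple_mutations", "mutation_plus_deletion",
                   "mutation_plus_cnloh", "mutant_allele_amplified",
                   "single_hit")
    lab <- alterationLabels(x)
    data.frame(gene = rownames(lab),
               mutated = as.integer(rowSums(matrix(lab %in% mutLabels,
                                                   nrow = nrow(lab)))),
               total = ncol(lab), row.names = NULL)
}

#' Compare per-gene mutation frequencies between two cohorts
#'
#' For each shared gene, runs the exact test, the conditional-MLE odds
#' ratio and its exact confidence interval on the 2x2 table
#' (mutated/unmutated in cohort 1 vs cohort 2), then adjusts p-values by
#' Benjamini-Hochberg.  Per-gene cohort sizes may differ (genes unsequenced
#' in part of a source cohort get their own denominators).
#'
#' @param cohort1,cohort2 Either [CohortMatrix-class] objects or data.frames
#'   with columns `gene`, `mutated`, `total`.
#' @param genes Optional gene subset; genes absent from either cohort are
#'   dropped with a warning.
#' @param level Confidence level for the odds-ratio interval.
#' @return data.frame sorted by p-value: `gene`, `mutated1`, `total1`,
#'   `mutated2`, `total2`, `pValue`, `oddsRatio`, `ciLow`, `ciHigh`,
#'   `adjustedP`.
#' @export
compareCohorts <- function(cohort1, cohort2, genes = NULL, level = 0.95) {
    c1 <- if (is(cohort1, "CohortMatrix")) geneMutationCounts(cohort1)
          else cohort1
    c2 <- if (is(cohort2, "CohortMatrix")) geneMutationCounts(cohort2)
          else cohort2
    shared <- intersect(c1$gene, c2$gene)
    if (!is.null(genes)) {
        missing <- setdiff(genes, shared)
        if (length(missing))
            warning("genes absent from one cohort dropped: ",
                    paste(missing, collapse = ", "))
        shared <- intersect(genes, shared)
    }
    if (length(shared) == 0L) stop("empty gene intersection")
    rows <- lapply(shared, function(g) {
        i <- match(g, c1$gene); j <- match(g, c2$gene)
        a <- c1$mutated[i]; b <- c1$total[i] - a
        cc <- c2$mutated[j]; dd <- c2$total[j] - cc
        ci <- exactCiOr(a, b, cc, dd, level)
        data.frame(gene = g, mutated1 = a, total1 = c1$total[i],
                   mutated2 = cc, total2 = c2$total[j],
                   pValue = fisherExactP(a, b, cc, dd),
                   oddsRatio = conditionalMleOr(a, b, cc, dd),
                   ciLow = ci[1], ciHigh = ci[2])
    })
    out <- do.call(rbind, rows)
    out$adjustedP <- p.adjust(out$pValue, method = "BH")
    out <- out[order(out$pValue, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}
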
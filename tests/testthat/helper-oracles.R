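## Independent oracles used to validate the analytical kernels, plus small
## fixture builders.  Every oracle here is a brute-force or closed-form
## computation that shares no code path with the implementation it checks.

## uniform pick that never falls into sample()'s scalar expansion
pick <- function(v) v[sample.int(length(v), 1L)]

## Exhaustive least-squares changepoint search on a noise-free series:
## returns the breakpoints of the smallest model (0-2 changes) with zero
## residual sum of squares, or NULL if none fits.
lsChangepointOracle <- function(x, minLen = 3L) {
    n <- length(x)
    rss <- function(v) sum((v - mean(v))^2)
    if (rss(x) < 1e-18) return(integer(0))
    for (i in minLen:(n - minLen))
        if (rss(x[1:i]) + rss(x[(i + 1):n]) < 1e-18) return(i)
    if (n >= 3 * minLen)
        for (i in minLen:(n - 2 * minLen))
            for (j in (i + minLen):(n - minLen))
                if (rss(x[1:i]) + rss(x[(i + 1):j]) + rss(x[(j + 1):n]) < 1e-18)
                    return(c(i, j))
    NULL
}

## random noise-free piecewise-constant series with k in 0..2 changes,
## segment lengths >= 5 and level jumps >= 0.5
randomStepSeries <- function() {
    k <- pick(0:2)
    n <- pick((5 * (k + 1) + 2):50)
    bp <- if (k == 0) integer(0)
          else if (k == 1) pick(5:(n - 5))
          else { i <- pick(5:(n - 10)); c(i, pick((i + 5):(n - 5))) }
    levels <- cumsum(c(runif(1, -1, 1),
                       sample(c(-1, 1), k, replace = TRUE) *
                           runif(k, 0.5, 1.5)))
    seg <- c(0L, bp, n)
    x <- unlist(lapply(seq_len(k + 1),
                       function(i) rep(levels[i], seg[i + 1] - seg[i])))
    list(x = x, breakpoints = as.integer(bp))
}

## Full hypergeometric enumeration p-value via log-factorials (no dhyper).
enumFisherOracle <- function(a, b, c, d) {
    n1 <- a + b; n2 <- c + d; k <- a + c; N <- n1 + n2
    lo <- max(0, k - n2); hi <- min(k, n1)
    logp <- function(x)
        lfactorial(n1) + lfactorial(n2) + lfactorial(k) +
        lfactorial(N - k) - lfactorial(N) - lfactorial(x) -
        lfactorial(n1 - x) - lfactorial(k - x) - lfactorial(n2 - k + x)
    px <- exp(vapply(lo:hi, logp, numeric(1)))
    min(1, sum(px[px <= exp(logp(a)) * (1 + 1e-7)]))
}

## noncentral hypergeometric log-likelihood at log-odds t
.nchgLogLik <- function(a, n1, n2, k, t) {
    x <- max(0, k - n2):min(k, n1)
    lw <- lchoose(n1, x) + lchoose(n2, k - x) + x * t
    (lchoose(n1, a) + lchoose(n2, k - a) + a * t) -
        (max(lw) + log(sum(exp(lw - max(lw)))))
}

## grid-search + local refinement oracle for the conditional MLE odds ratio
gridMleOracle <- function(a, b, c, d) {
    n1 <- a + b; n2 <- c + d; k <- a + c
    lo <- max(0, k - n2); hi <- min(k, n1)
    if (lo == hi) return(NA_real_)
    if (a == lo) return(0)
    if (a == hi) return(Inf)
    ts <- seq(-15, 15, length.out = 6001)
    ll <- vapply(ts, function(t) .nchgLogLik(a, n1, n2, k, t), numeric(1))
    tbest <- ts[which.max(ll)]
    exp(optimize(function(t) -.nchgLogLik(a, n1, n2, k, t),
                 c(tbest - 0.02, tbest + 0.02), tol = 1e-13)$minimum)
}

## bisection oracle for the exact CI (inverts the one-sided tail tests)
bisectCiOracle <- function(a, b, c, d, level = 0.95) {
    n1 <- a + b; n2 <- c + d; k <- a + c
    lo <- max(0, k - n2); hi <- min(k, n1)
    alpha2 <- (1 - level) / 2
    tailGe <- function(t) {   # P(X >= a; t), increasing in t
        x <- lo:hi
        lw <- lchoose(n1, x) + lchoose(n2, k - x) + x * t
        w <- exp(lw - max(lw)); w <- w / sum(w)
        sum(w[x >= a])
    }
    tailLe <- function(t) {   # P(X <= a; t), decreasing in t
        x <- lo:hi
        lw <- lchoose(n1, x) + lchoose(n2, k - x) + x * t
        w <- exp(lw - max(lw)); w <- w / sum(w)
        sum(w[x <= a])
    }
    bisect <- function(g, increasing) {
        L <- -80; U <- 80
        for (i in 1:100) {
            M <- (L + U) / 2
            if ((g(M) > alpha2) == increasing) U <- M else L <- M
        }
        exp((L + U) / 2)
    }
    lower <- if (a == lo) 0 else bisect(tailGe, increasing = TRUE)
    upper <- if (a == hi) Inf else bisect(tailLe, increasing = FALSE)
    c(lower, upper)
}

## two-gene toy panel used across I/O and unit tests
toyPanel <- function() {
    panelDesign(c("chr1", "chr2"), c(1001L, 2001L), c(5000L, 6000L),
                c("GENE_A", "GENE_B"))
}

## minimal variant-table row builder
variantRow <- function(sampleId = "S01", chrom = "chr1", pos = 1500L,
                       gene = "GENE_A", depth = 100L, altCount = 50L,
                       populationAf = 0.2, consequence = "silent",
                       predictedClass = NA_character_, hotspot = FALSE) {
    data.frame(sampleId = sampleId, chrom = chrom, pos = as.integer(pos),
               ref = "A", alt = "T", gene = gene, depth = as.integer(depth),
               altCount = as.integer(altCount), vaf = altCount / depth,
               populationAf = populationAf, consequence = consequence,
               predictedClass = predictedClass, hotspot = hotspot,
               stringsAsFactors = FALSE)
}

variantTable <- function(...) do.call(rbind, list(...))
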
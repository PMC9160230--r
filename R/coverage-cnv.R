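## Copy-number estimation from targeted coverage: pooled-normal reference
## model, per-bin log2 ratios, circular binary segmentation, recentering,
## and integer copy-number / copy-state assignment.

#' Build a pooled-normal reference coverage model
#'
#' Each normal sample is scaled to mean coverage 1 (total-depth
#' normalization); the reference location per bin is the across-sample
#' median of the normalized depths and the spread the corresponding MAD.
#' Bins whose median raw depth falls below `minMedianDepth` are flagged
#' unreliable and excluded from downstream ratio computation.
#'
#' @param normalDepth Numeric matrix of raw depths, bins x normal samples.
#'   A vector is treated as a single-sample matrix.
#' @param minMedianDepth Raw-depth floor below which a bin is unreliable.
#' @return List with `location`, `spread` (per-bin numeric) and
#'   `unreliable` (per-bin logical).
#' @export
buildReference <- function(normalDepth, minMedianDepth = 10) {
    if (is.vector(normalDepth)) normalDepth <- matrix(normalDepth, ncol = 1L)
    if (ncol(normalDepth) < 1L) stop("at least one normal sample required")
    if (any(is.na(normalDepth))) stop("mismatched bin grids: NA depths")
    tot <- colMeans(normalDepth)
    if (any(tot == 0)) stop("all-zero normal sample")
    norm <- sweep(normalDepth, 2L, tot, "/")
    location <- apply(norm, 1L, median)
    spread <- apply(norm, 1L, mad)
    rawMedian <- apply(normalDepth, 1L, median)
    list(location = location, spread = spread,
         unreliable = rawMedian < minMedianDepth)
}

#' Per-bin log2 coverage ratios against a reference model
#'
#' The sample is total-depth normalized, divided by the reference location,
#' log2-transformed and median-centered (so a globally scaled sample maps to
#' ratio 0).  Unreliable reference bins yield `NA`.
#'
#' @param sampleDepth Numeric vector of raw depths on the reference's bin
#'   grid.
#' @param ref A reference model from [buildReference()].
#' @return Numeric vector of median-centered log2 ratios (NA on unreliable
#'   bins).
#' @export
log2Ratios <- function(sampleDepth, ref) {
    if (length(sampleDepth) != length(ref$location))
        stop("sample and reference are on different bin grids")
    ok <- !ref$unreliable
    if (any(ref$location[ok] == 0))
        stop("zero reference location on a reliable bin")
    norm <- sampleDepth / mean(sampleDepth)
    lr <- rep(NA_real_, length(sampleDepth))
    lr[ok] <- log2(pmax(norm[ok], 2^(.LOG2_FLOOR - 1)) / ref$location[ok])
    lr[ok] <- lr[ok] - median(lr[ok])
    lr
}

#' Circular binary segmentation breakpoints
#'
#' Recursive circular binary segmentation of an ordered numeric series: the
#' arc maximizing the pooled-variance two-sample t statistic against its
#' complement is accepted as a split when its permutation p-value falls
#' below `alpha`, and the search recurses into the resulting pieces.  Ties
#' break to the leftmost arc; every emitted segment has at least `minBins`
#' elements.  An arc that leaves both sides exactly constant (infinite t,
#' zero within-segment variance) is accepted without a permutation test:
#' such splits arise only in the noise-free limit, where they are certain.
#' The permutation stream is seeded independently of R's RNG, so results
#' are reproducible given `seed`.
#'
#' @param values Ordered numeric series (one chromosome's bins or variant
#'   deviations).
#' @param alpha Permutation significance level for accepting a split.
#' @param nPerm Number of permutations per split test.
#' @param minBins Minimum segment length.
#' @param seed Integer seed for the permutation stream.
#' @return Sorted integer vector of breakpoints; breakpoint `k` means the
#'   split falls between elements `k` and `k + 1`.
#' @examples
#' cbsSegment(c(rep(0, 15), rep(1, 10), rep(0, 15)))  # 15, 25
#' @export
cbsSegment <- function(values, alpha = 0.01, nPerm = 1000L, minBins = 3L,
                       seed = 1L) {
    values <- as.numeric(values)
    if (anyNA(values)) stop("values must not contain NA")
    if (length(values) < minBins) {
        warning("series shorter than minBins; no breakpoints")
        return(integer(0))
    }
    cpp_cbs_breakpoints(values, alpha, as.integer(nPerm),
                        as.integer(minBins), as.numeric(seed))
}

#' Segment one sample's coverage log2 ratios into copy-number segments
#'
#' Runs [cbsSegment()] independently within each chromosome of the bin grid,
#' averages the log2 ratios per segment, and assigns integer copy numbers
#' ([estimateCopies()]) and copy-state classes ([classifyCopyState()]).
#' Bins with `NA` ratios are dropped before segmentation.
#'
#' @param bins GRanges of coverage bins (sorted), e.g. from [panelBins()].
#' @param values Per-bin log2 ratios aligned with `bins`.
#' @param purity Optional tumor purity for copy-number estimation.
#' @param alpha,nPerm,minBins,seed Passed to [cbsSegment()].
#' @param thresholds Copy-state thresholds, see [classifyCopyState()].
#' @return GRanges of segments with `nBins`, `meanLog2`, `copyNumber`,
#'   `state` metadata columns.
#' @export
segmentCoverage <- function(bins, values, purity = NULL, alpha = 0.01,
                            nPerm = 1000L, minBins = 3L, seed = 1L,
                            thresholds = copyStateThresholds()) {
    stopifnot(length(bins) == length(values))
    keep <- !is.na(values)
    bins <- bins[keep]; values <- values[keep]
    chroms <- as.character(unique(seqnames(bins)))
    segs <- lapply(seq_along(chroms), function(ci) {
        sel <- as.logical(seqnames(bins) == chroms[ci])
        v <- values[sel]; b <- bins[sel]
        bp <- if (length(v) >= minBins)
            cbsSegment(v, alpha, nPerm, minBins, seed = seed + ci)
        else integer(0)
        bounds <- c(0L, bp, length(v))
        lo <- head(bounds, -1L) + 1L; hi <- tail(bounds, -1L)
        data.frame(chrom = chroms[ci], start = start(b)[lo],
                   end = end(b)[hi], nBins = hi - lo + 1L,
                   meanLog2 = vapply(seq_along(lo), function(i)
                       mean(v[lo[i]:hi[i]]), numeric(1)))
    })
    df <- do.call(rbind, segs)
    out <- GRanges(df$chrom, IRanges(df$start, df$end), nBins = df$nBins,
                   meanLog2 = df$meanLog2)
    mcols(out)$copyNumber <- estimateCopies(mcols(out)$meanLog2, purity)
    mcols(out)$state <- classifyCopyState(mcols(out)$copyNumber, thresholds)
    out
}

#' Recenter copy-number segments
#'
#' Subtracts a log2 shift from every segment mean and recomputes copy
#' numbers and states.  `shift = "auto"` estimates the shift as the
#' bin-weighted modal segment mean (segment means clustered within 0.05
#' log2 units; the cluster holding the most bins defines the mode), which
#' restores the dominant copy state to neutral when a sample's baseline has
#' drifted.  Auto-recentering is idempotent.
#'
#' @param segments GRanges from [segmentCoverage()].
#' @param shift Numeric log2 shift, or `"auto"`.
#' @param purity,thresholds Passed through to copy-number re-estimation.
#' @return Recentered segments GRanges.
#' @export
recenterSegments <- function(segments, shift = "auto", purity = NULL,
                             thresholds = copyStateThresholds()) {
    stopifnot(length(segments) > 0L)
    m <- mcols(segments)$meanLog2
    w <- mcols(segments)$nBins
    if (identical(shift, "auto")) {
        cl <- round(m / 0.05)
        wt <- tapply(w, cl, sum)
        modal <- as.numeric(names(wt))[which.max(wt)]
        sel <- cl == modal
        shift <- sum(m[sel] * w[sel]) / sum(w[sel])
    }
    mcols(segments)$meanLog2 <- m - shift
    mcols(segments)$copyNumber <- estimateCopies(mcols(segments)$meanLog2,
                                                 purity)
    mcols(segments)$state <- classifyCopyState(mcols(segments)$copyNumber,
                                               thresholds)
    segments
}

#' Integer copy number from a segment's mean log2 ratio
#'
#' Without purity: `round(2 * 2^meanLog2)`.  With purity `p` the diploid
#' normal admixture is removed first:
#' `round((2 * 2^meanLog2 - 2 * (1 - p)) / p)`, clipped at 0.  Exact halves
#' round away from zero.
#'
#' @param meanLog2 Numeric vector of segment mean log2 ratios.
#' @param purity Tumor purity in (0, 1\], or `NULL` when unknown.
#' @return Non-negative integer copy numbers.
#' @examples
#' estimateCopies(0)            # 2
#' estimateCopies(1)            # 4
#' estimateCopies(-1, purity = 0.5)  # 0
#' @export
estimateCopies <- function(meanLog2, purity = NULL) {
    stopifnot(all(is.finite(meanLog2)))
    raw <- 2 * 2^meanLog2
    if (!is.null(purity)) {
        if (any(purity <= 0)) stop("purity must be > 0")
        raw <- (raw - 2 * (1 - purity)) / purity
    }
    as.integer(pmax(.roundHalfAway(pmax(raw, 0)), 0))
}

.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Copy-state classification thresholds
#'
#' @param gainMin Lowest copy number called a gain.
#' @param ampMin Lowest copy number called an amplification.
#' @return Named list of thresholds.
#' @export
copyStateThresholds <- function(gainMin = 3L, ampMin = 5L) {
    stopifnot(gainMin >= 3L, ampMin > gainMin)
    list(gainMin = as.integer(gainMin), ampMin = as.integer(ampMin))
}

#' Classify an integer copy number into a copy-state class
#'
#' Defaults: 0 deep deletion, 1 shallow deletion, 2 neutral, 3--4 gain,
#' >= 5 amplification.
#'
#' @param copyNumber Non-negative integer vector.
#' @param thresholds From [copyStateThresholds()].
#' @return Character vector of states (see [copyStates()]).
#' @export
classifyCopyState <- function(copyNumber, thresholds = copyStateThresholds()) {
    stopifnot(all(copyNumber >= 0))
    out <- ifelse(copyNumber == 0L, "deep_deletion",
           ifelse(copyNumber == 1L, "shallow_deletion",
           ifelse(copyNumber < thresholds$gainMin, "neutral",
           ifelse(copyNumber < thresholds$ampMin, "gain", "amplification"))))
    out
}
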
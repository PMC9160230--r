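## Allelic-imbalance / LOH detection from heterozygous-SNP VAF deviations:
## informative-SNP selection, |VAF - 0.5| deviation series, segmentation,
## the 0.15 segment-mean threshold, paired VAF shifts, and LOH mechanism
## classification against copy number.

#' Select informative heterozygous SNPs
#'
#' Keeps variants whose population allele frequency lies strictly inside
#' `afRange`, whose depth strictly exceeds `minDepth`, and whose observed
#' VAF lies strictly inside the homozygous-exclusion cutoffs.  Defaults
#' follow the tumor-only heterozygosity analysis: gnomAD frequency in
#' (0.0001, 0.95), coverage larger than 30x, homozygous calls (VAF outside
#' (0.05, 0.95)) excluded.
#'
#' @param variants Variant data.frame with `chrom`, `pos`, `vaf`, `depth`,
#'   `populationAf` columns (see [readVariants()]).
#' @param afRange Open population-AF interval.
#' @param minDepth Depth must be strictly greater than this.
#' @param homCutoffs Open VAF interval treated as heterozygous; `NULL`
#'   disables homozygous exclusion.
#' @return The retained rows, ordered by (chrom, pos), with a `deviation`
#'   column `|vaf - 0.5|` appended.
#' @export
selectInformative <- function(variants, afRange = c(1e-4, 0.95),
                              minDepth = 30, homCutoffs = c(0.05, 0.95)) {
    keep <- variants$populationAf > afRange[1] &
            variants$populationAf < afRange[2] &
            variants$depth > minDepth
    if (!is.null(homCutoffs))
        keep <- keep & variants$vaf > homCutoffs[1] &
                       variants$vaf < homCutoffs[2]
    out <- variants[keep, , drop = FALSE]
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    out$deviation <- deviationSeries(out$vaf)
    rownames(out) <- NULL
    out
}

#' VAF deviation from the heterozygous state
#'
#' @param vaf Numeric VAF vector (or a data.frame with a `vaf` column).
#' @return `|vaf - 0.5|`, symmetric under allele swap.
#' @export
deviationSeries <- function(vaf) {
    if (is.data.frame(vaf)) vaf <- vaf$vaf
    abs(vaf - 0.5)
}

#' Segment VAF deviations and flag allelic imbalance
#'
#' Deviations are segmented per chromosome with [cbsSegment()] on the
#' variant index (panel gaps do not inflate arc statistics), and a segment
#' is flagged imbalanced when its mean deviation reaches `threshold`
#' (default 0.15; segments below it are considered not altered).
#' Chromosomes with fewer than `minBins` informative variants yield a
#' single low-confidence segment.
#'
#' @param hets data.frame from [selectInformative()] (needs `chrom`, `pos`,
#'   `deviation`).
#' @param threshold Segment-mean deviation at or above which imbalance is
#'   called.
#' @param statistic `"mean"` (default) or `"median"` segment deviation.
#' @param alpha,nPerm,minBins,seed Passed to [cbsSegment()].
#' @return data.frame of segments: `chrom`, `start`, `end`, `nVariants`,
#'   `meanDeviation`, `imbalance`, `lowConfidence`.
#' @export
callImbalance <- function(hets, threshold = 0.15, statistic = c("mean", "median"),
                          alpha = 0.01, nPerm = 1000L, minBins = 3L,
                          seed = 1L) {
    statistic <- match.arg(statistic)
    stat <- if (statistic == "mean") mean else median
    chroms <- unique(hets$chrom)
    segs <- lapply(seq_along(chroms), function(ci) {
        h <- hets[hets$chrom == chroms[ci], , drop = FALSE]
        n <- nrow(h)
        if (n == 0L) return(NULL)
        lowConf <- n < minBins
        bp <- if (lowConf) integer(0)
              else cbsSegment(h$deviation, alpha, nPerm, minBins,
                              seed = seed + ci)
        bounds <- c(0L, bp, n)
        lo <- head(bounds, -1L) + 1L; hi <- tail(bounds, -1L)
        md <- vapply(seq_along(lo), function(i)
            stat(h$deviation[lo[i]:hi[i]]), numeric(1))
        data.frame(chrom = chroms[ci], start = h$pos[lo], end = h$pos[hi],
                   nVariants = hi - lo + 1L, meanDeviation = md,
                   imbalance = md >= threshold, lowConfidence = lowConf)
    })
    out <- do.call(rbind, segs)
    if (is.null(out))
        out <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), nVariants = integer(0),
                          meanDeviation = numeric(0), imbalance = logical(0),
                          lowConfidence = logical(0))
    rownames(out) <- NULL
    out
}

#' Tumor-normal VAF shifts and paired segment support
#'
#' Matches tumor and matched-normal variants by locus, restricts to loci
#' heterozygous in the normal, computes per-variant shifts
#' `|vaf_tumor - vaf_normal|`, and marks a deviation segment as
#' paired-supported when the mean shift of its variants reaches
#' `shiftThreshold`.  Without shared heterozygous loci, `pairedSupport` is
#' `NA` for every segment.
#'
#' @param normalVariants,tumorVariants Variant data.frames.
#' @param devSegments Segments from [callImbalance()].
#' @param shiftThreshold Mean shift at or above which a segment gains
#'   support.
#' @param normalHetCutoffs Open VAF interval defining a heterozygous normal
#'   genotype.
#' @return List with `shifts` (per-locus data.frame: `chrom`, `pos`,
#'   `vafNormal`, `vafTumor`, `shift`) and `segments` (`devSegments` with a
#'   `pairedSupport` column).
#' @export
pairedShift <- function(normalVariants, tumorVariants, devSegments,
                        shiftThreshold = 0.15,
                        normalHetCutoffs = c(0.25, 0.75)) {
    keyN <- paste(normalVariants$chrom, normalVariants$pos)
    keyT <- paste(tumorVariants$chrom, tumorVariants$pos)
    het <- normalVariants$vaf > normalHetCutoffs[1] &
           normalVariants$vaf < normalHetCutoffs[2]
    idx <- match(keyN[het], keyT)
    ok <- !is.na(idx)
    shifts <- data.frame(
        chrom = normalVariants$chrom[het][ok],
        pos = normalVariants$pos[het][ok],
        vafNormal = normalVariants$vaf[het][ok],
        vafTumor = tumorVariants$vaf[idx[ok]])
    shifts$shift <- abs(shifts$vafTumor - shifts$vafNormal)
    devSegments$pairedSupport <- NA
    if (nrow(shifts) > 0L) {
        for (i in seq_len(nrow(devSegments))) {
            sel <- shifts$chrom == devSegments$chrom[i] &
                   shifts$pos >= devSegments$start[i] &
                   shifts$pos <= devSegments$end[i]
            if (any(sel))
                devSegments$pairedSupport[i] <-
                    mean(shifts$shift[sel]) >= shiftThreshold
        }
    }
    list(shifts = shifts, segments = devSegments)
}

#' Classify LOH mechanism from imbalance and copy number
#'
#' Each imbalanced deviation segment is intersected with the copy-number
#' segments; the bin-weighted majority copy number over the overlap decides
#' the mechanism: copy number 2 is copy-neutral LOH, <= 1 is LOH through
#' deletion, >= 3 is an imbalanced gain.  Balanced segments are `none`.  An
#' imbalanced segment with no copy-number information is reported as
#' `imbalance_unknown_cn`.
#'
#' @param devSegments data.frame from [callImbalance()] (optionally with
#'   `pairedSupport` from [pairedShift()]).
#' @param cnSegments GRanges from [segmentCoverage()].
#' @return `devSegments` with `copyNumber` and `mechanism` columns appended.
#' @export
classifyLoh <- function(devSegments, cnSegments) {
    n <- nrow(devSegments)
    if (is.null(devSegments$pairedSupport))
        devSegments$pairedSupport <- NA
    cn <- rep(NA_integer_, n)
    if (n > 0L && length(cnSegments) > 0L) {
        dev <- GRanges(devSegments$chrom,
                       IRanges(devSegments$start, devSegments$end))
        ov <- findOverlaps(dev, cnSegments)
        if (length(ov)) {
            ow <- width(pintersect(dev[queryHits(ov)],
                                   cnSegments[subjectHits(ov)]))
            cnv <- mcols(cnSegments)$copyNumber[subjectHits(ov)]
            for (i in unique(queryHits(ov))) {
                sel <- queryHits(ov) == i
                w <- tapply(ow[sel], cnv[sel], sum)
                cn[i] <- as.integer(names(w)[which.max(w)])
            }
        }
    }
    devSegments$copyNumber <- cn
    devSegments$mechanism <- ifelse(!devSegments$imbalance, "none",
        ifelse(is.na(cn), "imbalance_unknown_cn",
        ifelse(cn == 2L, "cnloh",
        ifelse(cn <= 1L, "deletion_loh", "imbalanced_gain"))))
    devSegments
}
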
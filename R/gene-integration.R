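## Gene-level integration: merge mutation summaries, copy states and LOH
## calls into per-gene per-sample alteration records with biallelic
## mechanism labels, and assemble the cohort alteration matrix.

#' Mutant-allele multiplicity estimate
#'
#' Number of DNA copies per tumor cell carrying a somatic mutation, inverted
#' from the admixture VAF model:
#' `vaf * (purity * copyNumber + 2 * (1 - purity)) / purity`.
#'
#' @param vaf Observed variant allele frequency.
#' @param copyNumber Total copy number at the locus.
#' @param purity Tumor purity in (0, 1\].
#' @return Estimated multiplicity (copies).
#' @examples
#' multiplicityEstimate(0.5, 2, 1)       # 1
#' multiplicityEstimate(0.25, 4, 0.5)    # 1.5
#' @export
multiplicityEstimate <- function(vaf, copyNumber, purity) {
    if (any(purity <= 0)) stop("purity must be > 0")
    vaf * (purity * copyNumber + 2 * (1 - purity)) / purity
}

#' Integrate one gene-sample record
#'
#' Applies the mechanism priority: deep deletion; multiple mutations; one
#' mutation plus shallow deletion or deletion-LOH; one mutation plus
#' copy-neutral LOH; one mutation whose estimated multiplicity is >= 1.5 at
#' copy number >= 3 (amplified mutant allele); amplification without
#' mutation; single mutation; none.  The first five labels are biallelic.
#' When purity is unknown the multiplicity uses purity 1 and the amplified
#' mutant-allele call is marked putative.
#'
#' @param nMutations Count of non-benign mutations in the gene.
#' @param copyNumber,copyState Gene-level copy number and state (see
#'   [geneCopyState()]).
#' @param lohMechanism LOH mechanism over the gene (`cnloh`,
#'   `deletion_loh`, `imbalanced_gain`, `imbalance_unknown_cn` or `none`).
#' @param vaf VAF of the (highest-VAF) mutation, NA when no mutation.
#' @param purity Tumor purity, or NA when unknown.
#' @param multThreshold Multiplicity at or above which the mutant allele is
#'   considered amplified.
#' @param highDepth Depth beyond which a mutation inside a deep deletion is
#'   flagged inconsistent.
#' @param depth Depth of the mutation call (for the consistency flag).
#' @return List: `label`, `biallelic`, `putative`, `inconsistent`.
#' @export
integrateGeneSample <- function(nMutations, copyNumber, copyState,
                                lohMechanism = "none", vaf = NA,
                                purity = NA, multThreshold = 1.5,
                                highDepth = 50, depth = NA) {
    putative <- FALSE
    inconsistent <- FALSE
    if (identical(copyState, "deep_deletion")) {
        if (nMutations > 0 && !is.na(vaf) && vaf > 0 &&
            !is.na(depth) && depth >= highDepth)
            inconsistent <- TRUE
        label <- "deep_deletion"
    } else if (nMutations >= 2) {
        label <- "multiple_mutations"
    } else if (nMutations == 1 &&
               (identical(copyState, "shallow_deletion") ||
                identical(lohMechanism, "deletion_loh"))) {
        label <- "mutation_plus_deletion"
    } else if (nMutations == 1 && identical(lohMechanism, "cnloh")) {
        label <- "mutation_plus_cnloh"
    } else if (nMutations == 1 && !is.na(copyNumber) && copyNumber >= 3 &&
               !is.na(vaf)) {
        p <- if (is.na(purity)) 1 else purity
        mult <- multiplicityEstimate(vaf, copyNumber, p)
        if (mult >= multThreshold) {
            label <- "mutant_allele_amplified"
            putative <- is.na(purity)
        } else label <- "single_hit"
    } else if (nMutations == 0 && identical(copyState, "amplification")) {
        label <- "amplification"
    } else if (nMutations == 1) {
        label <- "single_hit"
    } else {
        label <- "none"
    }
    list(label = label, biallelic = label %in% .BIALLELIC_LABELS,
         putative = putative, inconsistent = inconsistent)
}

#' Gene-level copy number and state by bin-weighted majority
#'
#' Genes may span segmentation breakpoints; each gene takes the copy number
#' of the overlapping segment(s) holding the most bins of overlap (overlap
#' width as the weight).
#'
#' @param cnSegments GRanges from [segmentCoverage()].
#' @param geneRanges GRanges of gene targets with a `gene` metadata column.
#' @return data.frame: `gene`, `copyNumber`, `state` (NA where no overlap).
#' @export
geneCopyState <- function(cnSegments, geneRanges) {
    genes <- as.character(mcols(geneRanges)$gene)
    cn <- rep(NA_integer_, length(geneRanges))
    st <- rep(NA_character_, length(geneRanges))
    ov <- findOverlaps(geneRanges, cnSegments)
    if (length(ov)) {
        ow <- width(pintersect(geneRanges[queryHits(ov)],
                               cnSegments[subjectHits(ov)]))
        for (i in unique(queryHits(ov))) {
            sel <- queryHits(ov) == i
            sub <- subjectHits(ov)[sel]
            w <- tapply(ow[sel], mcols(cnSegments)$copyNumber[sub], sum)
            cn[i] <- as.integer(names(w)[which.max(w)])
            st[i] <- classifyCopyState(cn[i])
        }
    }
    data.frame(gene = genes, copyNumber = cn, state = st)
}

#' Gene-level LOH mechanism
#'
#' Assigns to each gene the imbalance status of the overlapping deviation
#' segment covering most of it.  When per-gene copy numbers are supplied,
#' the mechanism of an imbalanced gene is re-derived from the gene's own
#' copy number (a deviation segment can span a CN-LOH gene and a deleted
#' neighbor, whose |VAF - 0.5| signals are indistinguishable); otherwise
#' the overlapping call's segment-level mechanism is used.
#'
#' @param lohCalls data.frame from [classifyLoh()].
#' @param geneRanges GRanges of gene targets with a `gene` column.
#' @param copyNumber Optional integer vector of gene-level copy numbers
#'   aligned with `geneRanges` (from [geneCopyState()]).
#' @return data.frame: `gene`, `imbalance`, `lohMechanism`.
#' @export
geneLohMechanism <- function(lohCalls, geneRanges, copyNumber = NULL) {
    genes <- as.character(mcols(geneRanges)$gene)
    mech <- rep("none", length(geneRanges))
    imb <- rep(FALSE, length(geneRanges))
    if (NROW(lohCalls) > 0L) {
        loh <- GRanges(lohCalls$chrom, IRanges(lohCalls$start, lohCalls$end))
        ov <- findOverlaps(geneRanges, loh)
        if (length(ov)) {
            ow <- width(pintersect(geneRanges[queryHits(ov)],
                                   loh[subjectHits(ov)]))
            for (i in unique(queryHits(ov))) {
                sel <- queryHits(ov) == i
                sub <- subjectHits(ov)[sel]
                best <- sub[which.max(ow[sel])]
                mech[i] <- lohCalls$mechanism[best]
                imb[i] <- lohCalls$imbalance[best]
            }
        }
    }
    if (!is.null(copyNumber)) {
        cn <- as.integer(copyNumber)
        mech <- ifelse(!imb, "none",
                ifelse(is.na(cn), "imbalance_unknown_cn",
                ifelse(cn == 2L, "cnloh",
                ifelse(cn <= 1L, "deletion_loh", "imbalanced_gain"))))
    }
    data.frame(gene = genes, imbalance = imb, lohMechanism = mech)
}

#' Integrate a whole sample
#'
#' Convenience wrapper running [geneCopyState()], [geneLohMechanism()] and
#' [integrateGeneSample()] across all panel genes for one sample.
#'
#' @param mutationSummary data.frame from [collapseToGene()] restricted to
#'   this sample.
#' @param cnSegments GRanges of the sample's copy-number segments.
#' @param lohCalls data.frame of the sample's LOH calls.
#' @param panel A [PanelDesign-class].
#' @param sampleIdValue Sample identifier for the output rows.
#' @param purity Tumor purity or NA.
#' @return data.frame with one row per gene: `gene`, `sampleId`,
#'   `nMutations`, `copyNumber`, `copyState`, `lohMechanism`, `label`,
#'   `biallelic`, `putative`, `inconsistent`.
#' @export
integrateSample <- function(mutationSummary, cnSegments, lohCalls, panel,
                            sampleIdValue, purity = NA) {
    geneRanges <- panelTargets(panel)
    cs <- geneCopyState(cnSegments, geneRanges)
    lm <- geneLohMechanism(lohCalls, geneRanges, copyNumber = cs$copyNumber)
    res <- lapply(seq_len(nrow(cs)), function(i) {
        g <- cs$gene[i]
        mrow <- mutationSummary[mutationSummary$gene == g, , drop = FALSE]
        nMut <- if (nrow(mrow)) mrow$nMutations[1L] else 0L
        vaf <- if (nrow(mrow)) mrow$maxVaf[1L] else NA
        r <- integrateGeneSample(nMut, cs$copyNumber[i], cs$state[i],
                                 lm$lohMechanism[i], vaf = vaf,
                                 purity = purity)
        data.frame(gene = g, sampleId = sampleIdValue, nMutations = nMut,
                   copyNumber = cs$copyNumber[i], copyState = cs$state[i],
                   lohMechanism = lm$lohMechanism[i], label = r$label,
                   biallelic = r$biallelic, putative = r$putative,
                   inconsistent = r$inconsistent)
    })
    do.call(rbind, res)
}

#' Build the cohort alteration matrix
#'
#' @param alterations data.frame of gene-sample records (rows from
#'   [integrateSample()], all samples bound together); exactly one row per
#'   (gene, sample).
#' @return A [CohortMatrix-class] with genes sorted by decreasing alteration
#'   frequency (fraction of samples whose label is not `none`).
#' @export
buildMatrix <- function(alterations) {
    if (NROW(alterations) == 0L) stop("empty cohort")
    key <- paste(alterations$gene, alterations$sampleId)
    if (anyDuplicated(key)) stop("duplicate (gene, sample) records")
    genes <- unique(alterations$gene)
    samples <- unique(alterations$sampleId)
    labels <- matrix("none", length(genes), length(samples),
                     dimnames = list(genes, samples))
    biall <- matrix(FALSE, length(genes), length(samples),
                    dimnames = list(genes, samples))
    labels[cbind(match(alterations$gene, genes),
                 match(alterations$sampleId, samples))] <- alterations$label
    biall[cbind(match(alterations$gene, genes),
                match(alterations$sampleId, samples))] <- alterations$biallelic
    freq <- rowMeans(labels != "none")
    ord <- order(-freq, genes)
    new("CohortMatrix", labels = labels[ord, , drop = FALSE],
        biallelic = biall[ord, , drop = FALSE],
        frequency = freq[ord])
}
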
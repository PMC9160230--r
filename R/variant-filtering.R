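## Rule-based reduction of raw variant tables to candidate somatic,
## non-benign mutations: population-frequency and panel-of-normals filters
## plus an explicit pathogenicity precedence replacing manual curation.

#' Variant filtering configuration
#'
#' @param maxPopulationAf Maximum population allele frequency for a
#'   candidate somatic variant (variants above it are common germline
#'   variation).
#' @param minDepth,minAltReads Minimum total depth and alt-supporting reads.
#' @param ponMaxOccurrence Maximum panel-of-normals occurrence count.
#' @param treatTruncatingAsPathogenic Whether truncating variants in tumor
#'   suppressors are pathogenic absent an explicit prediction.
#' @return Named list of thresholds.
#' @export
filterConfig <- function(maxPopulationAf = 0.001, minDepth = 20,
                         minAltReads = 4, ponMaxOccurrence = 1,
                         treatTruncatingAsPathogenic = TRUE) {
    stopifnot(maxPopulationAf >= 0, minDepth >= 0, minAltReads >= 0,
              ponMaxOccurrence >= 0)
    list(maxPopulationAf = maxPopulationAf, minDepth = minDepth,
         minAltReads = minAltReads, ponMaxOccurrence = ponMaxOccurrence,
         treatTruncatingAsPathogenic = treatTruncatingAsPathogenic)
}

#' Remove common germline variation and technical artifacts
#'
#' Keeps variants with `populationAf <= maxPopulationAf`,
#' `depth >= minDepth`, `altCount >= minAltReads` and panel-of-normals
#' occurrence `<= ponMaxOccurrence`.  In paired mode any variant present at
#' the same locus and alt allele in the matched normal is removed (the
#' somatic definition).
#'
#' @param variants Variant data.frame (columns of [readVariants()]).
#' @param config From [filterConfig()].
#' @param pon Optional data.frame (`chrom`, `pos`, `alt`, `occurrence`) of
#'   panel-of-normals occurrence counts.
#' @param normalVariants Optional matched-normal variant table; supplying it
#'   switches on paired mode.
#' @return Filtered variant data.frame with a `matchedNormal` column when in
#'   paired mode.
#' @export
filterCommon <- function(variants, config = filterConfig(), pon = NULL,
                         normalVariants = NULL) {
    keep <- variants$populationAf <= config$maxPopulationAf &
            variants$depth >= config$minDepth &
            variants$altCount >= config$minAltReads
    if (!is.null(pon) && nrow(pon) > 0L) {
        occ <- pon$occurrence[match(paste(variants$chrom, variants$pos,
                                          variants$alt),
                                    paste(pon$chrom, pon$pos, pon$alt))]
        occ[is.na(occ)] <- 0
        keep <- keep & occ <= config$ponMaxOccurrence
    }
    out <- variants[keep, , drop = FALSE]
    out$matchedNormal <- rep(NA, nrow(out))
    if (!is.null(normalVariants)) {
        inNormal <- paste(out$chrom, out$pos, out$alt) %in%
            paste(normalVariants$chrom, normalVariants$pos,
                  normalVariants$alt)
        out$matchedNormal <- inNormal
        out <- out[!inNormal, , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}

#' Rule-based pathogenicity classification
#'
#' Precedence: an explicit predicted class wins; otherwise truncating
#' consequences (nonsense, frameshift, splice site) in a tumor suppressor
#' are pathogenic; hotspot variants are pathogenic; silent variants are
#' benign; everything else is a variant of unknown significance.  Unknown
#' consequence values fall to `vus` with a warning.
#'
#' @param consequence Character vector over \{nonsense, frameshift,
#'   splice_site, missense, silent, other\}.
#' @param predictedClass Optional per-variant prediction
#'   (\{pathogenic, benign, vus\} or NA).
#' @param hotspot Logical hotspot flag.
#' @param geneRole \{tumor_suppressor, oncogene, other\} per variant.
#' @param treatTruncatingAsPathogenic See [filterConfig()].
#' @return Character vector over \{pathogenic, benign, vus\}.
#' @export
classifyPathogenicity <- function(consequence, predictedClass = NA,
                                  hotspot = FALSE, geneRole = "other",
                                  treatTruncatingAsPathogenic = TRUE) {
    n <- length(consequence)
    predictedClass <- rep_len(as.character(predictedClass), n)
    hotspot <- rep_len(hotspot, n)
    geneRole <- rep_len(geneRole, n)
    known <- c("nonsense", "frameshift", "splice_site", "missense",
               "silent", "other")
    if (any(!consequence %in% known)) {
        warning("unknown consequence value(s): ",
                paste(unique(setdiff(consequence, known)), collapse = ", "),
                "; classified as vus")
    }
    truncating <- consequence %in% c("nonsense", "frameshift", "splice_site")
    out <- ifelse(!is.na(predictedClass), predictedClass,
           ifelse(treatTruncatingAsPathogenic & truncating &
                  geneRole == "tumor_suppressor", "pathogenic",
           ifelse(hotspot, "pathogenic",
           ifelse(consequence == "silent", "benign", "vus"))))
    out[!consequence %in% known] <- "vus"
    out
}

#' Collapse classified variants to per-gene per-sample mutation summaries
#'
#' Benign variants are dropped; genes with only benign variants are absent
#' from the summary.  Retained variants (pathogenic and vus) are counted per
#' (gene, sample) with flags for multiple mutations and truncating content.
#'
#' @param variants Variant data.frame with a `pathogenicity` column (from
#'   [classifyPathogenicity()]) plus `sampleId`, `gene`, `vaf`,
#'   `consequence`.
#' @return data.frame with one row per (gene, sample): `gene`, `sampleId`,
#'   `nMutations`, `multiMutation`, `hasTruncating`, `hasPathogenic`,
#'   `hasHotspot`, `maxVaf`.
#' @export
collapseToGene <- function(variants) {
    v <- variants[variants$pathogenicity != "benign", , drop = FALSE]
    if (nrow(v) == 0L)
        return(data.frame(gene = character(0), sampleId = character(0),
                          nMutations = integer(0), multiMutation = logical(0),
                          hasTruncating = logical(0),
                          hasPathogenic = logical(0), hasHotspot = logical(0),
                          maxVaf = numeric(0)))
    key <- interaction(v$gene, v$sampleId, drop = TRUE)
    trunc <- v$consequence %in% c("nonsense", "frameshift", "splice_site")
    hot <- if (is.null(v$hotspot)) rep(FALSE, nrow(v)) else v$hotspot
    out <- data.frame(
        gene = tapply(v$gene, key, `[`, 1L),
        sampleId = tapply(v$sampleId, key, `[`, 1L),
        nMutations = as.integer(tapply(seq_len(nrow(v)), key, length)),
        hasTruncating = as.logical(tapply(trunc, key, any)),
        hasPathogenic = as.logical(tapply(v$pathogenicity == "pathogenic",
                                          key, any)),
        hasHotspot = as.logical(tapply(hot, key, any)),
        maxVaf = as.numeric(tapply(v$vaf, key, max)))
    out$multiMutation <- out$nMutations >= 2L
    rownames(out) <- NULL
    out[order(out$sampleId, out$gene),
        c("gene", "sampleId", "nMutations", "multiMutation", "hasTruncating",
          "hasPathogenic", "hasHotspot", "maxVaf")]
}
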
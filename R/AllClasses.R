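## Central S4 containers.  Interval data live in GRanges; the cohort-level
## coverage matrix lives in a RangedSummarizedExperiment keyed by panel bins.

#' Targeted panel design
#'
#' A set of non-overlapping capture target intervals, each assigned to exactly
#' one gene.  Construct with [panelDesign()] or read from BED with
#' [readPanel()].
#'
#' @slot targets A [GenomicRanges::GRanges] with a `gene` metadata column.
#' @export
setClass("PanelDesign", slots = c(targets = "GRanges"))

setValidity("PanelDesign", function(object) {
    gr <- object@targets
    if (length(gr) == 0L)
        return("panel must contain at least one target interval")
    if (is.null(mcols(gr)$gene) || any(is.na(mcols(gr)$gene)) ||
        any(mcols(gr)$gene == ""))
        return("every target interval must carry a non-empty 'gene'")
    ov <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov) > 0L)
        return("target intervals must not overlap within a chromosome")
    TRUE
})

#' Simulation configuration for synthetic tumor cohorts
#'
#' Defaults emulate a 48-sample head-and-neck panel cohort with 13 matched
#' normals, median on-target depth around 150x, negative-binomial depth
#' overdispersion, Gaussian log2-ratio noise and tumor purities in 0.6--0.9.
#'
#' @slot nSamples,nPaired Cohort size and number of samples with a matched
#'   normal.
#' @slot meanDepth Mean on-target sequencing depth (reads).
#' @slot depthDispersion Negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 makes depths deterministic.
#' @slot log2NoiseSd Per-bin Gaussian noise SD on coverage log2 ratios; 0
#'   makes coverage (and, together with `depthDispersion = 0`, allele counts)
#'   deterministic -- the noise-free limit.
#' @slot hetSnpDensity Germline heterozygous SNP density per kilobase of
#'   target.
#' @slot purityRange Tumor purity is drawn uniformly from this interval.
#' @slot driverTable Per-gene event probabilities, see [defaultDriverTable()].
#' @slot binSize Coverage bin size in bp.
#' @slot seed Base seed for all randomness in [generateCohort()].
#' @export
setClass("SimConfig", slots = c(
    nSamples = "integer", nPaired = "integer",
    meanDepth = "numeric", depthDispersion = "numeric",
    log2NoiseSd = "numeric", hetSnpDensity = "numeric",
    purityRange = "numeric", driverTable = "data.frame",
    binSize = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
    if (object@nSamples < 1L) return("nSamples must be >= 1")
    if (object@nPaired < 0L || object@nPaired > object@nSamples)
        return("nPaired must lie in [0, nSamples]")
    if (any(c(object@meanDepth, object@depthDispersion, object@log2NoiseSd,
              object@hetSnpDensity) < 0))
        return("rates and noise parameters must be >= 0")
    if (length(object@purityRange) != 2L ||
        any(object@purityRange < 0) || any(object@purityRange > 1) ||
        diff(object@purityRange) < 0)
        return("purityRange must be an increasing interval inside [0, 1]")
    dt <- object@driverTable
    need <- c("gene", "role", eventTypes())
    if (!all(need %in% names(dt)))
        return(paste("driverTable must have columns:",
                     paste(need, collapse = ", ")))
    pm <- as.matrix(dt[, eventTypes()])
    if (any(pm < 0) || any(abs(rowSums(pm) - 1) > 1e-8))
        return("driverTable event probabilities must be >= 0 and sum to 1 per gene")
    TRUE
})

#' Ground truth for one simulated tumor sample
#'
#' @slot sampleId Sample identifier.
#' @slot purity Fraction of neoplastic cells in the sample, in \[0, 1\].
#' @slot segments GRanges tiling the panel, with integer `totalCopies` and
#'   `minorCopies` metadata columns.
#' @slot variants GRanges of planted variants with gene, origin
#'   (germline/somatic), multiplicity (copies per tumor cell carrying the alt
#'   allele), populationAf, annotation and hotspot columns.
#' @slot hasMatchedNormal Whether a matched-normal sample was emitted.
#' @export
setClass("TumorTruth", slots = c(
    sampleId = "character", purity = "numeric",
    segments = "GRanges", variants = "GRanges",
    hasMatchedNormal = "logical"))

setValidity("TumorTruth", function(object) {
    if (object@purity < 0 || object@purity > 1)
        return("purity must lie in [0, 1]")
    seg <- object@segments
    if (length(seg)) {
        tc <- mcols(seg)$totalCopies
        mc <- mcols(seg)$minorCopies
        if (is.null(tc) || is.null(mc))
            return("segments need totalCopies and minorCopies")
        if (any(tc < 0) || any(tc > 60)) return("totalCopies must be in [0, 60]")
        if (any(mc < 0) || any(mc > tc - mc))
            return("minorCopies must be the smaller allele count")
        if (length(findOverlaps(seg, drop.self = TRUE, drop.redundant = TRUE)))
            return("truth segments must not overlap")
    }
    v <- object@variants
    if (length(v)) {
        m <- mcols(v)
        if (any(m$origin == "germline" & m$populationAf <= 0))
            return("germline variants must have populationAf > 0")
        if (any(m$origin == "somatic" & m$populationAf != 0))
            return("somatic variants must have populationAf == 0")
    }
    TRUE
})

#' A simulated cohort: ground truth plus observed data
#'
#' @slot coverage RangedSummarizedExperiment over panel bins with assays
#'   `depth`, `log2ratio` and `normalDepth` (NA columns for unpaired samples).
#' @slot tumorVariants,normalVariants Observed variant tables
#'   (one row per called variant per sample; see [readVariants()] for the
#'   column contract).
#' @slot truth List of [TumorTruth-class] objects, one per sample.
#' @slot panel The [PanelDesign-class] the cohort was simulated on.
#' @slot config The [SimConfig-class] used.
#' @export
setClass("SyntheticCohort", slots = c(
    coverage = "RangedSummarizedExperiment",
    tumorVariants = "data.frame", normalVariants = "data.frame",
    truth = "list", panel = "PanelDesign", config = "SimConfig"))

setValidity("SyntheticCohort", function(object) {
    if (length(object@truth) != object@config@nSamples)
        return("one TumorTruth per configured sample required")
    if (!all(vapply(object@truth, is, logical(1), "TumorTruth")))
        return("truth must be a list of TumorTruth objects")
    TRUE
})

#' Gene-by-sample cohort alteration matrix
#'
#' The integrated view of a cohort: one mechanism label per (gene, sample),
#' the matching biallelic-inactivation flag, and per-gene alteration
#' frequencies (altered samples / total samples), sorted decreasing.
#'
#' @slot labels Character matrix, genes x samples, values from
#'   [mechanismLabels()].
#' @slot biallelic Logical matrix of the same shape.
#' @slot frequency Named numeric vector of per-gene alteration frequencies.
#' @export
setClass("CohortMatrix", slots = c(
    labels = "matrix", biallelic = "matrix", frequency = "numeric"))

setValidity("CohortMatrix", function(object) {
    if (!identical(dim(object@labels), dim(object@biallelic)))
        return("labels and biallelic must have identical dimensions")
    if (!all(object@labels %in% mechanismLabels()))
        return("labels outside the mechanism vocabulary")
    if (length(object@frequency) != nrow(object@labels))
        return("one frequency per gene required")
    TRUE
})

#' Mechanism label vocabulary for integrated gene-sample alterations
#' @return Character vector of the valid `mechanism_label` values.
#' @export
mechanismLabels <- function() {
    c("multiple_mutations", "mutation_plus_deletion", "mutation_plus_cnloh",
      "mutant_allele_amplified", "deep_deletion", "amplification",
      "single_hit", "none")
}

#' Copy-state vocabulary
#' @return Character vector of copy-state classes, ordered from loss to gain.
#' @export
copyStates <- function() {
    c("deep_deletion", "shallow_deletion", "neutral", "gain", "amplification")
}

## Event vocabulary of the simulator's per-gene driver table.
eventTypes <- function() {
    c("none", "single_mut", "multi_mut", "mut_cnloh", "mut_shallow",
      "deep_del", "amp", "gain", "mut_amp")
}

setMethod("show", "PanelDesign", function(object) {
    gr <- object@targets
    cat("PanelDesign:", length(gr), "target intervals,",
        length(unique(mcols(gr)$gene)), "genes,",
        length(seqlevelsInUse(gr)), "chromosomes\n")
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0(
        "SimConfig: %d samples (%d paired), depth %g (phi %g), ",
        "log2 noise sd %g,\n  het SNP density %g/kb, purity [%g, %g], ",
        "bin %d bp, seed %d\n"),
        object@nSamples, object@nPaired, object@meanDepth,
        object@depthDispersion, object@log2NoiseSd, object@hetSnpDensity,
        object@purityRange[1], object@purityRange[2], object@binSize,
        object@seed))
})

setMethod("show", "TumorTruth", function(object) {
    cat(sprintf("TumorTruth %s: purity %.2f, %d segments, %d variants%s\n",
                object@sampleId, object@purity, length(object@segments),
                length(object@variants),
                if (object@hasMatchedNormal) ", matched normal" else ""))
})

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort:", length(object@truth), "samples,",
        nrow(object@coverage), "coverage bins,",
        nrow(object@tumorVariants), "tumor variant calls\n")
})

setMethod("show", "CohortMatrix", function(object) {
    cat("CohortMatrix:", nrow(object@labels), "genes x",
        ncol(object@labels), "samples\n")
    top <- head(object@frequency, 5L)
    cat("  top frequencies:",
        paste(sprintf("%s %.2f", names(top), top), collapse = ", "), "\n")
})

## ---- accessors ----

#' @describeIn PanelDesign-class Target intervals as a GRanges.
#' @param object,x A `PanelDesign`.
#' @export
setGeneric("panelTargets", function(object) standardGeneric("panelTargets"))
#' @export
setMethod("panelTargets", "PanelDesign", function(object) object@targets)

#' @describeIn PanelDesign-class Unique gene symbols on the panel.
#' @export
setGeneric("panelGenes", function(object) standardGeneric("panelGenes"))
#' @export
setMethod("panelGenes", "PanelDesign", function(object)
    unique(as.character(mcols(object@targets)$gene)))

#' Sample identifier accessor
#' @param object A `TumorTruth`.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @export
setMethod("sampleId", "TumorTruth", function(object) object@sampleId)

#' Tumor purity accessor
#' @param object A `TumorTruth`.
#' @export
setGeneric("purity", function(object) standardGeneric("purity"))
#' @export
setMethod("purity", "TumorTruth", function(object) object@purity)

#' Truth segments accessor
#' @param object A `TumorTruth`.
#' @export
setGeneric("truthSegments", function(object) standardGeneric("truthSegments"))
#' @export
setMethod("truthSegments", "TumorTruth", function(object) object@segments)

#' Truth variants accessor
#' @param object A `TumorTruth`.
#' @export
setGeneric("truthVariants", function(object) standardGeneric("truthVariants"))
#' @export
setMethod("truthVariants", "TumorTruth", function(object) object@variants)

#' Cohort truth accessor
#' @param object A `SyntheticCohort`.
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(object) object@truth)

#' Coverage experiment accessor
#' @param object A `SyntheticCohort`.
#' @export
setGeneric("cohortCoverage", function(object) standardGeneric("cohortCoverage"))
#' @export
setMethod("cohortCoverage", "SyntheticCohort", function(object) object@coverage)

#' Observed tumor variant table accessor
#' @param object A `SyntheticCohort`.
#' @export
setGeneric("tumorVariants", function(object) standardGeneric("tumorVariants"))
#' @export
setMethod("tumorVariants", "SyntheticCohort", function(object) object@tumorVariants)

#' Observed matched-normal variant table accessor
#' @param object A `SyntheticCohort`.
#' @export
setGeneric("normalVariants", function(object) standardGeneric("normalVariants"))
#' @export
setMethod("normalVariants", "SyntheticCohort", function(object) object@normalVariants)

#' Mechanism-label matrix accessor
#' @param object A `CohortMatrix`.
#' @export
setGeneric("alterationLabels", function(object) standardGeneric("alterationLabels"))
#' @export
setMethod("alterationLabels", "CohortMatrix", function(object) object@labels)

#' Biallelic-flag matrix accessor
#' @param object A `CohortMatrix`.
#' @export
setGeneric("biallelicFlags", function(object) standardGeneric("biallelicFlags"))
#' @export
setMethod("biallelicFlags", "CohortMatrix", function(object) object@biallelic)

#' Per-gene alteration frequency accessor
#' @param object A `CohortMatrix`.
#' @export
setGeneric("alterationFrequency", function(object) standardGeneric("alterationFrequency"))
#' @export
setMethod("alterationFrequency", "CohortMatrix", function(object) object@frequency)

#' Construct a panel design
#'
#' @param chrom,start,end,gene Vectors describing target intervals (1-based,
#'   closed coordinates, the GRanges convention), or `chrom` may be a GRanges
#'   with a `gene` metadata column.
#' @return A [PanelDesign-class].
#' @examples
#' panelDesign(c("chr1", "chr1"), c(1001, 5001), c(2000, 6000),
#'             c("GENE1", "GENE2"))
#' @export
panelDesign <- function(chrom, start = NULL, end = NULL, gene = NULL) {
    if (is(chrom, "GRanges")) {
        gr <- chrom
    } else {
        gr <- GRanges(chrom, IRanges(start, end), gene = gene)
    }
    gr <- GenomicRanges::sort(gr)
    new("PanelDesign", targets = gr)
}
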
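## Synthetic tumor cohort simulator.  Emits observed coverage log2 ratios,
## raw depths and variant tables with the statistical structure the
## downstream stages assume, alongside full ground truth for recovery
## scoring.

#' Expected variant allele frequency under the tumor admixture model
#'
#' For a locus inside a segment with `totalCopies` total copies per tumor
#' cell, of which `multiplicity` carry the alternate allele, in a sample of
#' purity `purity` (admixed with diploid normal cells carrying
#' `germlineCopiesInNormal` alt copies), the expected VAF is
#' \deqn{\frac{p\,m + (1-p)\,g}{p\,C_T + (1-p)\,2}}
#' clipped to \[0, 1\].
#'
#' @param purity Tumor cell fraction in \[0, 1\].
#' @param totalCopies Total copy number of the segment in tumor cells.
#' @param multiplicity Copies per tumor cell carrying the alt allele.
#' @param germlineCopiesInNormal 0 for somatic variants, 1 for a germline
#'   heterozygote.
#' @return Expected VAF (vectorized over all arguments).
#' @examples
#' expectedVaf(1, 2, 1, 1)    # balanced heterozygote: 0.5
#' expectedVaf(1, 2, 2, 1)    # CN-LOH retaining the alt allele: 1
#' expectedVaf(0.5, 1, 1, 0)  # somatic, hemizygous, 50% purity: 1/3
#' @export
expectedVaf <- function(purity, totalCopies, multiplicity,
                        germlineCopiesInNormal) {
    stopifnot(all(purity >= 0 & purity <= 1),
              all(multiplicity <= totalCopies),
              all(multiplicity >= 0),
              all(germlineCopiesInNormal %in% c(0L, 1L)))
    den <- purity * totalCopies + (1 - purity) * 2
    if (any(den <= 0))
        stop("degenerate locus: zero DNA content ",
             "(purity 1 with totalCopies 0 and no normal contamination)")
    pmin(pmax((purity * multiplicity +
               (1 - purity) * germlineCopiesInNormal) / den, 0), 1)
}

#' Default per-gene driver event table
#'
#' One row per panel gene with its functional role and a probability
#' distribution over simulated event types: `none`, `single_mut`,
#' `multi_mut`, `mut_cnloh` (mutation duplicated by copy-neutral LOH),
#' `mut_shallow` (mutation plus one-copy loss), `deep_del` (homozygous
#' deletion), `amp` (amplification to >= 5 copies), `gain` (3--4 copies) and
#' `mut_amp` (amplified mutant allele).  Tumor suppressors favor truncating
#' second hits; oncogenes favor hotspot mutations and copy gains.  All
#' probabilities are configuration, not estimates of any real cohort.
#'
#' @return A data.frame with columns `gene`, `role` and one column per event
#'   type summing to 1 within each row.
#' @export
defaultDriverTable <- function() {
    tsg <- c("TP53", "FAT1", "NOTCH1", "KMT2C", "CDKN2A", "KMT2D", "CASP8",
             "NF1", "PTEN", "SMAD4", "AJUBA", "NSD1")
    onc <- c("CCND1", "PIK3CA", "EGFR", "ERBB2", "MYC", "FGFR1", "TERT",
             "MDM2", "HRAS", "TP63", "MET", "BIRC2")
    genes <- c(tsg, onc)
    role <- c(rep("tumor_suppressor", length(tsg)),
              rep("oncogene", length(onc)))
    p <- matrix(0, nrow = length(genes), ncol = length(eventTypes()),
                dimnames = list(genes, eventTypes()))
    ## tumor suppressors: second hits by deletion or CN-LOH
    p[tsg, ] <- matrix(rep(c(none = 0.55, single_mut = 0.08, multi_mut = 0.08,
                             mut_cnloh = 0.10, mut_shallow = 0.09,
                             deep_del = 0.05, amp = 0, gain = 0.05,
                             mut_amp = 0), length(tsg)),
                       nrow = length(tsg), byrow = TRUE)
    ## oncogenes: activation by hotspot mutation or copy gain
    p[onc, ] <- matrix(rep(c(none = 0.60, single_mut = 0.10, multi_mut = 0,
                             mut_cnloh = 0, mut_shallow = 0,
                             deep_del = 0, amp = 0.12, gain = 0.13,
                             mut_amp = 0.05), length(onc)),
                       nrow = length(onc), byrow = TRUE)
    data.frame(gene = genes, role = role, p, row.names = NULL,
               check.names = FALSE)
}

#' Default synthetic panel
#'
#' 24 recurrently altered head-and-neck cancer genes placed on their true
#' chromosomes at synthetic coordinates, one contiguous 16 kb target per gene
#' (40 bins of 400 bp).  Sex chromosomes are omitted.
#'
#' @param targetWidth Width of each gene target in bp.
#' @return A [PanelDesign-class].
#' @export
defaultPanel <- function(targetWidth = 16000L) {
    chrom <- c(TP53 = "chr17", FAT1 = "chr4", NOTCH1 = "chr9",
               KMT2C = "chr7", CDKN2A = "chr9", KMT2D = "chr12",
               CASP8 = "chr2", NF1 = "chr17", PTEN = "chr10",
               SMAD4 = "chr18", AJUBA = "chr14", NSD1 = "chr5",
               CCND1 = "chr11", PIK3CA = "chr3", EGFR = "chr7",
               ERBB2 = "chr17", MYC = "chr8", FGFR1 = "chr8",
               TERT = "chr5", MDM2 = "chr12", HRAS = "chr11",
               TP63 = "chr3", MET = "chr7", BIRC2 = "chr11")
    genes <- names(chrom)
    idx <- unlist(lapply(split(seq_along(genes), chrom), seq_along))
    names(idx) <- unlist(split(genes, chrom))
    start <- 1e6 + (idx[genes] - 1L) * 5e6
    panelDesign(unname(chrom), unname(start),
                unname(start + targetWidth - 1L), genes)
}

#' Build a simulation configuration
#'
#' @param nSamples,nPaired Cohort size and number of matched-normal pairs.
#' @param meanDepth Mean on-target depth.
#' @param depthDispersion Negative-binomial dispersion phi; 0 for
#'   deterministic depths.
#' @param log2NoiseSd Gaussian noise SD on coverage log2 ratios; together
#'   with `depthDispersion = 0`, 0 switches the generator to the fully
#'   deterministic noise-free limit (rounded expected allele counts instead
#'   of binomial draws).
#' @param hetSnpDensity Germline heterozygous SNPs per kb of target.
#' @param purityRange Interval tumor purity is drawn from.
#' @param driverTable See [defaultDriverTable()].
#' @param binSize Coverage bin size (bp).
#' @param seed Base seed for [generateCohort()].
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nSamples = 48L, nPaired = 13L, meanDepth = 150,
                      depthDispersion = 0.05, log2NoiseSd = 0.15,
                      hetSnpDensity = 1.5, purityRange = c(0.6, 0.9),
                      driverTable = defaultDriverTable(),
                      binSize = 400L, seed = 1L) {
    new("SimConfig", nSamples = as.integer(nSamples),
        nPaired = as.integer(nPaired), meanDepth = meanDepth,
        depthDispersion = depthDispersion, log2NoiseSd = log2NoiseSd,
        hetSnpDensity = hetSnpDensity, purityRange = as.numeric(purityRange),
        driverTable = driverTable, binSize = as.integer(binSize),
        seed = as.integer(seed))
}

## Floor applied to the copy-ratio before log2 so homozygous deletions give a
## finite ratio; matches the clamp used when estimating copies back.
.LOG2_FLOOR <- -8

.isNoiseFree <- function(config)
    config@log2NoiseSd == 0 && config@depthDispersion == 0

## negative-binomial depth around mu with dispersion phi (variance mu+phi*mu^2)
.drawDepth <- function(n, mu, phi) {
    if (phi == 0) return(rep(as.integer(round(mu)), n))
    rnbinom(n, size = 1 / phi, mu = mu)
}

## per-gene event layout: returns total/minor copies, somatic variant plan
.eventLayout <- function(event) {
    switch(event,
        none       = list(total = 2L, minor = 1L, muts = integer(0)),
        single_mut = list(total = 2L, minor = 1L, muts = 1L),
        multi_mut  = list(total = 2L, minor = 1L, muts = c(1L, 1L)),
        mut_cnloh  = list(total = 2L, minor = 0L, muts = 2L),
        mut_shallow= list(total = 1L, minor = 0L, muts = 1L),
        deep_del   = list(total = 0L, minor = 0L, muts = integer(0)),
        amp        = list(total = NA_integer_, minor = 1L, muts = integer(0)),
        gain       = list(total = NA_integer_, minor = 1L, muts = integer(0)),
        mut_amp    = list(total = 4L, minor = 1L, muts = 3L),
        stop("unknown event type: ", event))
}

#' Generate a synthetic tumor cohort
#'
#' For every sample the generator draws a purity, assigns one event per panel
#' gene from the driver table, places germline heterozygous SNPs as a
#' homogeneous Poisson process along the targets (population allele
#' frequencies from a mixture spanning both sides of the downstream
#' informativeness filter), and emits
#' \itemize{
#'   \item per-bin coverage log2 ratios
#'     \eqn{\log_2((p C_T + (1-p)2)/2)} plus Gaussian noise, and raw
#'     negative-binomial depths,
#'   \item a tumor variant table with binomial alt counts at the
#'     [expectedVaf()] of each locus,
#'   \item for paired samples, a matched-normal variant table with germline
#'     variants at their diploid VAFs.
#' }
#' With `log2NoiseSd = 0` and `depthDispersion = 0` every quantity is the
#' rounded expectation (the noise-free limit).  Identical seeds give
#' identical cohorts.
#'
#' @param config A [SimConfig-class].
#' @param panel A [PanelDesign-class].
#' @return A [SyntheticCohort-class].
#' @export
generateCohort <- function(config = simConfig(), panel = defaultPanel()) {
    validObject(config); validObject(panel)
    targets <- panelTargets(panel)
    if (length(targets) == 0L) stop("empty panel")
    dt <- config@driverTable
    missingGenes <- setdiff(panelGenes(panel), dt$gene)
    if (length(missingGenes))
        dt <- rbind(dt, data.frame(gene = missingGenes, role = "other",
            matrix(rep(c(1, rep(0, length(eventTypes()) - 1L)),
                       length(missingGenes)), ncol = length(eventTypes()),
                   byrow = TRUE, dimnames = list(NULL, eventTypes())),
            check.names = FALSE))
    rownames(dt) <- dt$gene
    nf <- .isNoiseFree(config)

    set.seed(config@seed)
    bins <- panelBins(panel, config@binSize)
    nb <- length(bins)
    ids <- sprintf("S%02d", seq_len(config@nSamples))
    paired <- seq_len(config@nSamples) <= config@nPaired

    depthM <- matrix(NA_real_, nb, config@nSamples, dimnames = list(NULL, ids))
    lrM <- depthM
    normDepthM <- depthM
    truth <- vector("list", config@nSamples)
    tumTabs <- list(); nrmTabs <- list()

    for (s in seq_len(config@nSamples)) {
        p <- if (diff(config@purityRange) == 0) config@purityRange[1]
             else runif(1, config@purityRange[1], config@purityRange[2])
        events <- vapply(panelGenes(panel), function(g)
            sample(eventTypes(), 1L, prob = as.numeric(dt[g, eventTypes()])),
            character(1))
        sim <- .simulateSample(ids[s], p, events, dt, targets, bins, config, nf,
                               paired[s])
        truth[[s]] <- sim$truth
        depthM[, s] <- sim$depth
        lrM[, s] <- sim$log2ratio
        if (paired[s]) normDepthM[, s] <- sim$normalDepth
        tumTabs[[s]] <- sim$tumorTab
        if (paired[s]) nrmTabs[[s]] <- sim$normalTab
    }

    se <- SummarizedExperiment(
        assays = list(depth = depthM, log2ratio = lrM,
                      normalDepth = normDepthM),
        rowRanges = bins,
        colData = DataFrame(sampleId = ids, paired = paired, row.names = ids))
    new("SyntheticCohort", coverage = se,
        tumorVariants = do.call(rbind, tumTabs),
        normalVariants = if (length(nrmTabs)) do.call(rbind, nrmTabs)
                         else .emptyVariantTable(),
        truth = truth, panel = panel, config = config)
}

.simulateSample <- function(id, p, events, dt, targets, bins, config, nf,
                            paired) {
    genes <- as.character(mcols(targets)$gene)
    total <- integer(length(targets)); minor <- integer(length(targets))
    rows <- list()
    for (k in seq_along(targets)) {
        g <- genes[k]
        lay <- .eventLayout(events[g])
        if (events[g] == "amp") lay$total <- sample(5:8, 1L)
        if (events[g] == "gain") lay$total <- sample(3:4, 1L)
        total[k] <- lay$total; minor[k] <- lay$minor
        role <- dt[g, "role"]

        ## somatic driver mutations
        for (m in lay$muts) {
            pos <- start(targets)[k] +
                sample.int(width(targets)[k], 1L) - 1L
            if (role == "tumor_suppressor") {
                ann <- if (runif(1) < 0.7) "truncating" else "missense_pathogenic"
                hot <- FALSE
            } else {
                ann <- "missense_pathogenic"; hot <- TRUE
            }
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = as.character(seqnames(targets))[k], pos = pos,
                gene = g, origin = "somatic", multiplicity = m,
                populationAf = 0, annotation = ann, hotspot = hot)
        }
        ## occasional benign somatic passenger
        if (runif(1) < 0.05) {
            pos <- start(targets)[k] + sample.int(width(targets)[k], 1L) - 1L
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = as.character(seqnames(targets))[k], pos = pos,
                gene = g, origin = "somatic", multiplicity = min(1L, total[k]),
                populationAf = 0,
                annotation = sample(c("silent", "missense_benign"), 1L),
                hotspot = FALSE)
        }
        ## germline heterozygous SNPs
        lam <- config@hetSnpDensity * width(targets)[k] / 1000
        nh <- if (nf) as.integer(round(lam)) else rpois(1, lam)
        if (nh > 0) {
            pos <- if (nf)
                start(targets)[k] +
                    as.integer(round(seq(0.5, nh - 0.5, by = 1) /
                               nh * width(targets)[k]))
            else sort(start(targets)[k] +
                      sample.int(width(targets)[k], nh) - 1L)
            u <- runif(nh)
            paf <- ifelse(u < 0.8, runif(nh, 0.01, 0.5),
                   ifelse(u < 0.9, runif(nh, 1e-6, 1e-4),
                          runif(nh, 0.951, 0.999)))
            onMajor <- runif(nh) < 0.5
            mult <- ifelse(onMajor, total[k] - minor[k], minor[k])
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = as.character(seqnames(targets))[k], pos = pos,
                gene = g, origin = "germline", multiplicity = mult,
                populationAf = paf,
                annotation = "silent", hotspot = FALSE)
        }
    }
    vtab <- do.call(rbind, rows)
    ## two variants can never share a genomic position; nudge collisions
    key <- paste(vtab$chrom, vtab$pos)
    while (anyDuplicated(key)) {
        i <- which(duplicated(key))
        vtab$pos[i] <- vtab$pos[i] + 1L
        key <- paste(vtab$chrom, vtab$pos)
    }
    vtab <- vtab[order(vtab$chrom, vtab$pos), , drop = FALSE]
    variants <- GRanges(vtab$chrom, IRanges(vtab$pos, vtab$pos),
                        gene = vtab$gene, origin = vtab$origin,
                        multiplicity = as.integer(vtab$multiplicity),
                        populationAf = vtab$populationAf,
                        annotation = vtab$annotation, hotspot = vtab$hotspot)
    segs <- granges(targets)
    mcols(segs)$gene <- genes
    mcols(segs)$totalCopies <- total
    mcols(segs)$minorCopies <- minor
    tr <- new("TumorTruth", sampleId = id, purity = p, segments = segs,
              variants = variants, hasMatchedNormal = paired)

    ## observed coverage over bins
    binGene <- as.character(mcols(bins)$gene)
    totalByGene <- setNames(total, genes)
    binTotal <- totalByGene[binGene]
    factor <- (p * binTotal + (1 - p) * 2) / 2
    lr <- pmax(log2(pmax(factor, 2^.LOG2_FLOOR)), .LOG2_FLOOR)
    if (!nf) lr <- lr + rnorm(length(lr), 0, config@log2NoiseSd)
    depth <- .drawDepth(length(lr), config@meanDepth, config@depthDispersion)
    depth <- as.integer(round(depth * factor))

    ## observed variant tables
    segIdx <- match(vtab$gene, genes)
    vt <- total[segIdx]
    gNorm <- ifelse(vtab$origin == "germline", 1L, 0L)
    den <- p * vt + (1 - p) * 2
    ev <- ifelse(den > 0,
                 pmin(pmax((p * vtab$multiplicity + (1 - p) * gNorm) / den,
                           0), 1), 0)
    vdepth <- .drawDepth(nrow(vtab), config@meanDepth, config@depthDispersion)
    vdepth <- as.integer(round(vdepth * pmax(den / 2, 0)))
    alt <- if (nf) as.integer(round(ev * vdepth))
           else rbinom(nrow(vtab), vdepth, ev)
    keep <- vdepth > 0 & alt > 0
    tumorTab <- data.frame(
        sampleId = id, chrom = vtab$chrom, pos = vtab$pos,
        ref = "A", alt = "T", gene = vtab$gene,
        depth = vdepth, altCount = alt, vaf = ifelse(vdepth > 0, alt / vdepth, NA),
        populationAf = vtab$populationAf,
        consequence = .annotationToConsequence(vtab$annotation),
        predictedClass = .annotationToPrediction(vtab$annotation),
        hotspot = vtab$hotspot, stringsAsFactors = FALSE)[keep, , drop = FALSE]
    rownames(tumorTab) <- NULL

    normalDepth <- NULL; normalTab <- NULL
    if (paired) {
        normalDepth <- .drawDepth(length(bins), config@meanDepth,
                                  config@depthDispersion)
        germ <- vtab$origin == "germline"
        nd <- .drawDepth(sum(germ), config@meanDepth, config@depthDispersion)
        nalt <- if (nf) as.integer(round(0.5 * nd))
                else rbinom(sum(germ), nd, 0.5)
        keepN <- nd > 0
        normalTab <- data.frame(
            sampleId = paste0(id, "N"), chrom = vtab$chrom[germ],
            pos = vtab$pos[germ], ref = "A", alt = "T",
            gene = vtab$gene[germ], depth = nd, altCount = nalt,
            vaf = ifelse(nd > 0, nalt / nd, NA),
            populationAf = vtab$populationAf[germ],
            consequence = "silent", predictedClass = NA_character_,
            hotspot = FALSE, stringsAsFactors = FALSE)[keepN, , drop = FALSE]
        rownames(normalTab) <- NULL
    }
    list(truth = tr, depth = depth, log2ratio = lr,
         normalDepth = normalDepth, tumorTab = tumorTab,
         normalTab = normalTab)
}

.annotationToConsequence <- function(ann) {
    vapply(ann, function(a) switch(a,
        truncating = sample(c("nonsense", "frameshift", "splice_site"), 1L),
        missense_pathogenic = "missense",
        missense_benign = "missense",
        silent = "silent", "other"), character(1), USE.NAMES = FALSE)
}

.annotationToPrediction <- function(ann) {
    ifelse(ann == "missense_pathogenic", "pathogenic",
    ifelse(ann == "missense_benign", "benign", NA_character_))
}

.emptyVariantTable <- function() {
    data.frame(sampleId = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               gene = character(0), depth = integer(0),
               altCount = integer(0), vaf = numeric(0),
               populationAf = numeric(0), consequence = character(0),
               predictedClass = character(0), hotspot = logical(0),
               stringsAsFactors = FALSE)
}

#' Tile a panel into fixed-width coverage bins
#'
#' @param panel A [PanelDesign-class].
#' @param binSize Bin width in bp; the last bin of a target absorbs any
#'   remainder shorter than `binSize`.
#' @return GRanges of bins carrying the parent `gene`.
#' @export
panelBins <- function(panel, binSize = 400L) {
    targets <- panelTargets(panel)
    pieces <- lapply(seq_along(targets), function(k) {
        s <- seq(start(targets)[k], end(targets)[k], by = binSize)
        e <- pmin(s + binSize - 1L, end(targets)[k])
        ## merge a trailing sliver into the previous bin
        if (length(s) > 1L && (e[length(e)] - s[length(s)] + 1L) < binSize / 2) {
            e[length(e) - 1L] <- e[length(e)]
            s <- s[-length(s)]; e <- e[-length(e)]
        }
        data.frame(chrom = as.character(seqnames(targets))[k],
                   start = s, end = e, gene = mcols(targets)$gene[k])
    })
    df <- do.call(rbind, pieces)
    GenomicRanges::sort(GRanges(df$chrom, IRanges(df$start, df$end),
                                gene = df$gene))
}

## ---- truth serialization ----

#' Write cohort ground truth to JSON
#'
#' @param truth List of [TumorTruth-class] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @seealso [readTruth()]
#' @export
writeTruth <- function(truth, path) {
    if (length(truth) == 0L) stop("truth must be non-empty")
    obj <- lapply(truth, function(t) list(
        sampleId = t@sampleId, purity = t@purity,
        hasMatchedNormal = t@hasMatchedNormal,
        segments = .grToDf(t@segments),
        variants = .grToDf(t@variants)))
    json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                             null = "null")
    writeLines(json, path)
    invisible(path)
}

#' Read cohort ground truth from JSON
#' @param path File written by [writeTruth()].
#' @return List of [TumorTruth-class] objects.
#' @export
readTruth <- function(path) {
    obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
    lapply(seq_len(nrow(obj)), function(i) {
        segs <- .dfToGr(obj$segments[[i]],
                        intCols = c("totalCopies", "minorCopies"))
        vars <- .dfToGr(obj$variants[[i]], intCols = "multiplicity")
        new("TumorTruth", sampleId = obj$sampleId[i], purity = obj$purity[i],
            segments = segs, variants = vars,
            hasMatchedNormal = obj$hasMatchedNormal[i])
    })
}

.grToDf <- function(gr) {
    if (length(gr) == 0L) return(data.frame())
    cbind(data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr)),
          as.data.frame(mcols(gr)))
}

.dfToGr <- function(df, intCols = character(0)) {
    if (is.null(df) || NROW(df) == 0L) return(GRanges())
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    meta <- df[, setdiff(names(df), c("chrom", "start", "end")), drop = FALSE]
    for (ic in intersect(intCols, names(meta)))
        meta[[ic]] <- as.integer(meta[[ic]])
    mcols(gr) <- meta
    gr
}

## ---- truth bookkeeping for recovery scoring ----

#' Truth-derived gene-sample alteration labels
#'
#' Applies the same mechanism-priority rule used by [integrateGeneSample()]
#' directly to the simulator's ground truth (copy numbers, planted mutation
#' counts and multiplicities), yielding the matrix an ideal analysis would
#' recover.  Benign/silent planted variants are ignored, mirroring the
#' filtering stage.
#'
#' @param truth List of [TumorTruth-class] objects.
#' @param genes Genes to tabulate (default: all genes in the first sample's
#'   segments).
#' @return data.frame with one row per (gene, sample): `gene`, `sampleId`,
#'   `totalCopies`, `minorCopies`, `nMutations`, `maxMultiplicity`, `label`,
#'   `biallelic`, `actionable`.
#' @export
truthAlterations <- function(truth, genes = NULL) {
    stopifnot(length(truth) > 0L)
    if (is.null(genes))
        genes <- unique(as.character(mcols(truth[[1L]]@segments)$gene))
    out <- lapply(truth, function(t) {
        seg <- t@segments
        segGene <- as.character(mcols(seg)$gene)
        v <- t@variants
        m <- mcols(v)
        isDriver <- m$origin == "somatic" &
            m$annotation %in% c("truncating", "missense_pathogenic")
        do.call(rbind, lapply(genes, function(g) {
            k <- match(g, segGene)
            tc <- mcols(seg)$totalCopies[k]
            mc <- mcols(seg)$minorCopies[k]
            sel <- isDriver & m$gene == g & m$multiplicity > 0
            nMut <- sum(sel)
            maxMult <- if (nMut) max(m$multiplicity[sel]) else 0L
            lab <- .truthLabel(tc, mc, nMut, maxMult)
            data.frame(gene = g, sampleId = t@sampleId,
                       totalCopies = tc, minorCopies = mc,
                       nMutations = nMut, maxMultiplicity = maxMult,
                       label = lab,
                       biallelic = lab %in% .BIALLELIC_LABELS,
                       actionable = nMut > 0 || tc >= 5 || tc == 0)
        }))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

.BIALLELIC_LABELS <- c("multiple_mutations", "mutation_plus_deletion",
                       "mutation_plus_cnloh", "mutant_allele_amplified",
                       "deep_deletion")

.truthLabel <- function(total, minor, nMut, maxMult) {
    if (total == 0L) return("deep_deletion")
    if (nMut >= 2L) return("multiple_mutations")
    if (nMut == 1L) {
        if (total == 1L) return("mutation_plus_deletion")
        if (total == 2L && minor == 0L) return("mutation_plus_cnloh")
        if (total >= 3L && maxMult >= 1.5) return("mutant_allele_amplified")
        return("single_hit")
    }
    if (total >= 5L) return("amplification")
    "none"
}
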
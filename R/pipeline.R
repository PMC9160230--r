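## End-to-end pipeline: simulate (or load) -> copy number -> allelic
## imbalance -> variant filtering -> gene integration -> actionability
## [-> cohort comparison], with a summary JSON recording parameters and
## per-stage counts.

.PIPELINE_KEYS <- c("seed", "simulate", "sim", "panelBed", "coveragePath",
                    "tumorVariantPath", "normalVariantPath", "usePurity",
                    "cnv", "loh", "filter", "integration", "actionability",
                    "compare", "logLevel")

#' Build a pipeline configuration
#'
#' Every stage parameter has a default; unknown keys are rejected.  Supply
#' either `simulate = TRUE` (with optional overrides in `sim`, passed to
#' [simConfig()]) or input paths for a real cohort.
#'
#' @param ... Named overrides of the default configuration.  Recognized
#'   keys: `seed`, `simulate`, `sim` (list of [simConfig()] arguments),
#'   `panelBed`, `coveragePath`, `tumorVariantPath`, `normalVariantPath`,
#'   `usePurity` (use simulator truth purity for copy estimation),
#'   `cnv` (alpha, nPerm, minBins, recenter), `loh` (threshold, afRange,
#'   minDepth, homCutoffs, shiftThreshold), `filter` ([filterConfig()]
#'   arguments), `integration` (multThreshold), `actionability`
#'   ([actionabilityRules()] arguments), `compare` (enabled, group1, group2),
#'   `logLevel`.
#' @return Named list, validated.
#' @export
pipelineConfig <- function(...) {
    defaults <- list(
        seed = 1L, simulate = TRUE, sim = list(), panelBed = NULL,
        coveragePath = NULL, tumorVariantPath = NULL,
        normalVariantPath = NULL, usePurity = TRUE,
        cnv = list(alpha = 0.01, nPerm = 1000L, minBins = 3L,
                   recenter = "auto"),
        loh = list(threshold = 0.15, afRange = c(1e-4, 0.95), minDepth = 30,
                   homCutoffs = c(0.05, 0.95), shiftThreshold = 0.15),
        filter = list(), integration = list(multThreshold = 1.5),
        actionability = list(),
        compare = list(enabled = FALSE, group1 = NULL, group2 = NULL),
        logLevel = "info")
    over <- list(...)
    unknown <- setdiff(names(over), .PIPELINE_KEYS)
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    for (k in names(over)) {
        if (is.list(defaults[[k]]) && is.list(over[[k]]))
            defaults[[k]] <- utils::modifyList(defaults[[k]], over[[k]])
        else defaults[[k]] <- over[[k]]
    }
    defaults
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose top-level keys follow [pipelineConfig()].
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(path) {
    do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the integrated profiling pipeline
#'
#' Executes simulate -> cnv -> loh -> filter -> integrate -> actionable
#' (-> compare) and writes segments (SEG), LOH calls, the gene-sample
#' alteration matrix, actionability verdicts, optional comparison results, a
#' summary JSON (parameters, versions, per-stage record counts; no
#' timestamps, so identical seeds give byte-identical output) and a log.
#'
#' @param config From [pipelineConfig()].
#' @param outDir Output directory, created if needed.
#' @return Invisibly, a list with the main in-memory results (`cohort`,
#'   `matrix`, `alterations`, `actionable`, `summary`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
    stopifnot(is.list(config))
    for (p in c("panelBed", "coveragePath", "tumorVariantPath",
                "normalVariantPath"))
        if (!is.null(config[[p]]) && !file.exists(config[[p]]))
            stop("missing input path (", p, "): ", config[[p]])
    if (!config$simulate && is.null(config$tumorVariantPath))
        stop("either simulate = TRUE or input paths are required")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logLines <- character(0)
    note <- function(...) {
        line <- paste0(...)
        logLines <<- c(logLines, line)
        if (identical(config$logLevel, "info")) message(line)
    }
    counts <- list()

    ## stage: simulate
    simArgs <- utils::modifyList(list(seed = config$seed), config$sim)
    sc <- do.call(simConfig, simArgs)
    panel <- if (!is.null(config$panelBed)) readPanel(config$panelBed)
             else defaultPanel()
    cohort <- generateCohort(sc, panel)
    writeTruth(cohortTruth(cohort), file.path(outDir, "truth.json"))
    note("simulate: ", sc@nSamples, " samples, ",
         nrow(tumorVariants(cohort)), " tumor variant calls")
    counts$simulate <- list(nSamples = sc@nSamples,
                            nTumorVariants = nrow(tumorVariants(cohort)))

    se <- cohortCoverage(cohort)
    bins <- SummarizedExperiment::rowRanges(se)
    ids <- colnames(se)
    truth <- cohortTruth(cohort)
    purities <- vapply(truth, purity, numeric(1))
    roles <- setNames(sc@driverTable$role, sc@driverTable$gene)

    ## stage: cnv
    segsBySample <- list()
    for (i in seq_along(ids)) {
        pu <- if (isTRUE(config$usePurity)) purities[i] else NULL
        seg <- segmentCoverage(bins, assay(se, "log2ratio")[, i],
                               purity = pu, alpha = config$cnv$alpha,
                               nPerm = config$cnv$nPerm,
                               minBins = config$cnv$minBins,
                               seed = config$seed + 1000L + i)
        if (!is.null(config$cnv$recenter) &&
            !identical(config$cnv$recenter, "none"))
            seg <- recenterSegments(seg, config$cnv$recenter, purity = pu)
        mcols(seg)$sample <- ids[i]
        segsBySample[[ids[i]]] <- seg
    }
    allSegs <- do.call(c, unname(segsBySample))
    writeSegments(allSegs, file.path(outDir, "segments.seg"))
    note("cnv: ", length(allSegs), " segments across ", length(ids),
         " samples")
    counts$cnv <- list(nSegments = length(allSegs))

    ## stage: loh
    tv <- tumorVariants(cohort)
    nv <- normalVariants(cohort)
    lohBySample <- list()
    for (i in seq_along(ids)) {
        v <- tv[tv$sampleId == ids[i], , drop = FALSE]
        hets <- selectInformative(v, afRange = config$loh$afRange,
                                  minDepth = config$loh$minDepth,
                                  homCutoffs = config$loh$homCutoffs)
        dev <- callImbalance(hets, threshold = config$loh$threshold,
                             alpha = config$cnv$alpha,
                             nPerm = config$cnv$nPerm,
                             minBins = config$cnv$minBins,
                             seed = config$seed + 2000L + i)
        nvi <- nv[nv$sampleId == paste0(ids[i], "N"), , drop = FALSE]
        if (nrow(nvi) > 0L)
            dev <- pairedShift(nvi, v, dev,
                               shiftThreshold = config$loh$shiftThreshold)$segments
        lohBySample[[ids[i]]] <- classifyLoh(dev, segsBySample[[ids[i]]])
    }
    lohAll <- do.call(rbind, lapply(ids, function(s)
        cbind(sampleId = s, lohBySample[[s]])))
    write.table(lohAll, file.path(outDir, "loh_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("loh: ", sum(lohAll$imbalance), " imbalanced segments of ",
         nrow(lohAll))
    counts$loh <- list(nSegments = nrow(lohAll),
                       nImbalanced = sum(lohAll$imbalance))

    ## stage: filter
    fc <- do.call(filterConfig, config$filter)
    filtered <- list()
    for (i in seq_along(ids)) {
        v <- tv[tv$sampleId == ids[i], , drop = FALSE]
        nvi <- nv[nv$sampleId == paste0(ids[i], "N"), , drop = FALSE]
        f <- filterCommon(v, fc,
                          normalVariants = if (nrow(nvi)) nvi else NULL)
        f$pathogenicity <- classifyPathogenicity(
            f$consequence, f$predictedClass, f$hotspot,
            geneRole = ifelse(is.na(roles[f$gene]), "other", roles[f$gene]),
            treatTruncatingAsPathogenic = fc$treatTruncatingAsPathogenic)
        filtered[[ids[i]]] <- f
    }
    filteredAll <- do.call(rbind, filtered)
    rownames(filteredAll) <- NULL
    note("filter: ", nrow(tv), " in -> ", nrow(filteredAll), " out")
    counts$filter <- list(nIn = nrow(tv), nOut = nrow(filteredAll))

    ## stage: integrate
    mutSummary <- collapseToGene(filteredAll)
    alterations <- do.call(rbind, lapply(seq_along(ids), function(i) {
        pu <- if (isTRUE(config$usePurity)) purities[i] else NA
        integrateSample(
            mutSummary[mutSummary$sampleId == ids[i], , drop = FALSE],
            segsBySample[[ids[i]]], lohBySample[[ids[i]]],
            cohort@panel, ids[i], purity = pu)
    }))
    mat <- buildMatrix(alterations)
    write.table(
        data.frame(gene = rownames(alterationLabels(mat)),
                   frequency = alterationFrequency(mat),
                   alterationLabels(mat), check.names = FALSE),
        file.path(outDir, "cohort_matrix.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    note("integrate: ", sum(alterations$label != "none"),
         " altered gene-sample pairs")
    counts$integrate <- list(nAltered = sum(alterations$label != "none"),
                             nBiallelic = sum(alterations$biallelic))

    ## stage: actionable
    rules <- do.call(actionabilityRules, config$actionability)
    hp <- mutSummary[match(paste(alterations$gene, alterations$sampleId),
                           paste(mutSummary$gene, mutSummary$sampleId)), ]
    alterations$hasPathogenic <- ifelse(is.na(hp$hasPathogenic), FALSE,
                                        hp$hasPathogenic)
    alterations$hasHotspot <- ifelse(is.na(hp$hasHotspot), FALSE,
                                     hp$hasHotspot)
    actTab <- classifyActionableAll(alterations, rules)
    write.table(actTab, file.path(outDir, "actionability.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    frac <- cohortActionableFraction(actTab)
    note(sprintf("actionable: %.1f%% of samples carry >=1 actionable event",
                 100 * frac$fraction))
    counts$actionable <- list(fraction = frac$fraction,
                              perPathway = as.list(frac$perPathway))

    ## stage: compare (optional)
    comparison <- NULL
    if (isTRUE(config$compare$enabled)) {
        g1 <- config$compare$group1
        g2 <- config$compare$group2
        if (is.null(g1)) {
            half <- floor(length(ids) / 2)
            g1 <- ids[seq_len(half)]; g2 <- setdiff(ids, g1)
        }
        sub <- function(g) {
            a <- alterations[alterations$sampleId %in% g, , drop = FALSE]
            buildMatrix(a)
        }
        comparison <- compareCohorts(sub(g1), sub(g2))
        write.table(comparison, file.path(outDir, "comparison.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        counts$compare <- list(nGenes = nrow(comparison))
    }

    summary <- list(
        package = "PanelProfiler",
        version = as.character(utils::packageVersion("PanelProfiler")),
        seed = config$seed,
        parameters = config[setdiff(names(config), "logLevel")],
        counts = counts)
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = I(10),
                                null = "null", pretty = TRUE),
               file.path(outDir, "summary.json"))
    writeLines(logLines, file.path(outDir, "pipeline.log"))
    invisible(list(cohort = cohort, matrix = mat, alterations = actTab,
                   actionable = frac, comparison = comparison,
                   summary = summary))
}
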
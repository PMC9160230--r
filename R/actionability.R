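## Actionability rules: which integrated alterations qualify as candidate
## actionable/prognostic events, pathway grouping, and the cohort fraction
## with at least one qualifying alteration.

#' Default gene-to-pathway map
#'
#' Editable configuration grouping the panel genes into signalling pathways:
#' RTK/RAS/PI3K, cell cycle, DNA-damage repair, Notch/WNT, chromatin
#' modification, other.
#'
#' @return Named character vector, gene -> pathway label.
#' @export
defaultPathwayMap <- function() {
    c(PIK3CA = "RTK_RAS_PI3K", EGFR = "RTK_RAS_PI3K", ERBB2 = "RTK_RAS_PI3K",
      HRAS = "RTK_RAS_PI3K", KRAS = "RTK_RAS_PI3K", FGFR1 = "RTK_RAS_PI3K",
      FGFR3 = "RTK_RAS_PI3K", MET = "RTK_RAS_PI3K", PTEN = "RTK_RAS_PI3K",
      NF1 = "RTK_RAS_PI3K", PTPN11 = "RTK_RAS_PI3K",
      CDKN2A = "cell_cycle", CDKN2B = "cell_cycle", CCND1 = "cell_cycle",
      RB1 = "cell_cycle",
      TP53 = "DNA_repair", MDM2 = "DNA_repair", ATM = "DNA_repair",
      BRCA1 = "DNA_repair", BRCA2 = "DNA_repair",
      NOTCH1 = "Notch_WNT", FAT1 = "Notch_WNT", AJUBA = "Notch_WNT",
      KMT2C = "chromatin", KMT2D = "chromatin", NSD1 = "chromatin")
}

#' Actionability rule set
#'
#' Defaults mirror a strict clinical-reporting policy: pathogenic or hotspot
#' mutations qualify, amplifications only from 5 total copies (equivalently
#' at least 3 additional copies), deep deletions qualify, and shallow
#' deletions without a second hit are eliminated.
#'
#' @param minAmplificationCopies Lowest qualifying total copy number for an
#'   amplification (must be >= 3).
#' @param allowDeepDeletion Whether deep deletions qualify.
#' @param excludeShallowWithoutSecondHit Whether a shallow deletion with no
#'   mutation and no LOH second hit is excluded.
#' @param pathwayMap Named vector gene -> pathway.
#' @return Named list of rules.
#' @export
actionabilityRules <- function(minAmplificationCopies = 5L,
                               allowDeepDeletion = TRUE,
                               excludeShallowWithoutSecondHit = TRUE,
                               pathwayMap = defaultPathwayMap()) {
    if (minAmplificationCopies < 3L)
        stop("minAmplificationCopies must be >= 3")
    list(minAmplificationCopies = as.integer(minAmplificationCopies),
         allowDeepDeletion = allowDeepDeletion,
         excludeShallowWithoutSecondHit = excludeShallowWithoutSecondHit,
         pathwayMap = pathwayMap)
}

#' Assign a gene to a pathway
#'
#' @param gene Character vector of gene symbols.
#' @param map Named vector gene -> pathway (default [defaultPathwayMap()]).
#' @return Pathway labels; unmapped genes give `"other"`.
#' @export
assignPathway <- function(gene, map = defaultPathwayMap()) {
    out <- unname(map[gene])
    out[is.na(out)] <- "other"
    out
}

#' Classify one integrated alteration as actionable or excluded
#'
#' A pathogenic or hotspot mutation qualifies; an amplification to at least
#' `minAmplificationCopies` total copies qualifies; a deep deletion
#' qualifies; a shallow deletion without a mutation or LOH second hit is
#' excluded, as are VUS-only and unaltered records.  A pure function of the
#' record and the rules.
#'
#' @param alteration One-row data.frame (or list) with `gene`,
#'   `nMutations`, `copyNumber`, `copyState`, `lohMechanism`, `label` and
#'   optionally `hasPathogenic`/`hasHotspot` (both assumed TRUE for a
#'   mutation when absent).
#' @param rules From [actionabilityRules()].
#' @return List: `verdict` ("actionable"/"excluded"), `reason`, `pathway`.
#' @export
classifyActionable <- function(alteration, rules = actionabilityRules()) {
    a <- as.list(alteration)
    pathway <- assignPathway(a$gene, rules$pathwayMap)
    hasMut <- a$nMutations > 0
    qualMut <- hasMut &&
        (is.null(a$hasPathogenic) ||
         isTRUE(a$hasPathogenic) || isTRUE(a$hasHotspot))
    if (qualMut)
        return(list(verdict = "actionable",
                    reason = "pathogenic_or_hotspot_mutation",
                    pathway = pathway))
    if (!is.na(a$copyNumber) &&
        a$copyNumber >= rules$minAmplificationCopies)
        return(list(verdict = "actionable", reason = "amplification",
                    pathway = pathway))
    if (identical(a$copyState, "deep_deletion") && rules$allowDeepDeletion)
        return(list(verdict = "actionable", reason = "deep_deletion",
                    pathway = pathway))
    if (identical(a$copyState, "shallow_deletion") && !hasMut &&
        rules$excludeShallowWithoutSecondHit)
        return(list(verdict = "excluded",
                    reason = "shallow_deletion_without_second_hit",
                    pathway = pathway))
    if (hasMut)
        return(list(verdict = "excluded", reason = "vus_only",
                    pathway = pathway))
    list(verdict = "excluded", reason = "no_qualifying_alteration",
         pathway = pathway)
}

#' Classify a table of alterations
#'
#' @param alterations data.frame of gene-sample records (see
#'   [integrateSample()]).
#' @param rules From [actionabilityRules()].
#' @return `alterations` with `verdict`, `reason`, `pathway` columns.
#' @export
classifyActionableAll <- function(alterations, rules = actionabilityRules()) {
    res <- lapply(seq_len(nrow(alterations)), function(i)
        classifyActionable(alterations[i, , drop = FALSE], rules))
    alterations$verdict <- vapply(res, `[[`, character(1), "verdict")
    alterations$reason <- vapply(res, `[[`, character(1), "reason")
    alterations$pathway <- vapply(res, `[[`, character(1), "pathway")
    alterations
}

#' Fraction of samples with at least one actionable alteration
#'
#' @param alterations Classified table from [classifyActionableAll()].
#' @return List with `fraction` (overall), `perPathway` (named vector of
#'   per-pathway sample fractions) and `nSamples`.
#' @export
cohortActionableFraction <- function(alterations) {
    if (NROW(alterations) == 0L) stop("empty cohort")
    samples <- unique(alterations$sampleId)
    act <- alterations[alterations$verdict == "actionable", , drop = FALSE]
    fraction <- length(unique(act$sampleId)) / length(samples)
    perPathway <- vapply(sort(unique(alterations$pathway)), function(pw)
        length(unique(act$sampleId[act$pathway == pw])) / length(samples),
        numeric(1))
    list(fraction = fraction, perPathway = perPathway,
         nSamples = length(samples))
}
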
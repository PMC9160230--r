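## Readers and writers for the standard formats: BED panels, VCF / MAF-like
## TSV variant tables, SEG copy-number segments.  All coordinate conversions
## (0-based BED, 1-based VCF) happen here, at the I/O boundary; internal
## objects use the GRanges convention (1-based, closed).

.VARIANT_COLS <- c("sampleId", "chrom", "pos", "ref", "alt", "gene",
                   "depth", "altCount", "vaf", "populationAf",
                   "consequence", "predictedClass", "hotspot")

#' Read a panel design from BED
#'
#' Expects at least four columns, the name field holding the gene symbol.
#' BED's 0-based half-open coordinates become 1-based closed internally.
#'
#' @param path BED file.
#' @return A [PanelDesign-class].
#' @export
readPanel <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    mcols(gr) <- DataFrame(gene = mcols(gr)$name)
    panelDesign(gr)
}

#' Write a panel design to BED
#' @param panel A [PanelDesign-class].
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path) {
    gr <- panelTargets(panel)
    mcols(gr) <- DataFrame(name = mcols(gr)$gene)
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read a variant table (VCF or MAF-like TSV)
#'
#' The VCF dialect expects per-sample `AD` and `DP` FORMAT fields and the
#' INFO keys `PAF` (population allele frequency), `GENE`, `CSQ`
#' (consequence), `PRED` (predicted class) and `HOT` (hotspot flag), as
#' written by [writeVariants()].  Missing population AFs become 0 with one
#' summary warning.  The TSV dialect is a flat table with the columns
#' documented below; malformed rows raise an error naming the line.
#'
#' @param path Input file.
#' @param dialect `"auto"` (by extension), `"vcf"` or `"maf_tsv"`.
#' @return data.frame with columns `sampleId`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `gene`, `depth`, `altCount`, `vaf`, `populationAf`,
#'   `consequence`, `predictedClass`, `hotspot`.
#' @export
readVariants <- function(path, dialect = c("auto", "vcf", "maf_tsv")) {
    dialect <- match.arg(dialect)
    if (dialect == "auto")
        dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "maf_tsv"
    if (dialect == "vcf") .readVariantsVcf(path) else .readVariantsTsv(path)
}

.readVariantsVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- VariantAnnotation::info(vcf)
    ad <- VariantAnnotation::geno(vcf)$AD
    dp <- VariantAnnotation::geno(vcf)$DP
    sample <- colnames(vcf)[1L]
    altCount <- vapply(ad[, 1L], function(x) as.integer(x[2L]), integer(1))
    depth <- as.integer(dp[, 1L])
    paf <- as.numeric(info$PAF)
    nMissing <- sum(is.na(paf))
    if (nMissing > 0L) {
        warning(nMissing, " variant(s) without population AF; set to 0")
        paf[is.na(paf)] <- 0
    }
    pred <- as.character(info$PRED)
    pred[pred %in% c("NA", ".", "")] <- NA_character_
    data.frame(
        sampleId = sample,
        chrom = as.character(seqnames(rr)),
        pos = start(rr),
        ref = as.character(VariantAnnotation::ref(vcf)),
        alt = vapply(seq_along(rr), function(i)
            as.character(VariantAnnotation::alt(vcf)[[i]][1L]), character(1)),
        gene = as.character(info$GENE),
        depth = depth, altCount = altCount,
        vaf = altCount / depth,
        populationAf = paf,
        consequence = as.character(info$CSQ),
        predictedClass = pred,
        hotspot = as.logical(info$HOT),
        stringsAsFactors = FALSE, row.names = NULL)
}

.readVariantsTsv <- function(path) {
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    if (length(nf) == 0L) return(.emptyVariantTable())
    bad <- which(nf != nf[1L])
    if (length(bad))
        stop("malformed record at line ", bad[1L] + 0L, " of ", path)
    df <- read.delim(path, stringsAsFactors = FALSE, colClasses = c(
        sampleId = "character", chrom = "character", pos = "integer",
        ref = "character", alt = "character", gene = "character",
        depth = "integer", altCount = "integer", vaf = "numeric",
        populationAf = "numeric", consequence = "character",
        predictedClass = "character", hotspot = "logical"))
    missing <- setdiff(.VARIANT_COLS, names(df))
    if (length(missing))
        stop("variant TSV lacks columns: ", paste(missing, collapse = ", "))
    bad <- which(is.na(df$pos) | is.na(df$depth))
    if (length(bad))
        stop("malformed record at line ", bad[1L] + 1L, " of ", path)
    df$predictedClass <- as.character(df$predictedClass)
    df
}

#' Write a variant table
#'
#' @param variants data.frame in the [readVariants()] column contract.
#' @param path Output file.
#' @param dialect `"auto"` (by extension), `"vcf"` (single sample only) or
#'   `"maf_tsv"`.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(variants, path,
                          dialect = c("auto", "vcf", "maf_tsv")) {
    dialect <- match.arg(dialect)
    if (dialect == "auto")
        dialect <- if (grepl("\\.vcf$", path)) "vcf" else "maf_tsv"
    if (dialect == "vcf") .writeVariantsVcf(variants, path)
    else {
        df <- variants[, .VARIANT_COLS]
        for (cc in c("vaf", "populationAf"))
            df[[cc]] <- sprintf("%.17g", df[[cc]])
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

.writeVariantsVcf <- function(variants, path) {
    sample <- unique(variants$sampleId)
    if (length(sample) > 1L)
        stop("VCF dialect writes one sample per file")
    if (length(sample) == 0L) sample <- "SAMPLE"
    hdr <- c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=PAF,Number=1,Type=Float,Description=\"Population allele frequency\">",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
        "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
        "##INFO=<ID=PRED,Number=1,Type=String,Description=\"Predicted class\">",
        "##INFO=<ID=HOT,Number=0,Type=Flag,Description=\"Hotspot\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
               sample))
    v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
    info <- paste0("PAF=", sprintf("%.17g", v$populationAf),
                   ";GENE=", v$gene, ";CSQ=", v$consequence,
                   ";PRED=", ifelse(is.na(v$predictedClass), "NA",
                                    v$predictedClass),
                   ifelse(v$hotspot, ";HOT", ""))
    lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                   "GT:AD:DP",
                   paste0("0/1:", v$depth - v$altCount, ",", v$altCount,
                          ":", v$depth),
                   sep = "\t")
    writeLines(c(hdr, lines), path)
    invisible(path)
}

#' Read copy-number segments from SEG
#'
#' SEG columns: `ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean` (plus optional `copyNumber`, `state`).  Numeric fields round
#' trip bit-exact with [writeSegments()].  Overlapping segments within one
#' sample raise an error; a header-only file yields an empty result.
#'
#' @param path SEG file.
#' @return GRanges with metadata columns `sample`, `nBins`, `meanLog2` and,
#'   when present, `copyNumber`, `state`.
#' @export
readSegments <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
    if (!all(need %in% names(df)))
        stop("not a SEG file: need columns ", paste(need, collapse = ", "))
    if (nrow(df) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(sample = character(0), nBins = integer(0),
                               meanLog2 = numeric(0))
        return(gr)
    }
    gr <- GRanges(df$chrom, IRanges(df$loc.start, df$loc.end),
                  sample = df$ID, nBins = as.integer(df$num.mark),
                  meanLog2 = as.numeric(df$seg.mean))
    if ("copyNumber" %in% names(df)) {
        mcols(gr)$copyNumber <- as.integer(df$copyNumber)
        mcols(gr)$state <- as.character(df$state)
    }
    for (s in unique(df$ID)) {
        sub <- gr[mcols(gr)$sample == s]
        if (length(findOverlaps(sub, drop.self = TRUE,
                                drop.redundant = TRUE)))
            stop("overlapping segments for sample ", s)
    }
    gr
}

#' Write copy-number segments to SEG
#'
#' @param segments GRanges with `nBins` and `meanLog2` (and optionally
#'   `copyNumber`, `state`) metadata columns, e.g. from
#'   [segmentCoverage()].
#' @param path Output file.
#' @param sample Sample identifier for the `ID` column (ignored if the
#'   GRanges already has a `sample` column).
#' @return `path`, invisibly.
#' @export
writeSegments <- function(segments, path, sample = "sample") {
    m <- mcols(segments)
    df <- data.frame(
        ID = if (!is.null(m$sample)) m$sample else sample,
        chrom = as.character(seqnames(segments)),
        loc.start = start(segments), loc.end = end(segments),
        num.mark = m$nBins,
        seg.mean = sprintf("%.17g", m$meanLog2),
        stringsAsFactors = FALSE)
    if (!is.null(m$copyNumber)) {
        df$copyNumber <- m$copyNumber
        df$state <- m$state
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write per-bin coverage to TSV
#'
#' @param bins GRanges of bins with a `gene` column.
#' @param values Per-bin values (raw depth or log2 ratio).
#' @param path Output file.
#' @param valueName Column name for `values`.
#' @return `path`, invisibly.
#' @export
writeCoverage <- function(bins, values, path, valueName = "log2ratio") {
    df <- data.frame(chrom = as.character(seqnames(bins)),
                     start = start(bins), end = end(bins),
                     gene = mcols(bins)$gene,
                     value = sprintf("%.17g", values))
    names(df)[5L] <- valueName
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read per-bin coverage from TSV
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `gene` and one
#'   value column (raw `depth` or `log2ratio`).
#' @return List with `bins` (GRanges) and `values` (numeric), plus
#'   `valueName`.
#' @export
readCoverage <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    valueName <- setdiff(names(df), c("chrom", "start", "end", "gene"))[1L]
    list(bins = GRanges(df$chrom, IRanges(df$start, df$end),
                        gene = df$gene),
         values = as.numeric(df[[valueName]]), valueName = valueName)
}
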
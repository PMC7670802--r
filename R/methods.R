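#' Construct an OtuTable
#'
#' @param counts integer matrix of OTU counts. Either OTUs x samples or, with
#'   `samplesAsRows = TRUE`, samples x OTUs (the on-disk orientation).
#' @param sampleData optional data.frame of per-sample metadata (animal,
#'   family, tank, day, ...), one row per sample, rownames = sample ids.
#' @param arm treatment arm: `"pma"`, `"untreated"` or `"live"`.
#' @param taxonomy optional data.frame of per-OTU annotation (e.g. a
#'   `phylum` column), rownames = OTU ids.
#' @param samplesAsRows logical, set `TRUE` when `counts` has samples as rows.
#' @return an [OtuTable-class] object.
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("OTU", 1:3), paste0("S", 1:4)))
#' ot <- OtuTable(m, arm = "untreated")
#' otuCounts(ot)[1:2, 1:2]
#' @export
OtuTable <- function(counts, sampleData = NULL,
                     arm = c("untreated", "pma", "live"),
                     taxonomy = NULL, samplesAsRows = FALSE) {
    arm <- match.arg(arm)
    counts <- as.matrix(counts)
    if (samplesAsRows) counts <- t(counts)
    storage.mode(counts) <- "double"
    if (is.null(rownames(counts)) && nrow(counts))
        rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
    if (is.null(colnames(counts)) && ncol(counts))
        colnames(counts) <- paste0("S", seq_len(ncol(counts)))
    cd <- if (is.null(sampleData)) {
        S4Vectors::DataFrame(row.names = colnames(counts))
    } else {
        sampleData <- as.data.frame(sampleData)
        if (!is.null(sampleData$sample) && is.null(rownames(sampleData)))
            rownames(sampleData) <- sampleData$sample
        S4Vectors::DataFrame(sampleData[colnames(counts), , drop = FALSE],
                             row.names = colnames(counts))
    }
    rd <- if (is.null(taxonomy)) {
        S4Vectors::DataFrame(row.names = rownames(counts))
    } else {
        S4Vectors::DataFrame(as.data.frame(taxonomy)[rownames(counts), ,
                                                     drop = FALSE],
                             row.names = rownames(counts))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd, rowData = rd)
    new("OtuTable", se, arm = arm)
}

#' Accessors for OtuTable
#'
#' `otuCounts()` returns the OTUs-by-samples count matrix, `treatmentArm()`
#' the arm tag, and `sampleInfo()` the per-sample metadata as a data.frame.
#'
#' @param x an [OtuTable-class].
#' @name OtuTable-accessors
NULL

#' @rdname OtuTable-accessors
#' @export
setMethod("otuCounts", "OtuTable", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' @rdname OtuTable-accessors
#' @export
setMethod("treatmentArm", "OtuTable", function(x) x@arm)

#' @rdname OtuTable-accessors
#' @export
setMethod("sampleInfo", "OtuTable", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

setMethod("show", "OtuTable", function(object) {
    cat(sprintf("OtuTable (%s arm): %d OTUs x %d samples, %s reads\n",
                object@arm, nrow(object), ncol(object),
                format(sum(otuCounts(object)), big.mark = ",")))
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix, individuals x SNPs, values 0/1/2/NA,
#'   with individual rownames and SNP colnames.
#' @param map data.frame with columns `snp`, `chr`, `pos` matching the
#'   columns of `dosage`.
#' @return a [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, map) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "double"
    map <- as.data.frame(map)
    map$snp <- as.character(map$snp)
    map$chr <- as.character(map$chr)
    rownames(map) <- NULL
    new("GenotypeData", dosage = dosage, map = map)
}

#' Accessors for GenotypeData
#'
#' `dosages()` returns the individuals-by-SNPs matrix, `snpMap()` the SNP
#' map (snp, chr, pos).
#'
#' @param x a [GenotypeData-class].
#' @name GenotypeData-accessors
NULL

#' @rdname GenotypeData-accessors
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosage)

#' @rdname GenotypeData-accessors
#' @export
setMethod("snpMap", "GenotypeData", function(x) x@map)

setMethod("show", "GenotypeData", function(object) {
    miss <- mean(is.na(object@dosage))
    cat(sprintf("GenotypeData: %d individuals x %d SNPs on %d chromosome(s), %.2f%% missing\n",
                nrow(object@dosage), ncol(object@dosage),
                length(unique(object@map$chr)), 100 * miss))
})

#' Accessors for Grm
#'
#' `grmMatrix()` returns the dense relationship matrix, `nSnpsUsed()` the
#' number of SNPs it was built from.
#'
#' @param x a [Grm-class].
#' @name Grm-accessors
NULL

#' @rdname Grm-accessors
#' @export
setMethod("grmMatrix", "Grm", function(x) x@G)

#' @rdname Grm-accessors
#' @export
setMethod("nSnpsUsed", "Grm", function(x) x@nSnps)

setMethod("show", "Grm", function(object) {
    cat(sprintf("Grm: %d individuals, %d SNPs; mean diagonal %.3f\n",
                nrow(object@G), object@nSnps, mean(diag(object@G))))
})

#' Accessors for VarCompFit
#'
#' `varComp()` returns the named vector of variance-component estimates.
#'
#' @param x a [VarCompFit-class].
#' @name VarCompFit-accessors
NULL

#' @rdname VarCompFit-accessors
#' @export
setMethod("varComp", "VarCompFit", function(x) x@varComp)

setMethod("show", "VarCompFit", function(object) {
    vc <- object@varComp
    flag <- ifelse(object@boundary[names(vc)], " (boundary)", "")
    cat("REML variance-component fit\n")
    for (i in seq_along(vc))
        cat(sprintf("  %-9s %8.4g +/- %-8.3g%s\n", names(vc)[i], vc[i],
                    object@varCompSE[i], flag[i]))
    if (!is.na(object@h2))
        cat(sprintf("  h2 = %.3f +/- %.3f", object@h2, object@h2SE))
    if (!is.na(object@c2))
        cat(sprintf("   c2 = %.3f +/- %.3f", object@c2, object@c2SE))
    cat(sprintf("\n  logLik (restricted, const. omitted) = %.4f; %s in %d iter.\n",
                object@logLik,
                if (object@converged) "converged" else "NOT converged",
                object@iterations))
})

setMethod("show", "ScreenResult", function(object) {
    s <- object@summary
    cat(sprintf(paste0("ScreenResult: %d/%d samples pass QC; dead reads %.2f%%,",
                       " contaminant reads %.3f%% (untreated arm)\n"),
                length(object@qcPass), length(object@qcPass) +
                    attr(object@qcPass, "nFailed") %||% 0L,
                100 * s$fractionDeadReads, 100 * s$fractionContamReads))
    cat(sprintf("  dataset-level OTU classes: %d live, %d dead, %d contaminant\n",
                s$nLive, s$nDead, s$nContam))
})

setMethod("show", "OutlierReport", function(object) {
    cat(sprintf("OutlierReport: n = %d, p = %d, cutoff 3p/n = %.4f; %d flagged\n",
                object@n, object@p, object@cutoff, length(object@flagged)))
    if (length(object@flagged))
        cat("  flagged:", paste(object@flagged, collapse = ", "), "\n")
})

setMethod("show", "GwasResult", function(object) {
    cat(sprintf("GwasResult: %d SNPs on %d chromosomes; min p = %.3g\n",
                nrow(object@results), nrow(object@chromVar),
                min(object@results$p)))
})

setMethod("show", "AssocFit", function(object) {
    cat(sprintf("AssocFit for %s: %d fixed regressors\n", object@response,
                nrow(object@table)))
    print(object@table, digits = 3, row.names = FALSE)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
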
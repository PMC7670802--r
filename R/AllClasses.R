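#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats as.formula coef cor lm median optimize pchisq pf
#'   qchisq rbinom rmultinom rnorm runif sd setNames var hatvalues
#' @importFrom utils read.table write.table modifyList head
NULL

#' OtuTable: an OTU count table for one treatment arm
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' integer OTU counts (rows = OTUs, columns = samples), per-sample metadata
#' (animal, family, tank, sampling day where known), and a treatment-arm tag
#' distinguishing PMA-treated from untreated libraries. On disk the table is
#' tab-delimited with samples as rows (first column `sample`), the in-memory
#' orientation follows the Bioconductor features-by-samples convention.
#'
#' @slot arm character(1), one of `"pma"`, `"untreated"` or `"live"` (the
#'   post-screen or simulated ground-truth arm).
#' @export
setClass("OtuTable",
    contains = "SummarizedExperiment",
    representation(arm = "character"))

setValidity("OtuTable", function(object) {
    msg <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (!is.numeric(cnt) || any(!is.finite(cnt)) || any(cnt < 0))
            msg <- c(msg, "counts must be finite and non-negative")
        if ((nrow(cnt) && is.null(rownames(cnt))) ||
            (ncol(cnt) && is.null(colnames(cnt))))
            msg <- c(msg, "counts must have OTU rownames and sample colnames")
    }
    if (length(object@arm) != 1L ||
        !object@arm %in% c("pma", "untreated", "live"))
        msg <- c(msg, "arm must be one of 'pma', 'untreated', 'live'")
    if (length(msg)) msg else TRUE
})

#' GenotypeData: SNP dosages with a chromosome/position map
#'
#' Individuals-by-SNPs dosage matrix coded 0/1/2 (copies of the counted
#' allele) with `NA` for missing calls, plus a SNP map giving chromosome and
#' position for every marker.
#'
#' @slot dosage numeric matrix, individuals x SNPs, entries in \{0,1,2,NA\}.
#' @slot map data.frame with columns `snp`, `chr`, `pos`, one row per column
#'   of `dosage`, in the same order.
#' @export
setClass("GenotypeData",
    representation(dosage = "matrix", map = "data.frame"))

setValidity("GenotypeData", function(object) {
    msg <- character()
    d <- object@dosage
    if (!is.numeric(d)) msg <- c(msg, "dosage must be numeric")
    ok <- d[!is.na(d)]
    if (length(ok) && !all(ok %in% c(0, 1, 2)))
        msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    if (is.null(rownames(d))) msg <- c(msg, "dosage needs individual rownames")
    if (is.null(colnames(d))) msg <- c(msg, "dosage needs SNP colnames")
    if (!all(c("snp", "chr", "pos") %in% names(object@map)))
        msg <- c(msg, "map needs columns snp, chr, pos")
    else if (nrow(object@map) != ncol(d) ||
             !identical(as.character(object@map$snp), colnames(d)))
        msg <- c(msg, "map rows must match dosage columns (same SNPs, same order)")
    if (length(msg)) msg else TRUE
})

#' Grm: a genomic relationship matrix
#'
#' Dense symmetric realized-relationship matrix over individuals, built from
#' centred SNP dosages (VanRaden method 1), together with the number of SNPs
#' and the allele frequencies used.
#'
#' @slot G symmetric numeric matrix with individual ids as dimnames.
#' @slot nSnps integer, number of SNPs entering the matrix.
#' @slot freq numeric, counted-allele frequencies of those SNPs.
#' @export
setClass("Grm",
    representation(G = "matrix", nSnps = "integer", freq = "numeric"))

setValidity("Grm", function(object) {
    msg <- character()
    G <- object@G
    if (nrow(G) != ncol(G)) msg <- c(msg, "G must be square")
    else if (max(abs(G - t(G))) > 1e-8) msg <- c(msg, "G must be symmetric")
    if (is.null(rownames(G))) msg <- c(msg, "G needs individual id dimnames")
    if (length(msg)) msg else TRUE
})

#' VarCompFit: a restricted-maximum-likelihood variance-component fit
#'
#' Result of fitting the animal model with (optionally) a tank effect by
#' average-information REML: variance components with standard errors,
#' heritability and tank fraction with delta-method standard errors,
#' restricted log-likelihood (constants omitted), boundary flags, and the
#' fixed-effect solutions.
#'
#' @slot varComp named numeric, variance components (subset of
#'   `animal`, `tank`, `residual`).
#' @slot varCompSE standard errors from the inverse average-information
#'   matrix (`NA` for components held at the zero boundary).
#' @slot varCompVcov covariance matrix of the free components.
#' @slot h2,h2SE,c2,c2SE heritability / tank fraction and their
#'   delta-method standard errors (`NA` when the component is absent).
#' @slot logLik restricted log-likelihood up to an additive constant.
#' @slot boundary named logical, `TRUE` where a component was restricted to
#'   the zero boundary of the parameter space.
#' @slot converged logical(1); iterations integer(1).
#' @slot fixef,fixefSE generalized-least-squares fixed-effect estimates and
#'   standard errors at the REML solution.
#' @slot n integer(1), number of observations.
#' @export
setClass("VarCompFit",
    representation(varComp = "numeric", varCompSE = "numeric",
                   varCompVcov = "matrix",
                   h2 = "numeric", h2SE = "numeric",
                   c2 = "numeric", c2SE = "numeric",
                   logLik = "numeric", boundary = "logical",
                   converged = "logical", iterations = "integer",
                   fixef = "numeric", fixefSE = "numeric", n = "integer"))

#' ScreenResult: outcome of PMA live/dead/contaminant screening
#'
#' @slot filtered [OtuTable] of untreated-arm rarefied counts with dead and
#'   contaminant OTUs removed per sample (QC-passing samples only).
#' @slot calls data.frame of per-sample, per-OTU viability calls
#'   (`sample`, `otu`, `ratio`, `label`).
#' @slot summary one-row data.frame: read-weighted dead/contaminant
#'   fractions over the untreated arm and dataset-level OTU class counts.
#' @slot qcPass character, samples meeting the rarefaction depth in both arms.
#' @slot otuClass named character, dataset-level (pooled-count) class per OTU.
#' @export
setClass("ScreenResult",
    representation(filtered = "OtuTable", calls = "data.frame",
                   summary = "data.frame", qcPass = "character",
                   otuClass = "character"))

#' OutlierReport: leverage-based outlier screen of one OTU regression
#'
#' @slot p,n number of model parameters and samples; cutoff equals `3p/n`.
#' @slot cutoff numeric(1), the leverage cutoff.
#' @slot influence named numeric, hat-matrix diagonal per sample.
#' @slot flagged character, samples with influence above the cutoff.
#' @export
setClass("OutlierReport",
    representation(p = "integer", n = "integer", cutoff = "numeric",
                   influence = "numeric", flagged = "character"))

#' GwasResult: per-SNP mixed-model association results
#'
#' @slot results data.frame with one row per tested SNP: `snp`, `chr`, `pos`,
#'   `beta`, `se`, `stat`, `p`, `neglog10p`.
#' @slot chromVar data.frame of the polygenic and residual variance
#'   re-estimated for each left-out chromosome.
#' @export
setClass("GwasResult",
    representation(results = "data.frame", chromVar = "data.frame"))

#' AssocFit: mixed-model regression of one phenotype on log OTU abundances
#'
#' @slot response character(1), the phenotype name.
#' @slot table data.frame, one row per fixed regressor: `variable`,
#'   `estimate`, `se`, `Fvalue`, `p`.
#' @slot fit the underlying [VarCompFit] (animal + tank + residual).
#' @export
setClass("AssocFit",
    representation(response = "character", table = "data.frame",
                   fit = "VarCompFit"))
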
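# SNP/individual quality control and VanRaden method-1 genomic relationship
# matrices, including the leave-one-chromosome-out variant used by the
# mixed-model association scan.

#' Quality-control SNP genotypes
#'
#' Drops individuals whose missing-genotype fraction reaches
#' `indMissingMax`, then drops SNPs with minor allele frequency below
#' `mafMin` or call rate at or below `snpCallMin`.
#'
#' @param geno a [GenotypeData-class].
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param snpCallMin minimum call rate, exclusive (default 0.90: a SNP needs
#'   a call rate above 90%).
#' @param indMissingMax maximum individual missingness, exclusive (default
#'   0.10: individuals with less than 10% missing are kept).
#' @return the filtered [GenotypeData-class]; the numbers removed are
#'   attached as attribute `qc` and reported via `message()`.
#' @export
qcGenotypes <- function(geno, mafMin = 0.01, snpCallMin = 0.90,
                        indMissingMax = 0.10) {
    d <- dosages(geno)
    indMiss <- rowMeans(is.na(d))
    keepInd <- indMiss < indMissingMax
    d <- d[keepInd, , drop = FALSE]
    if (nrow(d) == 0L) stop("all individuals removed by missingness filter")
    callRate <- colMeans(!is.na(d))
    p <- colMeans(d, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    maf[is.nan(maf)] <- 0
    keepSnp <- callRate > snpCallMin & maf >= mafMin
    if (!any(keepSnp)) stop("all SNPs removed by QC")
    out <- GenotypeData(d[, keepSnp, drop = FALSE],
                        snpMap(geno)[keepSnp, , drop = FALSE])
    attr(out, "qc") <- list(indRemoved = sum(!keepInd),
                            snpRemoved = sum(!keepSnp),
                            indKept = nrow(d), snpKept = sum(keepSnp))
    message(sprintf("genotype QC: removed %d individual(s), %d SNP(s); kept %d x %d",
                    sum(!keepInd), sum(!keepSnp), nrow(d), sum(keepSnp)))
    out
}

# Column-centred dosage matrix (mean-imputed missing values) and the
# 2*sum(p(1-p)) scaling denominator for a SNP subset.
.centredDosage <- function(d) {
    p <- colMeans(d, na.rm = TRUE) / 2
    Z <- sweep(d, 2, 2 * p)
    Z[is.na(Z)] <- 0                       # mean imputation after centring
    list(Z = Z, p = p, denom = 2 * sum(p * (1 - p)))
}

#' VanRaden method-1 genomic relationship matrix
#'
#' `G = Z Z' / (2 sum p_j (1 - p_j))` with `Z` the dosage matrix centred at
#' twice the observed allele frequencies; missing dosages are mean-imputed
#' (equivalently set to zero after centring).
#'
#' @param geno a (QC'd) [GenotypeData-class].
#' @param snps optional character vector restricting the SNPs used.
#' @return a [Grm-class].
#' @examples
#' d <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
#' g <- GenotypeData(d, data.frame(snp = "s1", chr = "chr1", pos = 1))
#' grmMatrix(vanRadenGrm(g))   # diag (2, 0, 2), G[a, c] = -2
#' @export
vanRadenGrm <- function(geno, snps = NULL) {
    d <- dosages(geno)
    if (!is.null(snps)) d <- d[, snps, drop = FALSE]
    if (ncol(d) == 0L) stop("no SNPs to build the GRM from")
    cz <- .centredDosage(d)
    if (cz$denom <= 0)
        stop("zero scaling denominator: all SNPs are monomorphic")
    G <- tcrossprod(cz$Z) / cz$denom
    G <- (G + t(G)) / 2
    new("Grm", G = G, nSnps = ncol(d), freq = cz$p)
}

#' Leave-one-chromosome-out genomic relationship matrix
#'
#' Builds the GRM from all SNPs *not* on the excluded chromosome, so that a
#' candidate SNP's own chromosome does not contribute to the polygenic
#' covariance it is tested against.
#'
#' @param geno a (QC'd) [GenotypeData-class] with at least 2 chromosomes.
#' @param excludeChromosome chromosome label to leave out.
#' @return a [Grm-class].
#' @export
locoGrm <- function(geno, excludeChromosome) {
    map <- snpMap(geno)
    chroms <- unique(map$chr)
    if (length(chroms) < 2L)
        stop("leave-one-chromosome-out needs at least 2 chromosomes")
    keep <- map$snp[map$chr != as.character(excludeChromosome)]
    if (length(keep) == 0L)
        stop("excluding '", excludeChromosome, "' would leave no SNPs")
    vanRadenGrm(geno, snps = keep)
}
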
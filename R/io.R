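# Readers and writers for the documented plain-text formats: tab-delimited
# OTU tables (samples as rows), dosage matrices with a SNP map sidecar, VCF
# genotype input, square and triplet GRM files, phenotype tables, and the
# key-value truth/config sidecars. All tables are UTF-8, tab-delimited,
# header row mandatory, missing values written as "NA".

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", fileEncoding = "UTF-8")
    invisible(path)
}

.readTsv <- function(path, requiredCols = NULL) {
    if (!file.exists(path)) stop("input file not found: ", path)
    df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE, encoding = "UTF-8")
    if (!is.null(requiredCols)) {
        miss <- setdiff(requiredCols, names(df))
        if (length(miss))
            stop("malformed header in ", path, ": missing column(s) ",
                 paste(miss, collapse = ", "))
    }
    df
}

#' Read / write OTU count tables
#'
#' On-disk layout: first column `sample`, remaining columns one per OTU,
#' integer counts, tab-delimited with a header row.
#'
#' @param table an [OtuTable-class]; `path` the file; `arm` the treatment
#'   arm tag assigned on reading.
#' @return `readOtuTable` returns an [OtuTable-class]; `writeOtuTable`
#'   returns the path invisibly.
#' @export
writeOtuTable <- function(table, path) {
    cnt <- t(otuCounts(table))
    df <- data.frame(sample = rownames(cnt), cnt, check.names = FALSE)
    .writeTsv(df, path)
}

#' @rdname writeOtuTable
#' @param path file path.
#' @param sampleData optional per-sample metadata attached on reading.
#' @export
readOtuTable <- function(path, arm = c("untreated", "pma", "live"),
                         sampleData = NULL) {
    df <- .readTsv(path, "sample")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$sample
    OtuTable(m, sampleData = sampleData, arm = match.arg(arm),
             samplesAsRows = TRUE)
}

#' Read / write dosage matrices with a SNP map
#'
#' The dosage file has a first column `id` then one column per SNP
#' (0/1/2/NA); the map file has columns `snp`, `chr`, `pos`.
#'
#' @param geno a [GenotypeData-class].
#' @param path,mapPath dosage and map file paths.
#' @return `readDosage` returns a [GenotypeData-class].
#' @export
writeDosage <- function(geno, path, mapPath) {
    d <- dosages(geno)
    df <- data.frame(id = rownames(d), d, check.names = FALSE)
    .writeTsv(df, path)
    .writeTsv(snpMap(geno), mapPath)
    invisible(path)
}

#' @rdname writeDosage
#' @export
readDosage <- function(path, mapPath) {
    df <- .readTsv(path, "id")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$id
    map <- .readTsv(mapPath, c("snp", "chr", "pos"))
    GenotypeData(m, map)
}

#' Read genotypes from a VCF file
#'
#' Converts the GT field to a dosage of the ALT allele (0/1/2, `NA` for
#' missing), individuals x SNPs, with the chromosome/position map from the
#' VCF fixed columns.
#'
#' @param path VCF file (plain or gzipped).
#' @return a [GenotypeData-class].
#' @export
readVcfGenotypes <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    alt <- function(g) {
        out <- rep(NA_real_, length(g))
        clean <- gsub("\\|", "/", g)
        out[clean %in% c("0/0")] <- 0
        out[clean %in% c("0/1", "1/0")] <- 1
        out[clean %in% c("1/1")] <- 2
        out
    }
    dos <- t(apply(gt, 2, alt))
    colnames(dos) <- rownames(gt)
    rownames(dos) <- colnames(gt)
    fix <- vcfR::getFIX(v)
    map <- data.frame(snp = fix[, "ID"], chr = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]))
    GenotypeData(dos, map)
}

#' Write genotypes as a minimal VCF
#'
#' Emits an unphased GT-only VCF (`0/0`, `0/1`, `1/1`, `./.`) with the SNP
#' map in the fixed columns, suitable for round-tripping through
#' [readVcfGenotypes()].
#'
#' @param geno a [GenotypeData-class].
#' @param path output path (plain text).
#' @export
writeVcfGenotypes <- function(geno, path) {
    d <- dosages(geno)
    map <- snpMap(geno)
    gtOf <- c("0/0", "0/1", "1/1")
    body <- vapply(seq_len(ncol(d)), function(j) {
        g <- d[, j]
        gt <- ifelse(is.na(g), "./.", gtOf[g + 1])
        paste(c(map$chr[j], map$pos[j], map$snp[j], "A", "G", ".", "PASS",
                ".", "GT", gt), collapse = "\t")
    }, character(1))
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", rownames(d)),
                      collapse = "\t"))
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read / write genomic relationship matrices
#'
#' Square form: tab-delimited with an `id` first column and one column per
#' individual. Triplet form: an ids file (one id per line) plus a
#' lower-triangle file with columns `i`, `j`, `value` (1-based indices,
#' `i >= j`).
#'
#' @param grm a [Grm-class]; `path` etc. file paths.
#' @return readers return a [Grm-class].
#' @export
writeGrmSquare <- function(grm, path) {
    G <- grmMatrix(grm)
    df <- data.frame(id = rownames(G), G, check.names = FALSE)
    .writeTsv(df, path)
}

#' @rdname writeGrmSquare
#' @param path file path.
#' @export
readGrmSquare <- function(path) {
    df <- .readTsv(path, "id")
    G <- as.matrix(df[, -1, drop = FALSE])
    rownames(G) <- df$id
    new("Grm", G = (G + t(G)) / 2, nSnps = NA_integer_, freq = numeric())
}

#' @rdname writeGrmSquare
#' @param idsPath,valuesPath triplet-form file paths.
#' @export
writeGrmTriplet <- function(grm, idsPath, valuesPath) {
    G <- grmMatrix(grm)
    idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
    writeLines(rownames(G), idsPath)
    .writeTsv(data.frame(i = idx[, 1], j = idx[, 2], value = G[idx]),
              valuesPath)
}

#' @rdname writeGrmSquare
#' @export
readGrmTriplet <- function(idsPath, valuesPath) {
    ids <- readLines(idsPath)
    tr <- .readTsv(valuesPath, c("i", "j", "value"))
    n <- length(ids)
    G <- matrix(0, n, n, dimnames = list(ids, ids))
    G[cbind(tr$i, tr$j)] <- tr$value
    G[cbind(tr$j, tr$i)] <- tr$value
    new("Grm", G = G, nSnps = NA_integer_, freq = numeric())
}

#' Read / write phenotype tables
#'
#' Tab-delimited with columns `animal`, `family`, `tank`, `day` plus the
#' phenotype variables (IW, FW, WG, RG, AMC, AMN, ALC, ALN, AAC,
#' IFCR_AMC, IFCR_AMN, IFER_AMC, IFER_AMN).
#'
#' @param pheno data.frame; `path` the file path.
#' @export
writePhenotypes <- function(pheno, path) .writeTsv(pheno, path)

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path)
    .readTsv(path, c("animal", "family", "tank", "day"))

#' Write the planted-truth sidecar
#'
#' Key-value YAML with the scalar and per-OTU truth values needed by
#' recovery tests (variance fractions, fold factors, planted read
#' fractions, regression coefficients).
#'
#' @param truth a [simTruth()]; `path` the output file.
#' @export
writeTruthSidecar <- function(truth, path) {
    yaml::write_yaml(list(
        h2 = as.list(truth$h2), c2 = as.list(truth$c2),
        deadOtus = as.list(truth$deadOtus),
        contamOtus = as.list(truth$contamOtus),
        deadReadFraction = truth$deadReadFraction,
        contamReadFraction = truth$contamReadFraction,
        otuEffects = apply(truth$otuEffects, 1, as.list, simplify = FALSE)),
        path)
    invisible(path)
}

#' @rdname writeTruthSidecar
#' @export
readTruthSidecar <- function(path) yaml::read_yaml(path)
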
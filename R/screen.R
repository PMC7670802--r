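# PMA viability screening: rarefaction, per-sample live/dead/contaminant
# classification from paired PMA-treated / untreated counts, dataset
# summaries, and community descriptions (mean abundance, prevalence,
# Spearman correlations among the dominant OTUs).

#' Rarefy a count vector to fixed depth
#'
#' Subsamples reads without replacement to exactly `depth`. Samples whose
#' total is below `depth` cannot be rarefied and are flagged as failing QC.
#'
#' @param counts non-negative integer vector of per-OTU read counts.
#' @param depth target depth (> 0).
#' @param seed integer seed for the subsampling.
#' @return list with `counts` (the rarefied vector, summing to `depth` when
#'   `pass` is `TRUE`; the input unchanged otherwise) and `pass` (logical:
#'   did the sample meet the depth?).
#' @examples
#' rarefyCounts(c(9000, 6000), depth = 10000, seed = 1)$counts
#' @export
rarefyCounts <- function(counts, depth, seed = 1L) {
    if (depth <= 0) stop("depth must be positive")
    if (any(counts < 0)) stop("negative counts are not allowed")
    total <- sum(counts)
    if (total < depth)
        return(list(counts = counts, pass = FALSE))
    if (total == depth)
        return(list(counts = counts, pass = TRUE))
    out <- withr::with_seed(seed, {
        reads <- sample.int(total, depth)        # positions among pooled reads
        breaks <- c(0, cumsum(counts))
        tabulate(findInterval(reads, breaks, left.open = TRUE),
                 nbins = length(counts))
    })
    names(out) <- names(counts)
    list(counts = out, pass = TRUE)
}

#' Classify one OTU as live, dead or contaminant
#'
#' The untreated-to-PMA abundance ratio is computed on relative abundances
#' with a pseudocount of one added to both counts:
#' `ratio = ((cu + 1) / depthU) / ((cp + 1) / depthP)`. An OTU is a
#' contaminant when the ratio exceeds `contamFold` (its signal is inflated
#' more than 6-fold in the untreated library), dead when it exceeds
#' `deadFold` (more than 3-fold reduction under PMA), live otherwise, and
#' undetected when absent from both arms.
#'
#' @param countUntreated,countPma read counts in the two arms (>= 0).
#' @param deadFold,contamFold fold thresholds (> 1); defaults 3 and 6.
#' @param depthUntreated,depthPma library sizes used for the relative
#'   abundances; equal by default (rarefied input).
#' @return list with `ratio` and `label` (one of `"live"`, `"dead"`,
#'   `"contaminant"`, `"undetected"`).
#' @examples
#' classifyOtuViability(60, 5)$label   # contaminant
#' classifyOtuViability(40, 10)$label  # dead
#' classifyOtuViability(10, 10)$label  # live
#' @export
classifyOtuViability <- function(countUntreated, countPma,
                                 deadFold = 3, contamFold = 6,
                                 depthUntreated = 1, depthPma = depthUntreated) {
    stopifnot(countUntreated >= 0, countPma >= 0,
              deadFold > 1, contamFold > 1)
    if (countUntreated == 0 && countPma == 0)
        return(list(ratio = NA_real_, label = "undetected"))
    ratio <- ((countUntreated + 1) / depthUntreated) /
        ((countPma + 1) / depthPma)
    label <- if (ratio > contamFold) "contaminant"
             else if (ratio > deadFold) "dead"
             else "live"
    list(ratio = ratio, label = label)
}

# Vectorized classification of an OTU x sample pair of count matrices with
# equal per-sample depths.
.classifyMatrix <- function(untreated, pma, deadFold, contamFold) {
    ratio <- (untreated + 1) / (pma + 1)
    label <- matrix("live", nrow(ratio), ncol(ratio), dimnames = dimnames(ratio))
    label[ratio > deadFold] <- "dead"
    label[ratio > contamFold] <- "contaminant"
    und <- untreated == 0 & pma == 0
    label[und] <- "undetected"
    ratio[und] <- NA_real_
    list(ratio = ratio, label = label)
}

#' Screen a paired PMA/untreated dataset
#'
#' Rarefies both arms to `depth` (samples below depth in either arm fail
#' QC and are excluded), classifies every observed OTU in every passing
#' sample, removes dead and contaminant OTUs from that sample's untreated
#' counts, and summarizes the dead/contaminant read fractions over the
#' untreated arm together with dataset-level OTU class counts (classes of
#' pooled counts across samples).
#'
#' @param pmaTable,untreatedTable [OtuTable-class] objects with matching
#'   sample identifiers (an error if no samples overlap).
#' @param depth rarefaction depth (default 10000).
#' @param deadFold,contamFold classification thresholds (defaults 3 and 6).
#' @param seed integer seed for rarefaction.
#' @return a [ScreenResult-class].
#' @export
screenDataset <- function(pmaTable, untreatedTable, depth = 10000L,
                          deadFold = 3, contamFold = 6, seed = 1L) {
    cu <- otuCounts(untreatedTable)
    cp <- otuCounts(pmaTable)
    common <- intersect(colnames(cu), colnames(cp))
    if (length(common) == 0L)
        stop("no overlapping samples between the two arms")
    otus <- union(rownames(cu), rownames(cp))
    pad <- function(m) {
        out <- matrix(0, length(otus), length(common),
                      dimnames = list(otus, common))
        out[rownames(m), ] <- m[, common]
        out
    }
    cu <- pad(cu); cp <- pad(cp)
    nAll <- length(common)

    ru <- matrix(0, length(otus), nAll, dimnames = dimnames(cu))
    rp <- ru
    pass <- logical(nAll); names(pass) <- common
    for (i in seq_along(common)) {
        a <- rarefyCounts(cu[, i], depth, seed = seed + 2L * i)
        b <- rarefyCounts(cp[, i], depth, seed = seed + 2L * i + 1L)
        pass[i] <- a$pass && b$pass
        ru[, i] <- a$counts
        rp[, i] <- b$counts
    }
    qcPass <- common[pass]
    if (!length(qcPass)) stop("no samples meet the rarefaction depth")
    ru <- ru[, qcPass, drop = FALSE]
    rp <- rp[, qcPass, drop = FALSE]

    cls <- .classifyMatrix(ru, rp, deadFold, contamFold)
    filt <- ru
    filt[cls$label %in% c("dead", "contaminant")] <- 0

    totalReads <- sum(ru)
    fracDead <- sum(ru[cls$label == "dead"]) / totalReads
    fracContam <- sum(ru[cls$label == "contaminant"]) / totalReads

    # dataset-level class per OTU from pooled counts
    observed <- rowSums(ru) + rowSums(rp) > 0
    pooled <- .classifyMatrix(cbind(rowSums(ru)), cbind(rowSums(rp)),
                              deadFold, contamFold)
    otuClass <- setNames(pooled$label[, 1], otus)
    otuClass[!observed] <- "undetected"

    calls <- data.frame(
        sample = rep(qcPass, each = length(otus)),
        otu = rep(otus, length(qcPass)),
        ratio = as.vector(cls$ratio),
        label = as.vector(cls$label), stringsAsFactors = FALSE)
    calls <- calls[calls$label != "undetected", ]
    rownames(calls) <- NULL

    summ <- data.frame(
        fractionDeadReads = fracDead, fractionContamReads = fracContam,
        nLive = sum(otuClass == "live"), nDead = sum(otuClass == "dead"),
        nContam = sum(otuClass == "contaminant"))
    qcPassOut <- qcPass
    attr(qcPassOut, "nFailed") <- nAll - length(qcPass)
    sd <- sampleInfo(untreatedTable)
    new("ScreenResult",
        filtered = OtuTable(filt,
            sampleData = if (ncol(sd)) sd[qcPass, , drop = FALSE] else NULL,
            arm = "live"),
        calls = calls, summary = summ, qcPass = qcPassOut,
        otuClass = otuClass)
}

#' Summarize community composition
#'
#' Mean relative abundance and prevalence per OTU, the set of
#' high-abundance OTUs (mean relative abundance above `abundanceThreshold`),
#' and, when a `phylum` annotation is present in the table's row data, a
#' per-phylum rollup of OTU counts and mean abundance.
#'
#' @param table a non-empty [OtuTable-class].
#' @param abundanceThreshold high-abundance cutoff on the mean relative
#'   abundance (default 0.01, i.e. 1%).
#' @return list with `perOtu` (data.frame: otu, meanAbundance, prevalence),
#'   `highAbundance` (character vector of OTU ids) and `phylum` (data.frame
#'   or `NULL`).
#' @export
summarizeCommunity <- function(table, abundanceThreshold = 0.01) {
    cnt <- otuCounts(table)
    if (nrow(cnt) == 0L || ncol(cnt) == 0L || sum(cnt) == 0)
        stop("empty OTU table")
    rel <- sweep(cnt, 2, colSums(cnt), "/")
    perOtu <- data.frame(otu = rownames(cnt),
                         meanAbundance = rowMeans(rel),
                         prevalence = rowMeans(cnt > 0),
                         stringsAsFactors = FALSE)
    rownames(perOtu) <- NULL
    high <- perOtu$otu[perOtu$meanAbundance > abundanceThreshold]
    phy <- NULL
    rd <- as.data.frame(SummarizedExperiment::rowData(table))
    if ("phylum" %in% names(rd)) {
        agg <- stats::aggregate(perOtu$meanAbundance,
                                by = list(phylum = rd$phylum), FUN = sum)
        cntAgg <- as.data.frame(table(rd$phylum))
        phy <- data.frame(phylum = agg$phylum, nOtus = cntAgg$Freq,
                          meanAbundance = agg$x)
    }
    list(perOtu = perOtu, highAbundance = high, phylum = phy)
}

#' Spearman correlation matrix among selected OTUs
#'
#' Rank correlation (average ranks for ties) of relative abundances across
#' samples. OTUs constant across samples yield `NA` against every other OTU.
#'
#' @param table an [OtuTable-class] with at least 3 samples.
#' @param otus character vector of OTU ids (default: all).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(table, otus = NULL) {
    cnt <- otuCounts(table)
    if (ncol(cnt) < 3L) stop("at least 3 samples are required")
    rel <- sweep(cnt, 2, colSums(cnt), "/")
    if (!is.null(otus)) rel <- rel[otus, , drop = FALSE]
    x <- t(rel)
    constant <- apply(x, 2, function(v) length(unique(v)) == 1L)
    rho <- suppressWarnings(cor(x, method = "spearman"))
    rho[constant, ] <- NA_real_
    rho[, constant] <- NA_real_
    diag(rho) <- 1
    rho
}
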
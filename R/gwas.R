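# Mixed-linear-model association scan with leave-one-chromosome-out
# relationship matrices: the polygenic variance is re-estimated for each
# excluded chromosome (eigendecomposition-based REML profiled over the
# polygenic/residual ratio), then each SNP on that chromosome gets a
# generalized-least-squares Wald test with the variance components held at
# the null fit.

# Two-component REML (sigma_g^2 G + sigma_e^2 I) via the rotation U'y with
# G = U diag(d) U'; profiles the residual variance and optimizes the
# variance ratio in one dimension.
.eigenReml <- function(y, X, eig, lower = -12, upper = 12) {
    n <- length(y)
    p <- ncol(X)
    yr <- crossprod(eig$vectors, y)
    Xr <- crossprod(eig$vectors, X)
    d <- pmax(eig$values, 0)
    negRL <- function(loglam) {
        lam <- exp(loglam)
        v <- lam * d + 1
        w <- 1 / v
        XtWX <- crossprod(Xr, Xr * w)
        b <- solve(XtWX, crossprod(Xr, yr * w))
        r <- yr - Xr %*% b
        S <- sum(r^2 * w)
        se2 <- S / (n - p)
        0.5 * ((n - p) * log(se2) + sum(log(v)) +
               determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
    }
    opt <- optimize(negRL, c(lower, upper))
    lam <- exp(opt$minimum)
    v <- lam * d + 1
    w <- 1 / v
    XtWX <- crossprod(Xr, Xr * w)
    b <- solve(XtWX, crossprod(Xr, yr * w))
    S <- sum((yr - Xr %*% b)^2 * w)
    se2 <- S / (n - p)
    sg2 <- lam * se2
    boundary <- opt$minimum < lower + 1e-6
    if (boundary) { sg2 <- 0 }
    list(sigmaG = sg2, sigmaE = se2, lambda = lam,
         logLik = -opt$objective, yr = yr, Xr = Xr, d = d,
         U = eig$vectors, boundary = boundary)
}

# Wald tests of each column of M (rotated candidate SNPs) added to the null
# fixed design, with V = diag(sigmaG * d + sigmaE) held fixed.
.glsScan <- function(null, M) {
    w <- 1 / (null$sigmaG * null$d + null$sigmaE)
    Xr <- null$Xr
    yr <- null$yr
    XtWX <- crossprod(Xr, Xr * w)
    XtWy <- crossprod(Xr, yr * w)
    out <- matrix(NA_real_, ncol(M), 2,
                  dimnames = list(colnames(M), c("beta", "se")))
    for (j in seq_len(ncol(M))) {
        xj <- M[, j]
        xtwx <- sum(xj^2 * w)
        xtwX <- crossprod(Xr, xj * w)
        xtwy <- sum(xj * yr * w)
        A <- rbind(cbind(XtWX, xtwX), c(xtwX, xtwx))
        rhs <- c(XtWy, xtwy)
        sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        Ainv <- tryCatch(solve(A), error = function(e) NULL)
        if (is.null(Ainv)) next
        out[j, ] <- c(sol[length(sol)], sqrt(Ainv[nrow(A), nrow(A)]))
    }
    out
}

#' Mixed-model association scan with leave-one-chromosome-out GRMs
#'
#' For each chromosome, fits the null polygenic model
#' `y = X b + g + e`, `g ~ N(0, G_loco sigma_g^2)`, re-estimating the
#' polygenic variance with that chromosome excluded from the relationship
#' matrix, then tests every SNP on the chromosome by a generalized-least-
#' squares Wald test with the variance components held at the null fit.
#' Candidate-SNP dosages are mean-imputed where missing.
#'
#' @param y named numeric response (log OTU abundance), names = individual
#'   ids present in `geno`.
#' @param geno a QC'd [GenotypeData-class] with at least 2 chromosomes.
#' @param covariates optional numeric matrix of additional fixed covariates
#'   (rows aligned with `y`); the intercept is always included.
#' @param ridge diagonal ridge added to each LOCO GRM (default `1e-6`).
#' @return a [GwasResult-class].
#' @export
mlmLocoScan <- function(y, geno, covariates = NULL, ridge = 1e-6) {
    map <- snpMap(geno)
    chroms <- unique(map$chr)
    if (length(chroms) < 2L)
        stop("association scan needs at least 2 chromosomes for LOCO")
    ids <- names(y)
    if (is.null(ids)) stop("y must be named by individual id")
    d <- dosages(geno)
    missing <- setdiff(ids, rownames(d))
    if (length(missing))
        stop("individuals absent from genotypes: ",
             paste(head(missing, 5), collapse = ", "))
    d <- d[ids, , drop = FALSE]
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
    if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))

    resList <- vector("list", length(chroms))
    chromVar <- data.frame(chr = chroms, sigmaG = NA_real_,
                           sigmaE = NA_real_, nSnpsGrm = NA_integer_)
    sub <- GenotypeData(d, map)
    for (ci in seq_along(chroms)) {
        chr <- chroms[ci]
        g <- locoGrm(sub, chr)
        G <- grmMatrix(g) + diag(ridge, length(y))
        eig <- eigen(G, symmetric = TRUE)
        null <- .eigenReml(y, X, eig)
        chromVar$sigmaG[ci] <- null$sigmaG
        chromVar$sigmaE[ci] <- null$sigmaE
        chromVar$nSnpsGrm[ci] <- nSnpsUsed(g)
        snps <- map$snp[map$chr == chr]
        M <- d[, snps, drop = FALSE]
        # mean-impute candidate dosages, then rotate
        mImp <- apply(M, 2, function(x) {
            x[is.na(x)] <- mean(x, na.rm = TRUE); x })
        Mr <- crossprod(null$U, mImp)
        colnames(Mr) <- snps
        bs <- .glsScan(null, Mr)
        stat <- (bs[, "beta"] / bs[, "se"])^2
        p <- pchisq(stat, df = 1, lower.tail = FALSE)
        resList[[ci]] <- data.frame(
            snp = snps, chr = chr, pos = map$pos[map$chr == chr],
            beta = bs[, "beta"], se = bs[, "se"], stat = stat, p = p,
            neglog10p = -log10(p), stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, resList)
    rownames(res) <- NULL
    new("GwasResult", results = res, chromVar = chromVar)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param nTests number of tests (>= 1).
#' @return list with `p` (= `alpha/nTests`) and `neglog10` (its -log10).
#' @examples
#' bonferroniThreshold(0.05, 54200)  # p ~ 9.23e-7, -log10 ~ 6.03
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    if (nTests < 1) stop("nTests must be at least 1")
    p <- alpha / nTests
    list(p = p, neglog10 = -log10(p))
}

#' Genomic inflation factor
#'
#' Median of the observed one-degree-of-freedom chi-square statistics over
#' the median of the chi-square(1) reference distribution; values near 1
#' indicate a well-calibrated scan.
#'
#' @param result a [GwasResult-class], or a numeric vector of chi-square(1)
#'   statistics (at least 100).
#' @return the inflation factor lambda.
#' @export
genomicInflation <- function(result) {
    stat <- if (is(result, "GwasResult")) result@results$stat else
        as.numeric(result)
    stat <- stat[is.finite(stat)]
    if (length(stat) < 100L)
        stop("at least 100 test statistics are required")
    median(stat) / qchisq(0.5, df = 1)
}
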
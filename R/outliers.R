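# Log transformation of OTU relative abundances and leverage-based outlier
# screening of each OTU regression on the host phenotypes.

#' Natural-log transform of relative abundances
#'
#' @param abundances strictly positive numeric vector/matrix of relative
#'   abundances. Zeros raise an error: restrict to OTUs present in every
#'   sample (the dominant OTUs satisfy this) before transforming.
#' @return elementwise natural logarithm.
#' @examples
#' lnTransform(c(0.329, 0.348))
#' @export
lnTransform <- function(abundances) {
    if (any(abundances <= 0))
        stop("abundances must be strictly positive; restrict to OTUs ",
             "present in all samples before log-transforming")
    log(abundances)
}

#' Leverage cutoff for outlier flagging
#'
#' The classical `3p/n` rule: observations whose hat-matrix diagonal
#' exceeds three times the average leverage `p/n` are flagged.
#'
#' @param p number of model parameters (including the intercept).
#' @param n number of samples, `n > p`.
#' @return the cutoff `3p/n`.
#' @examples
#' leverageCutoff(5, 150)  # 0.10
#' @export
leverageCutoff <- function(p, n) {
    if (n <= 0) stop("n must be positive")
    if (p <= 0 || p >= n) stop("need n > p > 0")
    3 * p / n
}

#' Detect influential samples in an OTU-on-phenotypes regression
#'
#' Ordinary least squares of the log OTU abundance on the phenotype design
#' matrix; influence is measured by the hat-matrix diagonal and samples
#' with leverage above `3p/n` are flagged (to be removed from that OTU's
#' downstream analyses).
#'
#' @param y numeric vector of log OTU abundances (optionally named by
#'   sample).
#' @param X design matrix including the intercept column, `nrow(X) > ncol(X)`.
#' @param statistic influence measure: `"leverage"` (hat diagonal, the
#'   default, flagged above `3p/n`), `"cooks"` (Cook's distance, flagged
#'   above `4/n`) or `"dffits"` (absolute DFFITS, flagged above
#'   `2*sqrt(p/n)`).
#' @return an [OutlierReport-class].
#' @export
detectOutliers <- function(y, X,
                           statistic = c("leverage", "cooks", "dffits")) {
    statistic <- match.arg(statistic)
    X <- as.matrix(X)
    n <- nrow(X); p <- ncol(X)
    stopifnot(length(y) == n)
    if (n <= p) stop("need more samples than parameters")
    q <- qr(X)
    if (q$rank < p) {
        bad <- colnames(X)[q$pivot[(q$rank + 1L):p]]
        stop("design matrix is rank deficient; collinear column(s): ",
             paste(bad, collapse = ", "))
    }
    fit <- lm(y ~ 0 + X)
    infl <- switch(statistic,
        leverage = unname(hatvalues(fit)),
        cooks = unname(stats::cooks.distance(fit)),
        dffits = abs(unname(stats::dffits(fit))))
    cut <- switch(statistic,
        leverage = leverageCutoff(p, n),
        cooks = 4 / n,
        dffits = 2 * sqrt(p / n))
    ids <- names(y) %||% rownames(X) %||% as.character(seq_len(n))
    names(infl) <- ids
    new("OutlierReport", p = as.integer(p), n = as.integer(n),
        cutoff = cut, influence = infl, flagged = ids[infl > cut])
}

#' Tabulate an outlier report
#'
#' @param report an [OutlierReport-class].
#' @param otu optional OTU label carried into the table.
#' @return data.frame with columns sample, otu, influence, cutoff, flagged.
#' @export
outlierTable <- function(report, otu = NA_character_) {
    data.frame(sample = names(report@influence), otu = otu,
               influence = unname(report@influence),
               cutoff = report@cutoff,
               flagged = names(report@influence) %in% report@flagged,
               stringsAsFactors = FALSE)
}
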
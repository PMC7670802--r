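# Mixed-model regression of host phenotypes on sampling day and the log
# abundances of the dominant OTUs, with random genomic-animal and tank
# effects, producing a long-format report of estimates, standard errors,
# Wald F and p-values per regressor.

#' Regress one phenotype on log OTU abundances under the animal model
#'
#' Fits `y = intercept + Day + Ln(OTU) regressions + animal + tank + e`
#' with `animal ~ N(0, G sigma_a^2)` and `tank ~ N(0, I sigma_t^2)` by
#' REML ([remlFit()]). Day enters as a linear regression on the day index.
#' Each fixed regressor gets a Wald F statistic with 1 numerator degree of
#' freedom and `n - rank(X)` denominator degrees of freedom. Collinear OTU
#' regressors raise an error naming the offending columns.
#'
#' @param response numeric phenotype vector.
#' @param lnOtu matrix of log OTU abundances (samples x OTUs), columns are
#'   the joint regressors.
#' @param day numeric/integer sampling-day index (linear covariate).
#' @param tank rearing-tank ids.
#' @param animal animal ids matching rows of the GRM.
#' @param grm a [Grm-class].
#' @param responseName label for the report.
#' @param ridge diagonal ridge for the relationship matrix.
#' @param ... passed to [remlFit()].
#' @return an [AssocFit-class].
#' @export
fitAssociation <- function(response, lnOtu, day, tank, animal, grm,
                           responseName = "phenotype", ridge = 1e-6, ...) {
    lnOtu <- as.matrix(lnOtu)
    n <- length(response)
    stopifnot(nrow(lnOtu) == n, length(day) == n, length(animal) == n)
    X <- cbind("(Intercept)" = 1, Day = as.numeric(day), lnOtu)
    q <- qr(X)
    if (q$rank < ncol(X)) {
        bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
        stop("collinear fixed regressors: ", paste(bad, collapse = ", "))
    }
    G <- grmMatrix(grm)
    miss <- setdiff(as.character(animal), rownames(G))
    if (length(miss))
        stop("animals absent from the GRM: ",
             paste(head(miss, 5), collapse = ", "))
    Ka <- G[as.character(animal), as.character(animal)] + diag(ridge, n)
    tf <- factor(tank)
    Klist <- list(animal = Ka)
    if (nlevels(tf) > 1)
        Klist$tank <- tcrossprod(stats::model.matrix(~0 + tf))
    fit <- remlFit(response, X, Klist, ...)
    est <- fit@fixef[-1]                  # drop intercept from the report
    se <- fit@fixefSE[-1]
    Fval <- (est / se)^2
    ddf <- n - ncol(X)
    tab <- data.frame(variable = names(est), estimate = unname(est),
                      se = unname(se), Fvalue = unname(Fval),
                      p = pf(unname(Fval), 1, ddf, lower.tail = FALSE),
                      stringsAsFactors = FALSE)
    new("AssocFit", response = responseName, table = tab, fit = fit)
}

#' Combine association fits into a long-format report
#'
#' One block per dependent variable: regressor estimates with standard
#' errors, F and p, significance markers at `p < 0.05` and `p < 0.005`,
#' followed by the tank and animal variance components with their standard
#' errors.
#'
#' @param fits list of [AssocFit-class] objects (at least one).
#' @return data.frame with columns dependent, variable, estimate, se,
#'   Fvalue, p, signif.
#' @export
buildAssocReport <- function(fits) {
    if (!length(fits)) stop("no fitted phenotypes to report")
    blocks <- lapply(fits, function(f) {
        stopifnot(is(f, "AssocFit"))
        tab <- f@table
        sig <- ifelse(tab$p < 0.005, "< 0.005",
                      ifelse(tab$p < 0.05, "< 0.05", "NS"))
        main <- data.frame(dependent = f@response, tab, signif = sig,
                           stringsAsFactors = FALSE)
        vc <- f@fit@varComp
        vcse <- f@fit@varCompSE
        pick <- function(v, nm) if (nm %in% names(v)) v[[nm]] else NA_real_
        ranTab <- data.frame(
            dependent = f@response,
            variable = c("Tank", "Animal"),
            estimate = c(pick(vc, "tank"), pick(vc, "animal")),
            se = c(pick(vcse, "tank"), pick(vcse, "animal")),
            Fvalue = NA_real_, p = NA_real_, signif = "",
            stringsAsFactors = FALSE)
        rbind(main, ranTab)
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
}
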
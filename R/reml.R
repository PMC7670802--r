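# Average-information REML for linear mixed models with dense covariance
# structures: y = X b + sum_k u_k + e,  u_k ~ N(0, sigma_k^2 K_k),
# e ~ N(0, sigma_e^2 I). Each K_k is a dense n x n PSD matrix (e.g. Za G Za'
# for the animal term, Zt Zt' for the tank term). Sized for the hundreds of
# phenotyped animals typical of tank-based family experiments, where dense
# O(n^3) linear algebra per iteration is cheap.

# Restricted log-likelihood up to an additive constant:
#   -1/2 [ log|V| + log|X'V^-1 X| + y'Py ]
# Shared by the fitter and by external grid/profile checks.
remlObjective <- function(theta, y, X, Klist) {
    n <- length(y)
    V <- diag(theta[length(theta)], n)
    for (k in seq_along(Klist))
        V <- V + theta[k] * Klist[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdetV <- 2 * sum(log(diag(ch)))
    Vinv <- chol2inv(ch)
    VinvX <- Vinv %*% X
    XtVinvX <- crossprod(X, VinvX)
    chX <- tryCatch(chol(XtVinvX), error = function(e) NULL)
    if (is.null(chX)) return(-Inf)
    logdetX <- 2 * sum(log(diag(chX)))
    Py <- Vinv %*% y - VinvX %*% chol2inv(chX) %*% crossprod(VinvX, y)
    as.numeric(-0.5 * (logdetV + logdetX + crossprod(y, Py)))
}

# One inner evaluation: P matrix, Py, logL, per-component traces and
# quadratic forms, and the average-information matrix.
.remlInner <- function(theta, y, X, Klist) {
    n <- length(y)
    ncomp <- length(theta)                     # last = residual
    V <- diag(theta[ncomp], n)
    for (k in seq_len(ncomp - 1L))
        V <- V + theta[k] * Klist[[k]]
    ch <- chol(V)
    Vinv <- chol2inv(ch)
    VinvX <- Vinv %*% X
    XtVinvX <- chol2inv(chol(crossprod(X, VinvX)))
    P <- Vinv - VinvX %*% XtVinvX %*% t(VinvX)
    Py <- P %*% y
    logL <- as.numeric(-0.5 * (2 * sum(log(diag(ch))) -
        2 * sum(log(diag(chol(XtVinvX)))) + crossprod(y, Py)))
    # W[, k] = K_k P y; residual column is Py itself
    W <- matrix(0, n, ncomp)
    trPK <- numeric(ncomp)
    for (k in seq_len(ncomp - 1L)) {
        W[, k] <- Klist[[k]] %*% Py
        trPK[k] <- sum(P * Klist[[k]])         # tr(P K), both symmetric
    }
    W[, ncomp] <- Py
    trPK[ncomp] <- sum(diag(P))
    score <- -0.5 * (trPK - colSums(W * c(Py)))
    AI <- 0.5 * crossprod(W, P %*% W)
    list(logL = logL, score = score, AI = AI, P = P, Py = Py,
         XtVinvXinv = XtVinvX, Vinv = Vinv)
}

#' Fit a variance-component mixed model by average-information REML
#'
#' Fits `y = X b + sum_k u_k + e` with `u_k ~ N(0, sigma_k^2 K_k)` and
#' i.i.d. residuals by Fisher scoring on the average-information matrix, with
#' step halving and a multiplicative expectation-maximization-style fallback
#' whenever an AI step would decrease the restricted likelihood. Components
#' driven negative are restricted to the zero boundary and flagged; each
#' boundary component is restarted once from a small positive value to guard
#' against spurious boundary solutions.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (must include the intercept).
#' @param Klist named list of dense PSD covariance structure matrices, one
#'   per non-residual random effect (e.g. `list(animal = ZGZt, tank = ZZt)`).
#'   The residual identity term is implicit and always last.
#' @param start optional starting values for `c(names(Klist), "residual")`;
#'   default splits the phenotypic variance equally.
#' @param maxit maximum iterations.
#' @param tol convergence tolerance on the relative change of the restricted
#'   log-likelihood (parameter changes must also fall below `1e-6` times the
#'   phenotypic variance).
#' @return a [VarCompFit-class]. `h2`/`c2` are filled when `Klist` contains
#'   components named `animal` / `tank` respectively.
#' @seealso [fitAnimalModel()] for the front-end taking a [Grm-class] and
#'   tank/day factors.
#' @export
remlFit <- function(y, X, Klist, start = NULL, maxit = 200L, tol = 1e-8) {
    y <- as.numeric(y)
    X <- as.matrix(X)
    n <- length(y)
    stopifnot(nrow(X) == n)
    if (qr(X)$rank < ncol(X))
        stop("fixed-effect design is rank deficient")
    if (n <= ncol(X)) stop("more fixed effects than observations")
    if (length(Klist) == 0L) {
        # residual-only model: closed-form REML
        p <- ncol(X)
        rss <- sum(qr.resid(qr(X), y)^2)
        se2 <- rss / (n - p)
        logL <- -0.5 * ((n - p) * log(se2) +
            determinant(crossprod(X), logarithm = TRUE)$modulus + (n - p))
        XtXinv <- chol2inv(chol(crossprod(X)))
        fe <- drop(XtXinv %*% crossprod(X, y))
        names(fe) <- colnames(X) %||% paste0("b", seq_len(p))
        return(new("VarCompFit",
            varComp = c(residual = se2),
            varCompSE = c(residual = se2 * sqrt(2 / (n - p))),
            varCompVcov = matrix(2 * se2^2 / (n - p), 1, 1,
                                 dimnames = list("residual", "residual")),
            h2 = NA_real_, h2SE = NA_real_, c2 = NA_real_, c2SE = NA_real_,
            logLik = as.numeric(logL),
            boundary = c(residual = FALSE), converged = TRUE,
            iterations = 0L, fixef = fe,
            fixefSE = sqrt(diag(XtXinv) * se2), n = as.integer(n)))
    }
    if (is.null(names(Klist)) || any(names(Klist) == ""))
        names(Klist) <- paste0("K", seq_along(Klist))
    for (K in Klist) stopifnot(identical(dim(K), c(n, n)))
    compNames <- c(names(Klist), "residual")
    ncomp <- length(compNames)
    vp <- stats::var(y)
    theta <- if (is.null(start)) rep(vp / ncomp, ncomp) else {
        stopifnot(length(start) == ncomp)
        as.numeric(start)
    }
    floorVal <- 0                         # boundary value
    held <- rep(FALSE, ncomp)             # fixed at boundary
    restarted <- rep(FALSE, ncomp)
    eps <- 1e-8 * vp

    inner <- .remlInner(theta, y, X, Klist)
    iter <- 0L
    converged <- FALSE
    while (iter < maxit) {
        iter <- iter + 1L
        free <- which(!held)
        score <- inner$score[free]
        AI <- inner$AI[free, free, drop = FALSE]
        delta <- tryCatch(solve(AI, score), error = function(e) NULL)
        stepOK <- FALSE
        if (!is.null(delta)) {
            fac <- 1
            for (h in 1:12) {
                cand <- theta
                cand[free] <- theta[free] + fac * delta
                newHeld <- cand < 0
                cand[newHeld] <- floorVal
                ll <- remlObjective(cand, y, X, Klist)
                if (is.finite(ll) && ll >= inner$logL - 1e-10) {
                    thetaNew <- cand
                    heldNew <- held | newHeld
                    stepOK <- TRUE
                    break
                }
                fac <- fac / 2
            }
        }
        if (!stepOK) {
            # multiplicative EM-style update: monotone, keeps positivity
            cand <- theta
            for (k in free) {
                Kk <- if (k < ncomp) Klist[[k]] else NULL
                KPy <- if (is.null(Kk)) inner$Py else Kk %*% inner$Py
                num <- as.numeric(crossprod(inner$Py, KPy))
                den <- if (is.null(Kk)) sum(diag(inner$P))
                       else sum(inner$P * Kk)
                if (den > 0) cand[k] <- theta[k] * num / den
            }
            cand[cand < 0] <- floorVal
            thetaNew <- cand
            heldNew <- held | (thetaNew <= 0 & theta <= eps)
        }
        thetaNew[heldNew] <- floorVal
        innerNew <- .remlInner(pmax(thetaNew, 0), y, X, Klist)
        dll <- abs(innerNew$logL - inner$logL) /
            (abs(inner$logL) + 1e-10)
        dpar <- max(abs(thetaNew - theta)) / vp
        theta <- thetaNew
        held <- heldNew
        inner <- innerNew
        if (dll < tol && dpar < 1e-6) {
            # restart boundary components once from a small positive value
            toRestart <- which(held & !restarted)
            if (length(toRestart)) {
                k <- toRestart[1L]
                restarted[k] <- TRUE
                held[k] <- FALSE
                theta[k] <- 0.01 * vp
                inner <- .remlInner(theta, y, X, Klist)
                next
            }
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning(sprintf("REML did not converge in %d iterations (last rel. dlogL %.2g)",
                        maxit, dll))
    theta <- pmax(theta, 0)
    held <- held | theta <= eps
    theta[held] <- 0
    names(theta) <- compNames

    # SEs of the free components from the inverse AI matrix
    free <- which(!held)
    se <- rep(NA_real_, ncomp)
    vcov <- matrix(NA_real_, ncomp, ncomp,
                   dimnames = list(compNames, compNames))
    if (length(free)) {
        AIf <- inner$AI[free, free, drop = FALSE]
        covf <- tryCatch(solve(AIf), error = function(e)
            matrix(NA_real_, length(free), length(free)))
        vcov[free, free] <- covf
        se[free] <- sqrt(pmax(diag(covf), 0))
    }

    # fixed effects by GLS at the REML solution
    fe <- drop(inner$XtVinvXinv %*% crossprod(X, inner$Vinv %*% y))
    feSE <- sqrt(diag(inner$XtVinvXinv))
    names(fe) <- names(feSE) <-
        colnames(X) %||% paste0("b", seq_len(ncol(X)))

    tot <- sum(theta)
    ratio <- function(comp) {
        if (!comp %in% compNames) return(c(NA_real_, NA_real_))
        r <- unname(theta[comp]) / tot
        g <- -theta / tot^2
        g[comp] <- g[comp] + 1 / tot
        cv <- vcov
        cv[is.na(cv)] <- 0               # held components: no sampling variance
        rse <- sqrt(max(drop(t(g) %*% cv %*% g), 0))
        c(r, rse)
    }
    h2 <- ratio("animal"); c2 <- ratio("tank")
    names(se) <- compNames
    new("VarCompFit", varComp = theta, varCompSE = se, varCompVcov = vcov,
        h2 = h2[1], h2SE = h2[2], c2 = c2[1], c2SE = c2[2],
        logLik = inner$logL,
        boundary = setNames(held, compNames),
        converged = converged, iterations = iter,
        fixef = fe, fixefSE = feSE, n = as.integer(n))
}

#' Fit the animal model with a tank effect to one OTU trait
#'
#' Fits `y = X b + Za a + Zt t + e` with `a ~ N(0, G sigma_a^2)` (genomic
#' relationship matrix `G`), `t ~ N(0, I sigma_t^2)` (rearing tank) and
#' i.i.d. residuals, by [remlFit()]. Fixed effects are an intercept plus the
#' sampling day as a factor. Heritability `h2 = sigma_a^2 / (sigma_a^2 +
#' sigma_t^2 + sigma_e^2)` and tank fraction `c2` are returned with
#' delta-method standard errors.
#'
#' @param y numeric trait vector (typically `Ln(OTU)` relative abundance),
#'   named by animal id or aligned with `animal`.
#' @param grm a [Grm-class] covering at least all phenotyped animals.
#' @param animal character vector of animal ids, one per observation.
#' @param tank factor/vector of rearing-tank ids (`NULL` drops the tank term).
#' @param day factor/vector of sampling day (`NULL` for intercept only).
#' @param includeGenetic set `FALSE` to fit the no-genetics null model used
#'   by the likelihood-ratio test.
#' @param ridge small value added to the diagonal of `G` before use, for
#'   numerical positive-definiteness (default `1e-6`).
#' @param ... passed to [remlFit()].
#' @return a [VarCompFit-class].
#' @examples
#' sim <- simulateStudy(studyDesign(nFamilies = 6, nSnps = 200,
#'                                  nChromosomes = 2), seed = 7)
#' ph <- sim$phenotypes
#' fit <- fitAnimalModel(sim$lnOtu[, "OTU1"], sim$grm,
#'                       animal = ph$animal, tank = ph$tank, day = ph$day)
#' varComp(fit)
#' @export
fitAnimalModel <- function(y, grm, animal, tank = NULL, day = NULL,
                           includeGenetic = TRUE, ridge = 1e-6, ...) {
    n <- length(y)
    stopifnot(length(animal) == n)
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    if (!is.null(day)) {
        f <- factor(day)
        if (nlevels(f) > 1)
            X <- cbind(X, stats::model.matrix(~f)[, -1, drop = FALSE])
        colnames(X) <- c("(Intercept)",
                         paste0("day", levels(f)[-1])[seq_len(ncol(X) - 1)])
    }
    Klist <- list()
    if (includeGenetic) {
        G <- grmMatrix(grm)
        miss <- setdiff(as.character(animal), rownames(G))
        if (length(miss))
            stop("animals absent from the GRM: ",
                 paste(head(miss, 5), collapse = ", "))
        Gs <- G[as.character(animal), as.character(animal)]
        Klist$animal <- Gs + diag(ridge, n)
    }
    if (!is.null(tank)) {
        Zt <- stats::model.matrix(~0 + factor(tank))
        Klist$tank <- tcrossprod(Zt)
    }
    if (!length(Klist)) stop("at least one random term is required")
    remlFit(y, X, Klist, ...)
}

#' Heritability from variance components
#'
#' `h2 = sigma_a^2 / (sigma_a^2 + sigma_t^2 + sigma_e^2)`.
#'
#' @param va,vt,ve additive-genetic, tank and residual variance components
#'   (all `>= 0`, positive total).
#' @return the heritability fraction.
#' @examples
#' heritability(0.007, 0.009, 0.25)  # ~0.03
#' @export
heritability <- function(va, vt, ve) {
    stopifnot(va >= 0, vt >= 0, ve >= 0)
    tot <- va + vt + ve
    if (tot <= 0) stop("total variance must be positive")
    va / tot
}

#' Fraction of variance explained by the rearing tank
#'
#' `c2 = sigma_t^2 / (sigma_a^2 + sigma_t^2 + sigma_e^2)`.
#'
#' @inheritParams heritability
#' @return the tank fraction.
#' @export
tankFraction <- function(va, vt, ve) {
    stopifnot(va >= 0, vt >= 0, ve >= 0)
    tot <- va + vt + ve
    if (tot <= 0) stop("total variance must be positive")
    vt / tot
}

#' Likelihood-ratio test for the additive genetic effect
#'
#' `LR = 2 (logL_H1 - logL_H0)`, floored at zero, referred to a chi-square
#' with one degree of freedom (the conventional reference; the
#' half-and-half chi-square boundary mixture is available via
#' `mixture = TRUE`).
#'
#' @param fitH1 [VarCompFit-class] of the model with the genetic term.
#' @param fitH0 [VarCompFit-class] of the same model without it (same data
#'   and fixed effects).
#' @param mixture use the 0.5*chisq(0) + 0.5*chisq(1) boundary null instead
#'   of plain chisq(1).
#' @return list with `statistic`, `df`, `p.value`.
#' @examples
#' # chi-square arithmetic: LR = 1.72 on 1 df
#' pchisq(1.72, df = 1, lower.tail = FALSE)  # ~0.19
#' @export
lrTestGenetic <- function(fitH1, fitH0, mixture = FALSE) {
    if (fitH1@n != fitH0@n)
        stop("fits are on different data (unequal n)")
    lr <- max(0, 2 * (fitH1@logLik - fitH0@logLik))
    p <- pchisq(lr, df = 1, lower.tail = FALSE)
    if (mixture) p <- if (lr == 0) 1 else 0.5 * p
    list(statistic = lr, df = 1L, p.value = min(p, 1))
}

#' Per-OTU heritability table
#'
#' Runs the animal model and its no-genetics null for every OTU column and
#' assembles a report with variance components, `c2` and `h2` (with standard
#' errors), the likelihood-ratio chi-square and its p-value, and boundary
#' flags.
#'
#' @param lnOtu numeric matrix of log OTU abundances, samples x OTUs.
#' @param grm a [Grm-class].
#' @param animal,tank,day per-sample design vectors, see [fitAnimalModel()].
#' @param ... passed on to [fitAnimalModel()].
#' @return data.frame with one row per OTU, mirroring the usual
#'   variance-component report layout.
#' @export
heritabilityTable <- function(lnOtu, grm, animal, tank, day = NULL, ...) {
    lnOtu <- as.matrix(lnOtu)
    out <- lapply(colnames(lnOtu), function(o) {
        y <- lnOtu[, o]
        f1 <- fitAnimalModel(y, grm, animal, tank, day, ...)
        f0 <- fitAnimalModel(y, grm, animal, tank, day,
                             includeGenetic = FALSE, ...)
        lr <- lrTestGenetic(f1, f0)
        vc <- f1@varComp
        data.frame(otu = o,
                   sigmaA = vc[["animal"]], sigmaT = vc[["tank"]],
                   sigmaE = vc[["residual"]],
                   c2 = f1@c2, c2SE = f1@c2SE,
                   h2 = f1@h2, h2SE = f1@h2SE,
                   chisq = lr$statistic, p = lr$p.value,
                   boundary = paste(names(which(f1@boundary)),
                                    collapse = ","),
                   converged = f1@converged)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
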
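# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the restricted likelihood is evaluated through
# the error-contrast definition (a basis of the null space of X'), leverage
# through the explicit hat-matrix formula, and REML maximizers through a
# coarse grid followed by Nelder-Mead polish of the contrast likelihood.

# Restricted log-likelihood of y under V(theta) via error contrasts:
# K'X = 0, K orthonormal; logL = log N(K'y; 0, K'VK) (full constants kept).
contrastLogLik <- function(theta, y, X, Klist) {
    n <- length(y)
    Q <- qr.Q(qr(X), complete = TRUE)
    K <- Q[, (ncol(X) + 1):n, drop = FALSE]
    V <- diag(theta[length(theta)], n)
    for (k in seq_along(Klist)) V <- V + theta[k] * Klist[[k]]
    S <- crossprod(K, V %*% K)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    z <- crossprod(K, y)
    m <- ncol(K)
    q <- backsolve(ch, z, transpose = TRUE)
    as.numeric(-0.5 * (m * log(2 * pi) + 2 * sum(log(diag(ch))) +
                       sum(q^2)))
}

# Maximize the contrast restricted likelihood by grid search + polish.
# Returns the maximizing variance components (same order as c(Klist, resid)).
oracleRemlMax <- function(y, X, Klist, gridN = 8) {
    vp <- var(y)
    ncomp <- length(Klist) + 1L
    grid <- seq(0.02, 1.2, length.out = gridN) * vp
    combos <- as.matrix(expand.grid(rep(list(grid), ncomp)))
    lls <- vapply(seq_len(nrow(combos)), function(i)
        contrastLogLik(combos[i, ], y, X, Klist), numeric(1))
    best <- combos[which.max(lls), ]
    opt <- optim(log(best), function(lt)
        -contrastLogLik(exp(lt), y, X, Klist),
        method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-14))
    exp(opt$par)
}

# Explicit hat-matrix diagonal.
hatDiagOracle <- function(X) {
    H <- X %*% solve(crossprod(X)) %*% t(X)
    diag(H)
}

# Balanced one-way ANOVA REML estimators (k groups x m per group):
# sigma_e^2 = MSW, sigma_g^2 = (MSB - MSW)/m.
anovaRemlOracle <- function(y, group) {
    group <- factor(group)
    k <- nlevels(group)
    m <- length(y) / k
    gm <- tapply(y, group, mean)
    msb <- m * sum((gm - mean(y))^2) / (k - 1)
    msw <- sum((y - gm[group])^2) / (k * (m - 1))
    c(group = (msb - msw) / m, residual = msw)
}

# A small simulated study shared by several test files.
smallStudy <- function(seed = 11, nFamilies = 8, nSnps = 300,
                       nChromosomes = 3, truth = simTruth()) {
    design <- studyDesign(nFamilies = nFamilies, nSnps = nSnps,
                          nChromosomes = nChromosomes)
    suppressMessages(simulateStudy(design, truth, seed = seed,
                                   depth = 12000))
}
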
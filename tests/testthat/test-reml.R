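# REML correctness: closed-form balanced ANOVA, the error-contrast
# grid-search oracle, an lme4 cross-check, boundary behaviour under the
# null, and the ratio arithmetic.

test_that("heritability and tank-fraction arithmetic", {
    expect_equal(round(heritability(0.007, 0.009, 0.25), 2), 0.03)
    expect_equal(round(tankFraction(0.007, 0.009, 0.25), 2), 0.03)
    expect_equal(heritability(0, 0.2, 0.3), 0)
    expect_equal(heritability(1, 0, 0), 1)
    expect_equal(tankFraction(0.3, 0, 0.7), 0)
    expect_equal(tankFraction(0.2, 0.2, 0.6), 0.2)
    expect_error(heritability(0, 0, 0), "positive")
    expect_error(tankFraction(-1, 0, 1))
})

test_that("likelihood-ratio test arithmetic and contracts", {
    mkFit <- function(ll, n = 100L) new("VarCompFit",
        varComp = c(animal = 1, residual = 1),
        varCompSE = c(animal = NA_real_, residual = NA_real_),
        varCompVcov = matrix(NA_real_, 2, 2), h2 = NA_real_, h2SE = NA_real_,
        c2 = NA_real_, c2SE = NA_real_, logLik = ll,
        boundary = c(animal = FALSE, residual = FALSE), converged = TRUE,
        iterations = 1L, fixef = 0, fixefSE = 0, n = n)
    eq <- lrTestGenetic(mkFit(-10), mkFit(-10))
    expect_equal(eq$statistic, 0)
    expect_equal(eq$p.value, 1)
    expect_equal(round(lrTestGenetic(mkFit(-10 + 1.72 / 2),
                                     mkFit(-10))$p.value, 2), 0.19)
    expect_equal(round(lrTestGenetic(mkFit(-10 + 0.13 / 2),
                                     mkFit(-10))$p.value, 2), 0.72)
    # H1 below H0 floors at zero rather than going negative
    expect_equal(lrTestGenetic(mkFit(-11), mkFit(-10))$statistic, 0)
    expect_error(lrTestGenetic(mkFit(-10), mkFit(-10, n = 50L)),
                 "different data")
})

test_that("balanced tank-only REML equals the one-way ANOVA estimators", {
    set.seed(91)
    k <- 12; m <- 6
    tank <- rep(seq_len(k), each = m)
    y <- 2 + rnorm(k, 0, sqrt(0.8))[tank] + rnorm(k * m, 0, 1.2)
    Zt <- model.matrix(~0 + factor(tank))
    fit <- remlFit(y, matrix(1, k * m, 1), list(tank = tcrossprod(Zt)))
    oracle <- anovaRemlOracle(y, tank)
    expect_equal(unname(fit@varComp[["tank"]]), unname(oracle[["group"]]),
                 tolerance = 1e-6)
    expect_equal(unname(fit@varComp[["residual"]]),
                 unname(oracle[["residual"]]), tolerance = 1e-6)
})

test_that("REML matches lme4 on a two-random-effect model", {
    skip_if_not_installed("lme4")
    set.seed(92)
    n <- 120
    tank <- rep(1:12, each = 10)
    fam <- rep(1:6, each = 20)
    day <- rep(1:4, 30)
    y <- 1 + 0.2 * day + rnorm(12, 0, 0.7)[tank] +
        rnorm(6, 0, 0.5)[fam] + rnorm(n)
    X <- model.matrix(~factor(day))
    Kt <- tcrossprod(model.matrix(~0 + factor(tank)))
    Kf <- tcrossprod(model.matrix(~0 + factor(fam)))
    fit <- remlFit(y, X, list(tank = Kt, fam = Kf))
    lfit <- lme4::lmer(y ~ factor(day) + (1 | tank) + (1 | fam),
                       REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(lfit))
    expect_equal(unname(fit@varComp[["tank"]]),
                 vc$vcov[vc$grp == "tank"], tolerance = 1e-4)
    expect_equal(unname(fit@varComp[["fam"]]),
                 vc$vcov[vc$grp == "fam"], tolerance = 1e-4)
    expect_equal(unname(fit@varComp[["residual"]]),
                 vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
    expect_equal(unname(fit@fixef), unname(lme4::fixef(lfit)),
                 tolerance = 1e-4)
})

test_that("estimates agree with the error-contrast grid-search oracle", {
    set.seed(93)
    nf <- 10; m <- 5; n <- nf * m             # 50-animal instance
    fam <- rep(seq_len(nf), each = m)
    # G = 2 x pedigree kinship: 1 on the diagonal, 0.5 within families
    G <- 0.5 * outer(fam, fam, "==") + diag(0.5, n)
    A <- chol(G)
    y <- 1 + drop(t(A) %*% rnorm(n, 0, sqrt(0.5))) + rnorm(n, 0, sqrt(0.5))
    X <- matrix(1, n, 1)
    fit <- remlFit(y, X, list(animal = G))
    oracle <- oracleRemlMax(y, X, list(animal = G))
    expect_equal(unname(fit@varComp), unname(oracle), tolerance = 1e-3)
    # and the returned optimum dominates random perturbations
    th <- fit@varComp
    for (r in 1:20) {
        pert <- pmax(th * exp(rnorm(2, 0, 0.3)), 1e-6)
        expect_gte(otuHerit:::remlObjective(th, y, X, list(animal = G)) + 1e-8,
                   otuHerit:::remlObjective(pert, y, X, list(animal = G)))
    }
})

test_that("i.i.d. data give no spurious genetic signal", {
    noSignal <- 0L
    n <- 200
    X <- matrix(1, n, 1)
    G <- diag(n)
    dimnames(G) <- list(paste0("i", 1:n), paste0("i", 1:n))
    grm <- new("Grm", G = G, nSnps = 1L, freq = 0.5)
    for (r in 1:20) {
        set.seed(500 + r)
        y <- rnorm(n)
        f1 <- suppressWarnings(
            fitAnimalModel(y, grm, animal = paste0("i", 1:n)))
        f0 <- remlFit(y, X, list())
        lr <- lrTestGenetic(f1, f0)
        # with G = I the genetic term adds nothing: it either sits on the
        # zero boundary or is statistically indistinguishable from zero
        if (f1@boundary[["animal"]] || lr$p.value > 0.05)
            noSignal <- noSignal + 1L
    }
    expect_gte(noSignal, 18L)                 # >= 90% of null fits
})

test_that("profile likelihood in the residual variance is unimodal", {
    set.seed(94)
    n <- 40
    fam <- rep(1:8, each = 5)
    G <- 0.5 * outer(fam, fam, "==") + diag(0.5, n)
    y <- drop(chol(G) %*% rnorm(n, 0, 0.6)) + rnorm(n, 0, 0.8)
    X <- matrix(1, n, 1)
    fit <- remlFit(y, X, list(animal = G))
    va <- fit@varComp[["animal"]]
    grid <- seq(0.2, 3, length.out = 40) * fit@varComp[["residual"]]
    prof <- vapply(grid, function(ve)
        otuHerit:::remlObjective(c(va, ve), y, X, list(animal = G)),
        numeric(1))
    signChanges <- sum(diff(sign(diff(prof))) != 0)
    expect_lte(signChanges, 1)
})

test_that("delta-method h2 standard error tracks the Monte-Carlo spread", {
    set.seed(95)
    nf <- 20; m <- 5; n <- nf * m
    fam <- rep(seq_len(nf), each = m)
    G <- 0.5 * outer(fam, fam, "==") + diag(0.5, n)
    ch <- chol(G)
    h2hat <- se <- numeric(50)
    X <- matrix(1, n, 1)
    for (r in 1:50) {
        y <- drop(t(ch) %*% rnorm(n, 0, sqrt(0.4))) + rnorm(n, 0, sqrt(0.6))
        fit <- suppressWarnings(remlFit(y, X, list(animal = G)))
        h2hat[r] <- fit@h2
        se[r] <- fit@h2SE
    }
    ratio <- mean(se, na.rm = TRUE) / sd(h2hat)
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 2)
})

test_that("input contracts are enforced", {
    expect_error(remlFit(rnorm(10), cbind(1, 1:10, 2 * (1:10)),
                         list(K = diag(10))), "rank deficient")
    expect_error(remlFit(rnorm(3), matrix(1, 3, 3) + diag(0:2),
                         list(K = diag(3))), "")
    sim <- smallStudy(seed = 15)
    expect_error(fitAnimalModel(rnorm(5), sim$grm,
                                animal = paste0("nope", 1:5)),
                 "absent from the GRM")
})
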
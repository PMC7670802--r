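# Phenotype-on-OTU mixed-model regression: degenerate-case equivalence with
# ordinary least squares, regressor-order invariance, collinearity
# contracts, and report layout.

mkIdentityGrm <- function(ids) {
    G <- diag(length(ids))
    dimnames(G) <- list(ids, ids)
    new("Grm", G = G, nSnps = 1L, freq = 0.5)
}

test_that("identity relationships and a single tank reduce to OLS", {
    set.seed(121)
    n <- 60
    ids <- paste0("i", 1:n)
    lnOtu <- matrix(rnorm(3 * n), n, 3,
                    dimnames = list(ids, c("OTU1", "OTU2", "OTU3")))
    day <- rep(1:4, 15)
    y <- 2 + 0.5 * day + 1.2 * lnOtu[, 2] + rnorm(n)
    fit <- fitAssociation(y, lnOtu, day = day, tank = rep("T1", n),
                          animal = ids, grm = mkIdentityGrm(ids))
    ols <- coef(lm(y ~ day + lnOtu))
    expect_equal(fit@table$estimate,
                 unname(ols[-1]), tolerance = 1e-6)
})

test_that("estimates are invariant to the order of OTU regressors", {
    set.seed(122)
    sim <- smallStudy(seed = 122)
    ph <- sim$phenotypes
    otus <- c("OTU1", "OTU2", "OTU3", "OTU5", "OTU6", "OTU7")
    f1 <- fitAssociation(ph$WG, sim$lnOtu[, otus], day = ph$day,
                         tank = ph$tank, animal = ph$animal, grm = sim$grm)
    f2 <- fitAssociation(ph$WG, sim$lnOtu[, rev(otus)], day = ph$day,
                         tank = ph$tank, animal = ph$animal, grm = sim$grm)
    e1 <- setNames(f1@table$estimate, f1@table$variable)
    e2 <- setNames(f2@table$estimate, f2@table$variable)
    expect_equal(e1[otus], e2[otus], tolerance = 1e-6)
})

test_that("collinear regressors raise an error naming the column", {
    set.seed(123)
    n <- 40
    ids <- paste0("i", 1:n)
    lnOtu <- matrix(rnorm(2 * n), n, 2,
                    dimnames = list(ids, c("OTU1", "OTU2")))
    lnOtu <- cbind(lnOtu, OTUdup = lnOtu[, "OTU1"])
    expect_error(
        fitAssociation(rnorm(n), lnOtu, day = rep(1:2, 20),
                       tank = rep(c("a", "b"), 20), animal = ids,
                       grm = mkIdentityGrm(ids)),
        "OTUdup")
    # a constant OTU column is collinear with the intercept
    lnOtu2 <- matrix(rnorm(2 * n), n, 2,
                     dimnames = list(ids, c("OTU1", "OTUconst")))
    lnOtu2[, 2] <- 1.7
    expect_error(
        fitAssociation(rnorm(n), lnOtu2, day = rep(1:2, 20),
                       tank = rep(c("a", "b"), 20), animal = ids,
                       grm = mkIdentityGrm(ids)),
        "collinear")
})

test_that("the combined report mirrors the expected layout", {
    sim <- smallStudy(seed = 124)
    ph <- sim$phenotypes
    otus <- c("OTU1", "OTU2", "OTU3", "OTU5", "OTU6", "OTU7")
    fits <- lapply(c("WG", "AAC"), function(v)
        fitAssociation(ph[[v]], sim$lnOtu[, otus], day = ph$day,
                       tank = ph$tank, animal = ph$animal, grm = sim$grm,
                       responseName = v))
    rep <- buildAssocReport(fits)
    wg <- rep[rep$dependent == "WG", ]
    expect_equal(nrow(wg), 7 + 2)        # Day + 6 OTUs + 2 variance comps
    expect_identical(wg$variable[1], "Day")
    expect_identical(utils::tail(wg$variable, 2), c("Tank", "Animal"))
    expect_error(buildAssocReport(list()), "no fitted")
    # significance labelling at the reported thresholds
    f <- fits[[1]]
    f@table$p <- c(0.004, 0.04, 0.5, 0.004999, 0.05, 0.951, 0.0001)
    lab <- buildAssocReport(list(f))$signif[1:7]
    expect_identical(lab, c("< 0.005", "< 0.05", "NS", "< 0.005",
                            "NS", "NS", "< 0.005"))
})

test_that("variance components recover simulated truth across replicates", {
    # phenotype simulated with known tank/animal variances; REML recovers
    # them within 2 Monte-Carlo standard errors over 20 replicates
    tanks <- 0; animals <- 0
    est <- matrix(NA_real_, 20, 2)
    for (r in 1:20) {
        d <- studyDesign(nFamilies = 15, nSnps = 200, nChromosomes = 2)
        g <- simulatePedigreeGenotypes(d, seed = 600 + r)
        ph <- g$familyMap[g$familyMap$phenotyped, ]
        dos <- dosages(g$genotypes)[ph$id, ]
        grm <- vanRadenGrm(GenotypeData(dos, snpMap(g$genotypes)))
        set.seed(700 + r)
        Z <- scale(dos, scale = FALSE)
        a <- drop(Z %*% rnorm(ncol(Z)))
        a <- a * sqrt(0.4) / sd(a)
        tEff <- rnorm(30, 0, sqrt(0.3))[as.integer(factor(ph$tank))]
        y <- 1 + a + tEff + rnorm(nrow(ph), 0, sqrt(0.5))
        lnOtu <- matrix(rnorm(nrow(ph)), ncol = 1,
                        dimnames = list(ph$id, "OTU1"))
        fit <- fitAssociation(y, lnOtu, day = ph$day, tank = ph$tank,
                              animal = ph$id, grm = grm)
        est[r, ] <- c(fit@fit@varComp[["animal"]],
                      fit@fit@varComp[["tank"]])
    }
    mcse <- apply(est, 2, sd) / sqrt(nrow(est))
    expect_lt(abs(mean(est[, 1]) - 0.4), 2 * mcse[1] + 0.05)
    expect_lt(abs(mean(est[, 2]) - 0.3), 2 * mcse[2] + 0.05)
})
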
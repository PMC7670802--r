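# The generator must reproduce the design's bookkeeping (family/tank/day
# layout), Mendelian inheritance, and the planted variance structure of the
# log OTU abundances.

test_that("design bookkeeping matches the family/tank/fish layout", {
    d <- studyDesign()
    expect_equal(d$nPhenotyped, 230L)
    g <- simulatePedigreeGenotypes(d, seed = 5)
    expect_equal(sum(g$familyMap$phenotyped), 230L)
    ph <- g$familyMap[g$familyMap$phenotyped, ]
    expect_equal(length(unique(ph$tank)), 46L)
    expect_true(all(table(ph$tank) == 5L))
    expect_error(studyDesign(nFamilies = 0), "positive")
    expect_error(studyDesign(nChromosomes = 1), "chromosomes")
})

test_that("offspring genotypes are Mendelian-consistent", {
    d <- studyDesign(nFamilies = 5, fishPerTank = 3, nSnps = 120,
                     nChromosomes = 2)
    g <- simulatePedigreeGenotypes(d, seed = 21)
    dos <- dosages(g$genotypes)
    fm <- g$familyMap
    nSires <- 4L
    off <- fm[fm$role == "offspring", ]
    for (f in unique(off$family)) {
        fIdx <- as.integer(sub("F", "", f))
        sire <- dos[sprintf("SIRE%02d", ((fIdx - 1L) %% nSires) + 1L), ]
        dam <- dos[sprintf("DAM%02d", fIdx), ]
        lo <- (sire == 2) + (dam == 2)
        hi <- (sire >= 1) + (dam >= 1)
        kids <- dos[off$id[off$family == f], , drop = FALSE]
        expect_true(all(t(kids) >= lo & t(kids) <= hi))
    }
    # forcing: both parents homozygous reference -> all offspring dosage 0
    bothZero <- which(dos["SIRE01", ] == 0 & dos["DAM01", ] == 0)
    kids <- dos[off$id[off$family == "F01"], bothZero, drop = FALSE]
    expect_true(all(kids == 0))
})

test_that("full-sib genomic relationship is near the pedigree expectation", {
    d <- studyDesign(nFamilies = 12, fishPerTank = 4, nSnps = 2000,
                     nChromosomes = 4)
    g <- simulatePedigreeGenotypes(d, seed = 31)
    ph <- g$familyMap[g$familyMap$phenotyped, ]
    grm <- vanRadenGrm(GenotypeData(dosages(g$genotypes)[ph$id, ],
                                    snpMap(g$genotypes)))
    G <- grmMatrix(grm)
    sameFam <- outer(ph$family, ph$family, "==") & !diag(nrow(ph))
    expect_lt(abs(mean(G[sameFam]) - 0.5), 0.05)   # pedigree oracle: sibs 0.5
})

test_that("h2 = c2 = 0 leaves no detectable between-family variance", {
    rejections <- 0L
    for (r in 1:50) {
        d <- studyDesign(nFamilies = 10, tanksPerFamily = 1,
                         fishPerTank = 5, nSnps = 60, nChromosomes = 2)
        g <- simulatePedigreeGenotypes(d, seed = 100 + r)
        op <- simulateOtuPhenotypes(g$genotypes, g$familyMap,
                                    simTruth(h2 = 0, c2 = 0), d,
                                    seed = 200 + r)
        fm <- g$familyMap[g$familyMap$phenotyped, ]
        p <- anova(lm(op$lnOtu[, "OTU1"] ~ factor(fm$family)))[["Pr(>F)"]][1]
        if (p < 0.01) rejections <- rejections + 1L
    }
    expect_lte(rejections, 5L)
})

test_that("zero OTU effects leave phenotypes uncorrelated with OTUs", {
    d <- studyDesign(nFamilies = 100, nSnps = 100, nChromosomes = 2)
    g <- simulatePedigreeGenotypes(d, seed = 41)
    tr <- simTruth(otuEffects = matrix(0, 6, 13,
        dimnames = list(c("OTU1", "OTU2", "OTU3", "OTU5", "OTU6", "OTU7"),
                        otuHerit:::.phenoVariables)))
    op <- simulateOtuPhenotypes(g$genotypes, g$familyMap, tr, d, seed = 42)
    expect_equal(nrow(op$phenotypes), 1000L)
    for (v in c("WG", "AAC"))
        expect_lt(abs(cor(op$phenotypes[[v]], op$lnOtu[, "OTU3"])), 0.1)
})

test_that("realized variance fractions of Ln(OTU) match their targets", {
    targets <- c(h2 = 0.3, c2 = 0.15)
    base <- c(OTU1 = 0.5, OTU2 = 0.3, OTU3 = 0.2)
    h2s <- c2s <- numeric(50)
    for (r in 1:50) {
        d <- studyDesign(nFamilies = 50, nSnps = 200, nChromosomes = 2)
        g <- simulatePedigreeGenotypes(d, seed = 300 + r)
        op <- simulateOtuPhenotypes(g$genotypes, g$familyMap,
            simTruth(h2 = targets["h2"], c2 = targets["c2"],
                     baseline = base), d, seed = 400 + r)
        h2s[r] <- var(op$truthValues$breedingValues[, "OTU1"]) /
            var(op$lnOtu[, "OTU1"] -
                op$truthValues$dayShift[as.character(op$phenotypes$day)])
        c2s[r] <- var(op$truthValues$tankEffects[, "OTU1"]) /
            var(op$lnOtu[, "OTU1"] -
                op$truthValues$dayShift[as.character(op$phenotypes$day)])
    }
    expect_lt(abs(mean(h2s) - targets["h2"]), 0.05)
    expect_lt(abs(mean(c2s) - targets["c2"]), 0.05)
})

test_that("identical seeds give identical outputs", {
    d <- studyDesign(nFamilies = 4, nSnps = 80, nChromosomes = 2)
    a <- suppressMessages(simulateStudy(d, seed = 9, depth = 4000))
    b <- suppressMessages(simulateStudy(d, seed = 9, depth = 4000))
    expect_identical(dosages(a$genotypes), dosages(b$genotypes))
    expect_identical(otuCounts(a$untreated), otuCounts(b$untreated))
    expect_identical(a$phenotypes, b$phenotypes)
    c <- suppressMessages(simulateStudy(d, seed = 10, depth = 4000))
    expect_false(identical(otuCounts(a$untreated), otuCounts(c$untreated)))
})

test_that("truth validation rejects inconsistent inputs", {
    expect_error(simTruth(h2 = 0.6, c2 = 0.5), "h2 \\+ c2")
    expect_error(simTruth(deadOtus = c(X = 2)), "exceed 3")
    expect_error(simTruth(contamOtus = c(X = 5)), "exceed 6")
    expect_error(simTruth(deadOtus = c(X = 5), contamOtus = c(X = 12)),
                 "disjoint")
    d <- studyDesign(nFamilies = 2, nSnps = 20, nChromosomes = 2)
    expect_error(simulatePedigreeGenotypes(d, mafRange = c(0, 0.6)),
                 "mafRange")
})
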
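# Rarefaction, viability classification and dataset screening against
# hypergeometric expectations and planted truth.

test_that("rarefaction subsamples without replacement to the target depth", {
    x <- c(a = 4000, b = 3000, c = 3000)
    r <- rarefyCounts(x, depth = 10000, seed = 1)
    expect_true(r$pass)
    expect_identical(r$counts, x)                  # total == depth: identity
    r2 <- rarefyCounts(c(9000, 6000), depth = 10000, seed = 1)
    expect_true(r2$pass)
    expect_equal(sum(r2$counts), 10000)
    expect_true(all(r2$counts <= c(9000, 6000)))   # without replacement
    expect_false(rarefyCounts(c(5000, 4000), depth = 10000)$pass)
    expect_error(rarefyCounts(c(-1, 5), 2), "negative")
    expect_error(rarefyCounts(c(1, 5), 0), "positive")
})

test_that("rarefaction matches the hypergeometric expectation", {
    firsts <- vapply(1:10000, function(s)
        rarefyCounts(c(5, 5), depth = 4, seed = s)$counts[1], numeric(1))
    expect_lt(abs(mean(firsts) - 2.0), 0.05)
})

test_that("rarefaction preserves expected relative abundance", {
    x <- c(600, 250, 100, 50)
    rel <- x / sum(x)
    mc <- rowMeans(vapply(1:400, function(s)
        rarefyCounts(x, depth = 200, seed = s)$counts / 200,
        numeric(4)))
    expect_true(all(abs(mc - rel) < 0.01))
})

test_that("viability thresholds classify live, dead and contaminant", {
    expect_equal(classifyOtuViability(60, 5)$label, "contaminant")
    expect_equal(classifyOtuViability(40, 10)$label, "dead")
    expect_equal(classifyOtuViability(10, 10)$label, "live")
    expect_equal(classifyOtuViability(0, 0)$label, "undetected")
    expect_equal(classifyOtuViability(0, 50)$label, "live")
    # unequal depths enter through relative abundances
    r <- classifyOtuViability(60, 5, depthUntreated = 10000,
                              depthPma = 10000)
    expect_gt(r$ratio, 6)
})

test_that("per-sample calls partition observed OTUs; contamFold is monotone", {
    sim <- smallStudy(seed = 13)
    scr <- screenDataset(sim$pma, sim$untreated, depth = 10000, seed = 2)
    otusAll <- union(rownames(otuCounts(sim$pma)),
                     rownames(otuCounts(sim$untreated)))
    filt <- otuCounts(scr@filtered)
    for (s in utils::head(scr@qcPass, 4)) {
        calls <- scr@calls[scr@calls$sample == s, ]
        # the calls partition the observed (non-undetected) OTU set
        expect_true(all(calls$label %in% c("live", "dead", "contaminant")))
        expect_true(all(table(calls$otu) == 1))
        # dead/contaminant OTUs are removed from that sample's counts
        removed <- calls$otu[calls$label != "live"]
        expect_true(all(filt[removed, s] == 0))
    }
    scr2 <- screenDataset(sim$pma, sim$untreated, depth = 10000,
                          contamFold = 12, seed = 2)
    expect_lte(sum(scr2@calls$label == "contaminant"),
               sum(scr@calls$label == "contaminant"))
})

test_that("all-live data yield zero dead and contaminant fractions", {
    sim <- smallStudy(seed = 17,
                      truth = simTruth(deadOtus = numeric(),
                                       contamOtus = numeric()))
    scr <- screenDataset(sim$pma, sim$untreated, depth = 5000, seed = 3)
    # no planted signal: expected untreated/PMA ratio ~ 1 per OTU
    expect_lt(scr@summary$fractionDeadReads, 0.01)
    expect_lt(scr@summary$fractionContamReads, 0.01)
    expect_equal(scr@summary$nDead + scr@summary$nContam, 0)
    # expected untreated/PMA ratio ~ 1 for the dominant OTUs
    for (o in c("OTU1", "OTU2")) {
        calls <- scr@calls[scr@calls$otu == o, ]
        expect_lt(abs(mean(calls$ratio) - 1), 0.2)
    }
})

test_that("samples below depth in either arm are excluded from QC pass", {
    cnt <- matrix(c(6000, 6000, 4000, 3000), 2, 2,
                  dimnames = list(c("OTU1", "OTU2"), c("good", "shallow")))
    unt <- OtuTable(cnt, arm = "untreated")
    pma <- OtuTable(cnt * 2, arm = "pma")
    scr <- screenDataset(pma, unt, depth = 10000, seed = 1)
    expect_identical(as.character(scr@qcPass), "good")
    other <- cnt
    colnames(other) <- c("x1", "x2")
    expect_error(screenDataset(OtuTable(other, arm = "pma"), unt),
                 "overlap")
})

test_that("planted fold factors are recovered by classification", {
    # fold 4 -> dead (3 < r <= 6), fold 10 -> contaminant, end to end
    tr <- simTruth(deadOtus = c(DEADX = 4), contamOtus = c(CONX = 10),
                   deadReadFraction = 0.04, contamReadFraction = 0.02)
    sim <- smallStudy(seed = 23, truth = tr)
    scr <- screenDataset(sim$pma, sim$untreated, depth = 10000, seed = 5)
    expect_identical(unname(scr@otuClass[["DEADX"]]), "dead")
    expect_identical(unname(scr@otuClass[["CONX"]]), "contaminant")
    calls <- scr@calls[scr@calls$otu == "CONX", ]
    expect_gte(mean(calls$label == "contaminant"), 0.95)
})

test_that("community summary finds the dominant OTUs", {
    comp <- c(OTU1 = 0.6, OTU2 = 0.3, OTU3 = 0.1)
    cnt <- cbind(S1 = comp * 1000, S2 = comp * 2000)
    tab <- OtuTable(cnt, arm = "live")
    cs <- summarizeCommunity(tab)
    expect_equal(setNames(cs$perOtu$meanAbundance, cs$perOtu$otu), comp)
    one <- OtuTable(rbind(OTU1 = c(100, 200), OTU2 = c(0, 0)), arm = "live")
    expect_identical(summarizeCommunity(one)$highAbundance, "OTU1")
    expect_error(summarizeCommunity(OtuTable(cbind(S1 = c(OTU1 = 0)),
                                             arm = "live")), "empty")
})

test_that("a six-OTU dominant structure yields exactly six above 1%", {
    base <- otuHerit:::.defaultBaseline()
    cnt <- vapply(1:20, function(i) round(base * 10000), numeric(length(base)))
    dimnames(cnt) <- list(names(base), paste0("S", 1:20))
    cs <- summarizeCommunity(OtuTable(cnt, arm = "live"))
    expect_setequal(cs$highAbundance,
                    c("OTU1", "OTU2", "OTU3", "OTU5", "OTU6", "OTU7"))
})

test_that("Spearman correlations follow rank arithmetic", {
    cnt <- rbind(x = c(10, 20, 30), y = c(30, 20, 10),
                 filler = c(60, 60, 60))
    colnames(cnt) <- paste0("S", 1:3)
    rho <- spearmanMatrix(OtuTable(cnt, arm = "live"))
    expect_equal(rho["x", "y"], -1)
    expect_true(is.na(rho["filler", "x"]))     # constant column
    expect_equal(diag(rho), rep(1, 3), ignore_attr = TRUE)

    cnt2 <- rbind(x = c(10, 20, 30, 40), y = c(20, 10, 40, 30),
                  f = c(70, 70, 30, 30))
    colnames(cnt2) <- paste0("S", 1:4)
    rho2 <- spearmanMatrix(OtuTable(cnt2, arm = "live"))
    expect_equal(rho2["x", "y"], 0.6)          # 1 - 6*4/(4*15)
    # monotone invariance: y = exp(x)
    cnt3 <- rbind(x = c(10, 20, 30), y = round(exp(c(1, 2, 3))),
                  f = c(50, 40, 30))
    colnames(cnt3) <- paste0("S", 1:3)
    expect_equal(spearmanMatrix(OtuTable(cnt3, arm = "live"))["x", "y"], 1)
    expect_error(spearmanMatrix(OtuTable(cnt2[, 1:2], arm = "live")),
                 "3 samples")
})
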
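# Synthetic-data generator for the full-sib family / dual rearing-tank
# design: family-structured genotypes, log OTU abundances with specified
# additive-genetic and tank variance fractions, paired PMA/untreated count
# tables with planted dead and contaminant OTUs, and host phenotypes with
# specified regressions on the log OTU abundances.

#' Describe a family/tank study design
#'
#' Parameter bag for the experimental layout: full-sib families split over
#' rearing tanks, a fixed number of fish sampled per tank, optional
#' additional genotyped-but-unphenotyped relatives, and the SNP panel
#' layout. Defaults mirror a 23-family x 2-tank x 5-fish design sampled
#' over 4 days (230 phenotyped fish) with a desk-scale SNP panel.
#'
#' @param nFamilies number of full-sib families.
#' @param tanksPerFamily rearing tanks per family.
#' @param fishPerTank fish sampled per tank.
#' @param nGenotypedExtra extra genotyped, non-phenotyped sibs (spread over
#'   families) enlarging the relationship-matrix population.
#' @param nSnps number of biallelic SNPs.
#' @param nChromosomes number of chromosomes the SNPs are spread over
#'   (at least 2, so one can always be left out).
#' @param samplingDays vector of sampling-day labels.
#' @return a `StudyDesign` list.
#' @examples
#' d <- studyDesign()
#' d$nFamilies * d$tanksPerFamily * d$fishPerTank  # 230 phenotyped fish
#' @export
studyDesign <- function(nFamilies = 23L, tanksPerFamily = 2L,
                        fishPerTank = 5L, nGenotypedExtra = 0L,
                        nSnps = 2000L, nChromosomes = 29L,
                        samplingDays = 1:4) {
    d <- list(nFamilies = as.integer(nFamilies),
              tanksPerFamily = as.integer(tanksPerFamily),
              fishPerTank = as.integer(fishPerTank),
              nGenotypedExtra = as.integer(nGenotypedExtra),
              nSnps = as.integer(nSnps),
              nChromosomes = as.integer(nChromosomes),
              samplingDays = samplingDays)
    if (any(vapply(d[1:6], length, 1L) != 1L) ||
        d$nFamilies < 1L || d$tanksPerFamily < 1L || d$fishPerTank < 1L ||
        d$nSnps < 1L || d$nGenotypedExtra < 0L)
        stop("design counts must be positive scalars")
    if (d$nChromosomes < 2L)
        stop("at least 2 chromosomes are required (one must be leavable-out)")
    if (length(samplingDays) < 1L)
        stop("at least one sampling day is required")
    d$nPhenotyped <- d$nFamilies * d$tanksPerFamily * d$fishPerTank
    class(d) <- "StudyDesign"
    d
}

# Default live community: two dominant OTUs plus four mid-abundance OTUs
# jointly carrying 85% of live reads (OTU4 is reserved for the planted dead
# set, hence the gap in the numbering), and a 20-OTU low-abundance tail.
.defaultBaseline <- function() {
    top <- c(OTU1 = 0.329, OTU2 = 0.348, OTU3 = 0.060, OTU5 = 0.050,
             OTU6 = 0.040, OTU7 = 0.023)
    tail <- rep(0.15 / 20, 20)             # each well below the 1% threshold
    names(tail) <- paste0("OTU", 8:27)
    c(top, tail)
}

.phenoVariables <- c("IW", "FW", "WG", "RG", "AMC", "AMN", "ALC", "ALN",
                     "AAC", "IFCR_AMC", "IFCR_AMN", "IFER_AMC", "IFER_AMN")

# Per-phenotype generative parameters: baseline level, per-day slope, and
# tank/animal/residual variances on the phenotype's own scale.
.defaultPhenoParams <- function() {
    p <- data.frame(
        variable = .phenoVariables,
        base   = c(20, 45, 25, 50, 1.5, 1.0, 1.6, 1.1, 1.3,
                   1.2, 1.1, 0.5, 0.45),
        dayCoef = c(0, 3.338, 3.338, 2.0, 0.05, 0.03, 0.05, 0.03, 0.082,
                    -0.05, -0.04, 0.365, 0.149),
        tankVar = c(1.0, 14, 13.84, 20, 0.05, 0.02, 0.05, 0.02, 0.90,
                    0.05, 0.04, 0.20, 0.04),
        animalVar = c(2.0, 6, 5.54, 8, 0.02, 0.01, 0.02, 0.01, 1e-4,
                      0.02, 0.02, 4.3e-3, 2.9e-4),
        residVar = c(2.0, 12, 10, 15, 0.04, 0.02, 0.04, 0.02, 0.5,
                     0.04, 0.03, 0.10, 0.02))
    rownames(p) <- p$variable
    p
}

#' Planted ground truth for a simulated study
#'
#' Collects everything the generator needs and downstream recovery tests
#' assert against: per-OTU additive-genetic (`h2`) and tank (`c2`) variance
#' fractions of the log abundances, regression coefficients of each
#' phenotype on the log OTU abundances, the planted dead and contaminant
#' OTUs with their untreated/PMA fold factors, and the read fractions the
#' planted sets carry in the untreated arm.
#'
#' Default fold factors sit well inside their class windows (5 for dead,
#' 12 for contaminants) so classification is stable under multinomial
#' counting noise; default effect sizes are on the scale of reported
#' salmon gut microbiome associations (e.g. a weight-gain slope of -1.352 g
#' per log-unit of the *Sphingomonas* OTU).
#'
#' @param nOtus number of live OTUs (>= 6; the first six named
#'   OTU1,2,3,5,6,7 are the high-abundance set).
#' @param h2,c2 scalar or per-OTU additive-genetic and tank variance
#'   fractions of log abundance (`h2 + c2 < 1`).
#' @param otuEffects matrix of regression coefficients, high-abundance OTUs
#'   x phenotypes (rows OTU1,2,3,5,6,7; columns the 13 phenotype
#'   variables). Default plants the reported significant associations.
#' @param deadOtus named numeric of untreated/PMA fold factors (> 3) for
#'   planted dead OTUs; `contamOtus` likewise with folds > 6. The sets must
#'   be disjoint.
#' @param deadReadFraction,contamReadFraction fractions of untreated-arm
#'   reads carried by the planted dead / contaminant sets. The default dead
#'   fraction (9.1%) is on the scale reported for salmon gut communities;
#'   the contaminant default (1%) is large enough to be observable at
#'   rarefaction depths of ten thousand reads (real contaminant loads can
#'   be orders of magnitude smaller).
#' @param dayEffects additive shift of log OTU abundance per sampling day.
#' @param baseline named mean relative abundances of the live OTUs
#'   (overrides `nOtus`).
#' @return a `SimTruth` list.
#' @export
simTruth <- function(nOtus = 26L, h2 = 0.05, c2 = 0.05,
                     otuEffects = NULL,
                     deadOtus = c(OTU4 = 5, DEAD1 = 5, DEAD2 = 5,
                                  DEAD3 = 5, DEAD4 = 5),
                     contamOtus = c(CONTAM1 = 12, CONTAM2 = 12, CONTAM3 = 12),
                     deadReadFraction = 0.091, contamReadFraction = 0.01,
                     dayEffects = NULL, baseline = NULL) {
    if (is.null(baseline)) {
        baseline <- .defaultBaseline()
        if (nOtus < 6L) stop("at least 6 live OTUs are required")
        baseline <- baseline[seq_len(min(nOtus, length(baseline)))]
        baseline <- baseline / sum(baseline)
    }
    nOtus <- length(baseline)
    h2 <- rep_len(h2, nOtus); c2 <- rep_len(c2, nOtus)
    names(h2) <- names(c2) <- names(baseline)
    if (any(h2 < 0) || any(c2 < 0) || any(h2 + c2 >= 1))
        stop("per-OTU variance fractions must satisfy h2 >= 0, c2 >= 0, h2 + c2 < 1")
    if (length(intersect(names(deadOtus), names(contamOtus))))
        stop("dead and contaminant OTU sets must be disjoint")
    if (length(deadOtus) && any(deadOtus <= 3))
        stop("dead fold factors must exceed 3")
    if (length(contamOtus) && any(contamOtus <= 6))
        stop("contaminant fold factors must exceed 6")
    highAb <- intersect(c("OTU1", "OTU2", "OTU3", "OTU5", "OTU6", "OTU7"),
                        names(baseline))
    if (is.null(otuEffects)) {
        otuEffects <- matrix(0, length(highAb), length(.phenoVariables),
                             dimnames = list(highAb, .phenoVariables))
        plant <- rbind(
            c("OTU3", "WG", -1.352), c("OTU5", "AAC", 0.006),
            c("OTU7", "AAC", 0.010), c("OTU1", "IFER_AMC", 0.043),
            c("OTU7", "IFER_AMC", 0.081), c("OTU1", "IFER_AMN", 0.020),
            c("OTU7", "IFER_AMN", 0.027))
        for (i in seq_len(nrow(plant)))
            if (plant[i, 1] %in% highAb)
                otuEffects[plant[i, 1], plant[i, 2]] <-
                    as.numeric(plant[i, 3])
    } else {
        otuEffects <- as.matrix(otuEffects)
        stopifnot(!is.null(rownames(otuEffects)), !is.null(colnames(otuEffects)))
    }
    structure(list(baseline = baseline, h2 = h2, c2 = c2,
                   otuEffects = otuEffects, deadOtus = deadOtus,
                   contamOtus = contamOtus,
                   deadReadFraction = deadReadFraction,
                   contamReadFraction = contamReadFraction,
                   dayEffects = dayEffects,
                   phenoParams = .defaultPhenoParams()),
              class = "SimTruth")
}

# Mendelian gamete: number of copies of the counted allele transmitted by a
# parent with the given dosage (0 -> 0, 2 -> 1, 1 -> Bernoulli(1/2)).
.transmit <- function(parentDosage) {
    out <- matrix(0, nrow(parentDosage), ncol(parentDosage))
    het <- parentDosage == 1
    out[parentDosage == 2] <- 1
    out[het] <- rbinom(sum(het), 1, 0.5)
    out
}

#' Simulate family-structured genotypes
#'
#' Draws parental genotypes in Hardy-Weinberg proportions at allele
#' frequencies uniform on `mafRange`, then produces full-sib offspring by
#' Mendelian transmission (one allele per parent per locus). One sire is
#' mated to two dams when `nFamilies > 1`, mirroring designs with slightly
#' fewer sires than dams. SNPs are assigned evenly to chromosomes.
#'
#' @param design a [studyDesign()].
#' @param mafRange allele-frequency interval within (0, 0.5].
#' @param seed integer seed.
#' @return list with `genotypes` (a [GenotypeData-class] for parents and
#'   offspring) and `familyMap` (data.frame: id, family, tank, day, role,
#'   phenotyped).
#' @examples
#' g <- simulatePedigreeGenotypes(studyDesign(nFamilies = 3, nSnps = 50,
#'                                            nChromosomes = 2), seed = 1)
#' table(g$familyMap$role)
#' @export
simulatePedigreeGenotypes <- function(design, mafRange = c(0.05, 0.5),
                                      seed = 1L) {
    stopifnot(inherits(design, "StudyDesign"))
    if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
        stop("mafRange must lie within (0, 0.5]")
    withr::with_seed(seed, {
        m <- design$nSnps
        nf <- design$nFamilies
        p <- runif(m, mafRange[1], mafRange[2])
        nSires <- max(1L, nf - 1L)
        sireOf <- ((seq_len(nf) - 1L) %% nSires) + 1L
        sires <- matrix(rbinom(nSires * m, 2, rep(p, each = nSires)),
                        nSires, m)
        dams <- matrix(rbinom(nf * m, 2, rep(p, each = nf)), nf, m)

        perFam <- design$tanksPerFamily * design$fishPerTank
        extra <- rep(design$nGenotypedExtra %/% nf, nf)
        if (design$nGenotypedExtra %% nf)
            extra[seq_len(design$nGenotypedExtra %% nf)] <-
                extra[seq_len(design$nGenotypedExtra %% nf)] + 1L
        offList <- vector("list", nf)
        mapList <- vector("list", nf)
        for (f in seq_len(nf)) {
            nOff <- perFam + extra[f]
            sireD <- matrix(sires[sireOf[f], ], nOff, m, byrow = TRUE)
            damD <- matrix(dams[f, ], nOff, m, byrow = TRUE)
            offList[[f]] <- .transmit(sireD) + .transmit(damD)
            phen <- c(rep(TRUE, perFam), rep(FALSE, extra[f]))
            tank <- c(rep(sprintf("T%02d_%d", f, seq_len(design$tanksPerFamily)),
                          each = design$fishPerTank),
                      rep(NA_character_, extra[f]))
            day <- c(rep_len(design$samplingDays, perFam),
                     rep(NA, extra[f]))
            mapList[[f]] <- data.frame(
                id = sprintf("F%02d_%02d", f, seq_len(nOff)),
                family = sprintf("F%02d", f), tank = tank, day = day,
                role = "offspring", phenotyped = phen,
                stringsAsFactors = FALSE)
        }
        off <- do.call(rbind, offList)
        map <- do.call(rbind, mapList)
        parentIds <- c(sprintf("SIRE%02d", seq_len(nSires)),
                       sprintf("DAM%02d", seq_len(nf)))
        parentMap <- data.frame(id = parentIds, family = NA_character_,
                                tank = NA_character_, day = NA,
                                role = "parent", phenotyped = FALSE,
                                stringsAsFactors = FALSE)
        dos <- rbind(sires, dams, off)
        rownames(dos) <- c(parentIds, map$id)
        snpIds <- sprintf("snp%05d", seq_len(m))
        colnames(dos) <- snpIds
        chr <- sort(rep_len(seq_len(design$nChromosomes), m))
        snpmap <- data.frame(snp = snpIds, chr = paste0("chr", chr),
                             pos = unlist(lapply(table(chr), seq_len)) * 1000L)
        list(genotypes = GenotypeData(dos, snpmap),
             familyMap = rbind(parentMap, map))
    })
}

# Breeding values from i.i.d. normal SNP effects (infinitesimal model),
# scaled so that var(a) equals targetVar in the simulated population.
.breedingValues <- function(Z, targetVar) {
    if (targetVar <= 0) return(numeric(nrow(Z)))
    beta <- rnorm(ncol(Z))
    a <- drop(Z %*% beta)
    a * sqrt(targetVar) / stats::sd(a)
}

#' Simulate log OTU abundances and host phenotypes
#'
#' For each live OTU the log abundance of a phenotyped fish is
#' `log(baseline) + day shift + a + t + e`, where the additive genetic value
#' `a` comes from i.i.d. normal effects over all SNPs scaled to variance
#' `h2`, the tank effect has variance `c2`, and the residual variance
#' `1 - h2 - c2` (unit total variance on the log scale). Host phenotypes are
#' linear in sampling day and the log abundances of the high-abundance OTUs,
#' plus their own genetic, tank and residual terms.
#'
#' @param geno a [GenotypeData-class] from [simulatePedigreeGenotypes()].
#' @param familyMap the matching family map.
#' @param truth a [simTruth()].
#' @param design the [studyDesign()] used.
#' @param seed integer seed.
#' @param depth sequencing depth of the live ground-truth count table.
#' @return list with `liveOtu` (an [OtuTable-class] of live-truth counts),
#'   `lnOtu` (matrix of the latent log abundances, samples x OTUs),
#'   `phenotypes` (data.frame with the 13 phenotype variables plus animal,
#'   family, tank, day), and `truthValues` (per-OTU true breeding values and
#'   tank effects, for recovery tests).
#' @export
simulateOtuPhenotypes <- function(geno, familyMap, truth, design,
                                  seed = 1L, depth = 22000L) {
    stopifnot(inherits(truth, "SimTruth"))
    ph <- familyMap[familyMap$phenotyped, ]
    n <- nrow(ph)
    withr::with_seed(seed, {
        dos <- dosages(geno)[ph$id, , drop = FALSE]
        pbar <- colMeans(dos) / 2
        Z <- sweep(dos, 2, 2 * pbar)
        tanks <- factor(ph$tank)
        days <- ph$day
        dayLevels <- sort(unique(days))
        dayShift <- truth$dayEffects
        if (is.null(dayShift))
            dayShift <- setNames(0.15 * (seq_along(dayLevels) - 1), dayLevels)
        otus <- names(truth$baseline)
        lnOtu <- matrix(0, n, length(otus), dimnames = list(ph$id, otus))
        aMat <- matrix(0, n, length(otus), dimnames = list(ph$id, otus))
        tMat <- matrix(0, n, length(otus), dimnames = list(ph$id, otus))
        for (k in seq_along(otus)) {
            h2k <- truth$h2[k]; c2k <- truth$c2[k]
            a <- .breedingValues(Z, h2k)
            tEff <- rnorm(nlevels(tanks), 0, sqrt(c2k))[as.integer(tanks)]
            e <- rnorm(n, 0, sqrt(1 - h2k - c2k))
            lnOtu[, k] <- log(truth$baseline[k]) +
                dayShift[as.character(days)] + a + tEff + e
            aMat[, k] <- a
            tMat[, k] <- tEff
        }
        # live ground-truth counts by multinomial sampling of the closed
        # composition
        rel <- exp(lnOtu)
        rel <- rel / rowSums(rel)
        cnt <- apply(rel, 1, function(r) rmultinom(1, depth, r))
        dimnames(cnt) <- list(otus, ph$id)

        pp <- truth$phenoParams
        B <- truth$otuEffects
        phen <- data.frame(animal = ph$id, family = ph$family,
                           tank = ph$tank, day = days,
                           stringsAsFactors = FALSE)
        dayIdx <- match(days, dayLevels)
        for (v in .phenoVariables) {
            if (v %in% c("FW", "RG")) next
            eff <- rep(0, n)
            for (o in rownames(B))
                if (B[o, v] != 0) eff <- eff + B[o, v] * lnOtu[, o]
            phen[[v]] <- pp[v, "base"] + pp[v, "dayCoef"] * dayIdx + eff +
                .breedingValues(Z, pp[v, "animalVar"]) +
                rnorm(nlevels(tanks), 0,
                      sqrt(pp[v, "tankVar"]))[as.integer(tanks)] +
                rnorm(n, 0, sqrt(pp[v, "residVar"]))
        }
        phen$FW <- phen$IW + phen$WG
        phen$RG <- 100 * phen$WG / phen$FW
        phen <- phen[, c("animal", "family", "tank", "day", .phenoVariables)]
        list(liveOtu = OtuTable(cnt,
                 sampleData = data.frame(sample = ph$id, family = ph$family,
                                         tank = ph$tank, day = days),
                 arm = "live"),
             lnOtu = lnOtu, phenotypes = phen,
             truthValues = list(breedingValues = aMat, tankEffects = tMat,
                                dayShift = dayShift))
    })
}

#' Simulate paired PMA-treated / untreated count tables
#'
#' Adds the planted dead and contaminant OTUs to the live composition: in
#' the untreated arm each planted OTU carries `fold` times its PMA-arm
#' abundance, with the planted sets scaled so they carry the target read
#' fractions of the untreated arm; both arms are then multinomially sampled
#' to `depth`. A shared per-sample log-normal jitter keeps the realized
#' untreated/PMA ratio centred on the fold factor.
#'
#' @param liveTable an [OtuTable-class] of live-truth counts.
#' @param truth the [simTruth()] carrying planted sets and fold factors.
#' @param depth total reads per sample in each arm (> 0).
#' @param seed integer seed.
#' @return list with `pma` and `untreated` [OtuTable-class] objects sharing
#'   the sample set of `liveTable`.
#' @export
simulatePairedPma <- function(liveTable, truth, depth = 22000L, seed = 1L) {
    stopifnot(inherits(truth, "SimTruth"))
    if (depth <= 0) stop("depth must be positive")
    planted <- c(truth$deadOtus, truth$contamOtus)
    if (length(planted) && any(planted <= 1))
        stop("planted fold factors must exceed 1")
    cnt <- otuCounts(liveTable)
    rel <- sweep(cnt, 2, colSums(cnt), "/")
    fd <- truth$deadReadFraction; fc <- truth$contamReadFraction
    if (length(truth$deadOtus) == 0) fd <- 0
    if (length(truth$contamOtus) == 0) fc <- 0
    liveShare <- 1 - fd - fc
    stopifnot(liveShare > 0)
    # untreated-arm mass per planted OTU (live mass = 1)
    uDead <- if (length(truth$deadOtus))
        rep(fd / liveShare / length(truth$deadOtus),
            length(truth$deadOtus)) else numeric()
    uContam <- if (length(truth$contamOtus))
        rep(fc / liveShare / length(truth$contamOtus),
            length(truth$contamOtus)) else numeric()
    uMass <- c(uDead, uContam)
    names(uMass) <- c(names(truth$deadOtus), names(truth$contamOtus))
    bMass <- uMass / planted[names(uMass)]      # PMA-arm mass
    nSamp <- ncol(cnt)
    withr::with_seed(seed, {
        jitter <- matrix(exp(rnorm(length(uMass) * nSamp, 0, 0.2)),
                         length(uMass), nSamp,
                         dimnames = list(names(uMass), colnames(cnt)))
        untreatedComp <- rbind(rel, jitter * uMass)
        pmaComp <- rbind(rel, jitter * bMass)
        drawArm <- function(comp) {
            comp <- sweep(comp, 2, colSums(comp), "/")
            out <- apply(comp, 2, function(r) rmultinom(1, depth, r))
            rownames(out) <- rownames(comp)
            out
        }
        sd <- sampleInfo(liveTable)
        list(pma = OtuTable(drawArm(pmaComp), sampleData = sd, arm = "pma"),
             untreated = OtuTable(drawArm(untreatedComp), sampleData = sd,
                                  arm = "untreated"))
    })
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [simulatePedigreeGenotypes()],
#' [simulateOtuPhenotypes()], [simulatePairedPma()] and [vanRadenGrm()]
#' (after [qcGenotypes()]).
#'
#' @param design a [studyDesign()].
#' @param truth a [simTruth()]; default [simTruth()].
#' @param seed integer seed driving every stage.
#' @param depth per-sample sequencing depth of the paired arms.
#' @return list with `genotypes`, `familyMap`, `liveOtu`, `lnOtu`,
#'   `phenotypes`, `truthValues`, `pma`, `untreated`, `grm`, `truth`,
#'   `design`.
#' @export
simulateStudy <- function(design = studyDesign(), truth = simTruth(),
                          seed = 1L, depth = 22000L) {
    g <- simulatePedigreeGenotypes(design, seed = seed)
    op <- simulateOtuPhenotypes(g$genotypes, g$familyMap, truth, design,
                                seed = seed + 1L, depth = depth)
    arms <- simulatePairedPma(op$liveOtu, truth, depth = depth,
                              seed = seed + 2L)
    ph <- g$familyMap[g$familyMap$phenotyped, ]
    sub <- GenotypeData(dosages(g$genotypes)[ph$id, , drop = FALSE],
                        snpMap(g$genotypes))
    grm <- vanRadenGrm(qcGenotypes(sub))
    c(g, op, arms, list(grm = grm, truth = truth, design = design))
}
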
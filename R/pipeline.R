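# End-to-end pipeline: each stage reads and writes the documented
# tab-delimited formats inside one working directory, appends a run-log
# record, and can be driven either programmatically (runPipeline) or from
# the command line (otuHeritCli). File layout within the directory:
#
#   genotypes.dosage.tsv / genotypes.map.tsv / genotypes.vcf
#   otu.pma.tsv / otu.untreated.tsv / phenotypes.tsv / truth.yaml
#   otu.filtered.tsv, screen.summary.tsv, screen.calls.tsv, screen.qcpass.txt
#   lnotu.tsv, outliers.tsv, grm.square.tsv, heritability.tsv
#   gwas.<OTU>.tsv, assoc.tsv, runlog.tsv

#' Pipeline configuration
#'
#' Validated key-value configuration aggregating the analysis constants:
#' rarefaction depth 10000, dead/contaminant fold thresholds 3 and 6,
#' genotype QC thresholds (MAF 0.01, call rate 0.90, individual
#' missingness 0.10), significance level 0.05, high-abundance threshold
#' 0.01 (1% mean relative abundance), and the seed. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults.
#' @param file optional YAML file of overrides (flags take precedence over
#'   the file, the file over the defaults).
#' @return named list of configuration values.
#' @export
pipelineConfig <- function(..., file = NULL) {
    defaults <- list(depth = 10000L, deadFold = 3, contamFold = 6,
                     mafMin = 0.01, snpCallMin = 0.90, indMissingMax = 0.10,
                     alpha = 0.05, abundanceThreshold = 0.01, seed = 1L)
    cfg <- defaults
    if (!is.null(file)) {
        fromFile <- yaml::read_yaml(file)
        unknown <- setdiff(names(fromFile), names(defaults))
        if (length(unknown))
            stop("unknown configuration key(s): ",
                 paste(unknown, collapse = ", "))
        cfg <- modifyList(cfg, fromFile)
    }
    dots <- list(...)
    unknown <- setdiff(names(dots), names(defaults))
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, dots)
    with(cfg, {
        stopifnot(depth > 0, deadFold > 1, contamFold > 1,
                  mafMin >= 0, mafMin < 0.5,
                  snpCallMin > 0, snpCallMin <= 1,
                  indMissingMax > 0, indMissingMax <= 1,
                  alpha > 0, alpha < 1,
                  abundanceThreshold > 0, abundanceThreshold < 1)
    })
    cfg
}

.logRecord <- function(stage, rowsIn, rowsOut, params, seed,
                       warnings = "") {
    data.frame(stage = stage, rowsIn = rowsIn, rowsOut = rowsOut,
               params = params, seed = seed, warnings = warnings,
               stringsAsFactors = FALSE)
}

.appendLog <- function(dir, rec) {
    path <- file.path(dir, "runlog.tsv")
    write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = !file.exists(path), append = file.exists(path))
    message(sprintf("[%s] in=%s out=%s %s", rec$stage, rec$rowsIn,
                    rec$rowsOut, rec$params))
}

#' Run pipeline stages in a working directory
#'
#' `runPipeline` chains simulate, screen, qc, grm, h2, gwas and assoc; the
#' individual `stage*` functions run one stage against the files already in
#' `dir`. Every stage appends one record to `runlog.tsv` (row counts,
#' parameters, seed), so no exclusion is silent.
#'
#' @param dir working directory (created if needed).
#' @param design a [studyDesign()] (simulate stage).
#' @param truth a [simTruth()] (simulate stage).
#' @param config a [pipelineConfig()].
#' @param stages subset of the stages, in order.
#' @return invisibly, a list with the final per-stage objects.
#' @export
runPipeline <- function(dir, design = studyDesign(), truth = simTruth(),
                        config = pipelineConfig(),
                        stages = c("simulate", "screen", "qc", "grm",
                                   "h2", "gwas", "assoc")) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out <- list()
    for (s in stages)
        out[[s]] <- switch(s,
            simulate = stageSimulate(dir, design, truth, config),
            screen = stageScreen(dir, config),
            qc = stageQc(dir, config),
            grm = stageGrm(dir, config),
            h2 = stageH2(dir, config),
            gwas = stageGwas(dir, config),
            assoc = stageAssoc(dir, config),
            stop("unknown stage: ", s))
    invisible(out)
}

#' @rdname runPipeline
#' @export
stageSimulate <- function(dir, design = studyDesign(), truth = simTruth(),
                          config = pipelineConfig()) {
    sim <- simulateStudy(design, truth, seed = config$seed,
                         depth = round(2.2 * config$depth))
    writeDosage(sim$genotypes, file.path(dir, "genotypes.dosage.tsv"),
                file.path(dir, "genotypes.map.tsv"))
    writeVcfGenotypes(sim$genotypes, file.path(dir, "genotypes.vcf"))
    writeOtuTable(sim$pma, file.path(dir, "otu.pma.tsv"))
    writeOtuTable(sim$untreated, file.path(dir, "otu.untreated.tsv"))
    writePhenotypes(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
    writeTruthSidecar(truth, file.path(dir, "truth.yaml"))
    .appendLog(dir, .logRecord("simulate", design$nPhenotyped,
                               nrow(sim$phenotypes),
                               sprintf("families=%d snps=%d", design$nFamilies,
                                       design$nSnps), config$seed))
    invisible(sim)
}

#' @rdname runPipeline
#' @export
stageScreen <- function(dir, config = pipelineConfig()) {
    pma <- readOtuTable(file.path(dir, "otu.pma.tsv"), arm = "pma")
    unt <- readOtuTable(file.path(dir, "otu.untreated.tsv"),
                        arm = "untreated")
    if (ncol(pma) == 0L || ncol(unt) == 0L)
        stop("screen: input table has zero samples")
    scr <- screenDataset(pma, unt, depth = config$depth,
                         deadFold = config$deadFold,
                         contamFold = config$contamFold, seed = config$seed)
    writeOtuTable(scr@filtered, file.path(dir, "otu.filtered.tsv"))
    .writeTsv(scr@summary, file.path(dir, "screen.summary.tsv"))
    .writeTsv(scr@calls, file.path(dir, "screen.calls.tsv"))
    writeLines(scr@qcPass, file.path(dir, "screen.qcpass.txt"))
    .appendLog(dir, .logRecord("screen", ncol(unt), length(scr@qcPass),
                               sprintf("depth=%d dead>%g contam>%g",
                                       config$depth, config$deadFold,
                                       config$contamFold), config$seed))
    invisible(scr)
}

#' @rdname runPipeline
#' @export
stageQc <- function(dir, config = pipelineConfig()) {
    filt <- readOtuTable(file.path(dir, "otu.filtered.tsv"), arm = "live")
    pheno <- readPhenotypes(file.path(dir, "phenotypes.tsv"))
    comm <- summarizeCommunity(filt, config$abundanceThreshold)
    cnt <- otuCounts(filt)
    high <- comm$highAbundance
    high <- high[apply(cnt[high, , drop = FALSE] > 0, 1, all)]
    if (!length(high)) stop("no high-abundance OTU present in all samples")
    rel <- sweep(cnt[high, , drop = FALSE], 2, colSums(cnt), "/")
    lnOtu <- t(lnTransform(rel))
    pheno <- pheno[match(rownames(lnOtu), pheno$animal), ]
    # FW is excluded: FW = IW + WG holds identically, so keeping all three
    # makes the regression rank deficient
    vars <- setdiff(intersect(.phenoVariables, names(pheno)), "FW")
    X <- cbind(1, as.matrix(pheno[, vars]))
    colnames(X)[1] <- "(Intercept)"
    reps <- lapply(high, function(o) {
        rep <- detectOutliers(setNames(lnOtu[, o], rownames(lnOtu)), X)
        outlierTable(rep, otu = o)
    })
    outliers <- do.call(rbind, reps)
    df <- data.frame(sample = rownames(lnOtu), lnOtu, check.names = FALSE)
    .writeTsv(df, file.path(dir, "lnotu.tsv"))
    .writeTsv(outliers, file.path(dir, "outliers.tsv"))
    .appendLog(dir, .logRecord("qc", ncol(cnt), nrow(lnOtu),
                               sprintf("highAbundance=%d flagged=%d",
                                       length(high), sum(outliers$flagged)),
                               config$seed))
    invisible(list(lnOtu = lnOtu, outliers = outliers, high = high))
}

#' @rdname runPipeline
#' @export
stageGrm <- function(dir, config = pipelineConfig()) {
    geno <- readDosage(file.path(dir, "genotypes.dosage.tsv"),
                       file.path(dir, "genotypes.map.tsv"))
    qcd <- qcGenotypes(geno, config$mafMin, config$snpCallMin,
                       config$indMissingMax)
    grm <- vanRadenGrm(qcd)
    writeGrmSquare(grm, file.path(dir, "grm.square.tsv"))
    .appendLog(dir, .logRecord("grm", ncol(dosages(geno)),
                               nSnpsUsed(grm),
                               sprintf("maf>=%g call>%g", config$mafMin,
                                       config$snpCallMin), config$seed))
    invisible(grm)
}

.loadLnOtu <- function(dir) {
    df <- .readTsv(file.path(dir, "lnotu.tsv"), "sample")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$sample
    m
}

.dropFlagged <- function(y, outliers, otu) {
    bad <- outliers$sample[outliers$otu == otu & outliers$flagged]
    y[!names(y) %in% bad]
}

#' @rdname runPipeline
#' @export
stageH2 <- function(dir, config = pipelineConfig()) {
    lnOtu <- .loadLnOtu(dir)
    pheno <- readPhenotypes(file.path(dir, "phenotypes.tsv"))
    grm <- readGrmSquare(file.path(dir, "grm.square.tsv"))
    outliers <- .readTsv(file.path(dir, "outliers.tsv"))
    pheno <- pheno[match(rownames(lnOtu), pheno$animal), ]
    rows <- lapply(colnames(lnOtu), function(o) {
        y <- .dropFlagged(setNames(lnOtu[, o], rownames(lnOtu)),
                          outliers, o)
        keep <- match(names(y), pheno$animal)
        heritabilityTable(matrix(y, dimnames = list(NULL, o)), grm,
                          animal = pheno$animal[keep],
                          tank = pheno$tank[keep], day = pheno$day[keep])
    })
    tab <- do.call(rbind, rows)
    .writeTsv(tab, file.path(dir, "heritability.tsv"))
    .appendLog(dir, .logRecord("h2", nrow(lnOtu), nrow(tab),
                               "animal+tank REML", config$seed))
    invisible(tab)
}

#' @rdname runPipeline
#' @param otus OTUs to scan (default: all columns of `lnotu.tsv`).
#' @export
stageGwas <- function(dir, config = pipelineConfig(), otus = NULL) {
    lnOtu <- .loadLnOtu(dir)
    geno <- readDosage(file.path(dir, "genotypes.dosage.tsv"),
                       file.path(dir, "genotypes.map.tsv"))
    qcd <- qcGenotypes(geno, config$mafMin, config$snpCallMin,
                       config$indMissingMax)
    outliers <- .readTsv(file.path(dir, "outliers.tsv"))
    if (is.null(otus)) otus <- colnames(lnOtu)
    thr <- bonferroniThreshold(config$alpha, ncol(dosages(qcd)))
    res <- list()
    for (o in otus) {
        y <- .dropFlagged(setNames(lnOtu[, o], rownames(lnOtu)),
                          outliers, o)
        scan <- mlmLocoScan(y, qcd)
        tab <- scan@results
        tab$significant <- tab$p < thr$p
        .writeTsv(tab, file.path(dir, paste0("gwas.", o, ".tsv")))
        res[[o]] <- scan
    }
    .appendLog(dir, .logRecord("gwas", ncol(dosages(qcd)),
                               length(otus) * ncol(dosages(qcd)),
                               sprintf("bonferroni p<%.3g (-log10 %.2f)",
                                       thr$p, thr$neglog10), config$seed))
    invisible(res)
}

#' @rdname runPipeline
#' @param phenotypes dependent variables for the association stage.
#' @export
stageAssoc <- function(dir, config = pipelineConfig(),
                       phenotypes = c("WG", "AAC", "IFER_AMC", "IFER_AMN")) {
    lnOtu <- .loadLnOtu(dir)
    pheno <- readPhenotypes(file.path(dir, "phenotypes.tsv"))
    grm <- readGrmSquare(file.path(dir, "grm.square.tsv"))
    pheno <- pheno[match(rownames(lnOtu), pheno$animal), ]
    fits <- lapply(phenotypes, function(v)
        fitAssociation(pheno[[v]], lnOtu, day = pheno$day,
                       tank = pheno$tank, animal = pheno$animal,
                       grm = grm, responseName = v))
    report <- buildAssocReport(fits)
    .writeTsv(report, file.path(dir, "assoc.tsv"))
    .appendLog(dir, .logRecord("assoc", nrow(lnOtu), nrow(report),
                               paste(phenotypes, collapse = ","),
                               config$seed))
    invisible(report)
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`simulate`, `screen`, `qc`, `grm`,
#' `h2`, `gwas`, `assoc`, `all`) with flags `--out DIR` (required),
#' `--config FILE`, `--seed N`, `--depth N`, `--families N`, `--snps N`,
#' `--chromosomes N`. Flag values take precedence over the configuration
#' file, which takes precedence over the defaults. A thin Rscript wrapper
#' is installed under `system.file("scripts", "otuherit", package =
#' "otuHerit")`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return 0 invisibly on success; errors propagate (the script wrapper
#'   maps them to a non-zero exit status).
#' @export
otuHeritCli <- function(args) {
    usage <- paste("usage: otuherit <simulate|screen|qc|grm|h2|gwas|assoc|all>",
                   "--out DIR [--config FILE] [--seed N] [--depth N]",
                   "[--families N] [--snps N] [--chromosomes N]")
    if (length(args) < 1L) stop(usage, call. = FALSE)
    sub <- args[1L]
    if (!sub %in% c("simulate", "screen", "qc", "grm", "h2", "gwas",
                    "assoc", "all"))
        stop("unknown subcommand '", sub, "'\n", usage, call. = FALSE)
    flags <- list()
    rest <- args[-1L]
    i <- 1L
    while (i <= length(rest)) {
        key <- rest[i]
        if (!startsWith(key, "--") || i == length(rest))
            stop("malformed flag '", key, "'\n", usage, call. = FALSE)
        flags[[substring(key, 3L)]] <- rest[i + 1L]
        i <- i + 2L
    }
    if (is.null(flags$out)) stop("--out DIR is required\n", usage,
                                 call. = FALSE)
    cfgArgs <- list()
    if (!is.null(flags$config)) {
        if (!file.exists(flags$config))
            stop("configuration file not found: ", flags$config,
                 call. = FALSE)
        cfgArgs$file <- flags$config
    }
    if (!is.null(flags$seed)) cfgArgs$seed <- as.integer(flags$seed)
    if (!is.null(flags$depth)) cfgArgs$depth <- as.integer(flags$depth)
    config <- do.call(pipelineConfig, cfgArgs)
    design <- studyDesign(
        nFamilies = as.integer(flags$families %||% 23L),
        nSnps = as.integer(flags$snps %||% 2000L),
        nChromosomes = as.integer(flags$chromosomes %||% 29L))
    stages <- if (sub == "all")
        c("simulate", "screen", "qc", "grm", "h2", "gwas", "assoc")
    else sub
    runPipeline(flags$out, design = design, config = config,
                stages = stages)
    invisible(0L)
}
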
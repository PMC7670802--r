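Package: otuHerit
Title: Heritability and Host-Phenotype Association of Viability-Screened
    Gut Microbiome Profiles
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of host genetic and environmental effects on
    gut microbial community composition in family-structured aquaculture
    designs. Provides propidium-monoazide (PMA) based live/dead/contaminant
    screening of paired OTU count tables with rarefaction, leverage-based
    outlier removal of log-abundances, VanRaden method-1 genomic relationship
    matrices from SNP dosages, average-information REML for the animal model
    with a rearing-tank effect (heritability, tank fraction, likelihood-ratio
    tests), mixed-linear-model genome-wide association with leave-one-
    chromosome-out relationship matrices, and mixed-model regression of growth
    and feed-efficiency phenotypes on log OTU abundances. A synthetic-data
    generator reproduces the statistical structure of a full-sib family / dual
    rearing-tank design so every stage can be exercised and validated against
    planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    vcfR,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
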
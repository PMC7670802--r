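---
title: "Models and methods in otuHerit"
author: "otuHerit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in otuHerit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otuHerit)
```

# Overview

`otuHerit` analyses how much of the variation in gut microbial community
composition among individually phenotyped fish is attributable to host
genetics and to the shared rearing environment, and whether the abundances
of the dominant gut microbes predict host growth and feed-efficiency
phenotypes. The pipeline was designed around a family-based aquaculture
experiment: full-sib families split over two rearing tanks each, a handful
of fish sampled per tank across several sampling days, paired
PMA-treated/untreated 16S libraries per fish, a dense SNP panel on all
animals, and a battery of growth and stable-isotope metabolism phenotypes.

Every stage is exercisable on synthetic data with planted ground truth, so
the statistical machinery can be validated end to end without any
sequencing data.

# Viability screening of paired PMA libraries

Propidium monoazide (PMA) blocks amplification of free DNA and DNA in
membrane-compromised cells, so comparing an untreated library with its
PMA-treated sibling separates signal from live cells, dead cells, and
DNA that never was in an intact cell in the gut (contamination).

Both arms are first rarefied to a common depth (default 10,000 reads,
subsampling without replacement; samples below depth fail QC in either
arm). For each OTU in each fish the untreated-to-PMA abundance ratio is

$$r = \frac{(c_u + 1)/d_u}{(c_p + 1)/d_p},$$

with a pseudocount of one on both counts. An OTU is called a
*contaminant* when $r > 6$, *dead* when $3 < r \le 6$, *live* otherwise,
and *undetected* when absent from both arms. Two points were genuinely
open and are resolved as follows:

* the two published rules overlap (any more-than-6-fold excess is also a
  more-than-3-fold reduction), so the contaminant call takes precedence —
  the only reading under which both rules bite;
* the ratio is computed within rarefied samples on relative abundances
  with a pseudocount, which avoids division by zero for OTUs seen in only
  one arm and removes depth confounding. The source protocol does not
  state its basis.

Classification and removal are per fish; dataset-level OTU classes (used
for summary counts) come from the pooled counts over all passing samples.
Dead/contaminant read *fractions* are read-weighted over the untreated
arm. The screened table that feeds downstream analysis is the untreated
arm with dead and contaminant OTUs zeroed per sample.

# Outlier screening of log abundances

Relative abundances of the dominant OTUs (present in every sample) are
natural-log transformed. Each `Ln(OTU)` is regressed on the host
phenotypes by ordinary least squares and the hat-matrix diagonal is used
as the influence statistic, with the classical cutoff $3p/n$. Cook's
distance and DFFITS are available behind `statistic=` but are not the
default, because $3p/n$ is the leverage cutoff. Flagged samples are
removed from that OTU's downstream analyses only, not globally — removing
a fish from all analyses because it is influential for one OTU would
discard far more observations than the influence evidence supports.

One rank-deficiency is structural: weight gain is final minus initial
weight, so the three weight variables are linearly dependent and the
final weight is dropped from the outlier design in the pipeline stage.

# Genomic relationships

After genotype QC (drop individuals with ≥ 10% missing genotypes, then
SNPs with minor allele frequency < 1% or call rate ≤ 90%), the
relationship matrix follows VanRaden's first method,

$$\mathbf{G} = \frac{\mathbf{Z}\mathbf{Z}'}{2\sum_j p_j (1 - p_j)},$$

with $\mathbf{Z}$ the dosage matrix centred at twice the observed allele
frequencies and missing dosages mean-imputed (zero after centring).
Frequencies are estimated from the post-QC sample — standard practice when
base-population frequencies are unavailable. A $10^{-6}$ ridge is added to
the diagonal before any mixed-model inversion, purely for numerical
positive-definiteness.

The matrix can be built on a larger genotyped population than the
phenotyped one; marginalizing unphenotyped relatives in a multivariate
normal is exactly the principal submatrix, so the animal-model code simply
subsets the rows it needs.

# The animal model and REML

For each OTU trait $\mathbf{y} = \text{Ln(OTU)}$:

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{Z}_a \mathbf{a} +
\mathbf{Z}_t \mathbf{t} + \mathbf{e}, \qquad
\mathbf{a} \sim N(0, \mathbf{G}\sigma_a^2),\;
\mathbf{t} \sim N(0, \mathbf{I}\sigma_t^2),\;
\mathbf{e} \sim N(0, \mathbf{I}\sigma_e^2),$$

with fixed effects an intercept and sampling day as a factor. Variance
components are estimated by average-information REML: Fisher scoring on
the AI matrix with step halving, falling back to a multiplicative
EM-style update whenever an AI step would decrease the restricted
likelihood. Components driven negative are restricted to the zero
boundary and flagged; each boundary component is restarted once from 1%
of the phenotypic variance to guard against spurious boundary solutions.
Convergence requires a relative change in restricted log-likelihood below
$10^{-8}$ and parameter changes below $10^{-6}$ (at most 200 iterations);
starting values are equal thirds of the phenotypic variance. Standard
errors come from the inverse AI matrix and ratios
($h^2 = \sigma_a^2/(\sigma_a^2+\sigma_t^2+\sigma_e^2)$,
$c^2 = \sigma_t^2/\cdot$) by the first-order delta method, with boundary
components contributing no sampling variance.

The genetic effect is tested by
$LR = 2(\log L_{H_1} - \log L_{H_0})$ against $\chi^2_1$. The boundary
null makes the nominal reference conservative-liberal in a known way; the
$\tfrac12\chi^2_0 : \tfrac12\chi^2_1$ mixture is available via
`mixture = TRUE`, but the plain $\chi^2_1$ convention is the default
because it is what variance-component reports in this literature use.

The restricted likelihood is reported without additive constants; only
differences on the same data and fixed-effect design are meaningful,
which is all the LR test needs.

# Leave-one-chromosome-out association

Per SNP the model is $Y_i = a + b x_i + g^-_i + \varepsilon_i$ with
$g^- \sim N(0, \mathbf{G}_{-c}\,\sigma^2_g)$, where $\mathbf{G}_{-c}$
excludes the candidate SNP's chromosome so the marker's own signal does
not sit in the polygenic covariance it is tested against. For each
chromosome the polygenic and residual variances are re-estimated with a
one-dimensional profiled REML on the eigendecomposition of
$\mathbf{G}_{-c}$; every SNP on that chromosome is then tested by a
generalized-least-squares Wald statistic with the variance components
held at that null fit (the familiar two-step of large-scale mixed-model
GWAS tools). With the components held fixed the Gaussian likelihood-ratio
statistic for $b$ equals the Wald statistic identically, so only the Wald
form is exposed. The eigendecomposition is reused across all SNPs of a
chromosome, making the per-SNP cost linear.

Genome-wide significance uses Bonferroni control ($\alpha/m$ and its
$-\log_{10}$); the median-based genomic inflation factor is provided for
calibration diagnostics.

# Phenotype-on-microbiome regression

Each host phenotype is regressed jointly on sampling day (as a linear
covariate — the reported layout carries a single day slope) and the log
abundances of the six dominant OTUs, with random genomic-animal and tank
effects, reusing the REML machinery. Each fixed regressor is reported
with a Wald $F$ (1 numerator df, $n - \mathrm{rank}(\mathbf{X})$
denominator df), which ignores the uncertainty of the estimated variance
components; conditional Wald tests with adjusted denominators would
differ slightly in small samples. Collinear regressor sets are an error
naming the offending columns, never a silent drop — tank and family are
heavily confounded in split-family designs and silent aliasing would be
misleading. A random-effects fit absorbs that confounding instead.

# The synthetic-data generator

The generator is first-class, tested code. It emulates:

* **Design** — 23 full-sib families × 2 tanks × 5 sampled fish (230
  phenotyped animals) across 4 sampling days by default, with optional
  extra genotyped-but-unphenotyped sibs; all counts configurable.
  One sire is mated to two dams so sires number one fewer than dams.
* **Genotypes** — parents in Hardy–Weinberg proportions at frequencies
  uniform on a MAF range, offspring by Mendelian transmission, SNPs
  spread evenly over the chromosomes. Breeding values are built from
  i.i.d. normal effects over all SNPs (infinitesimal model) scaled to the
  target variance, so the same generator serves heritability recovery and
  GWAS power studies.
* **Log OTU abundances** — per OTU,
  $\ln A = \log(\text{baseline}) + \text{day shift} + a + t + e$ with
  unit total variance and planted fractions $h^2$ (genetic) and $c^2$
  (tank). The abundance distribution is assumed log-normal; the source
  literature does not state one.
* **Counts** — multinomial sampling of the closed composition at fixed
  depth (default 22,000 reads, matching typical per-sample yields, later
  rarefied to 10,000), which is exactly the regime the rarefied-count
  analysis assumes.
* **Paired arms** — planted dead OTUs carry 9.1% of untreated reads by
  default (the scale reported for salmon gut communities) at a fold
  factor of 5, planted contaminants 1% at fold 12. Fold factors sit
  mid-window so classification is stable under counting noise; real
  contaminant loads can be orders of magnitude smaller than 1%, but at a
  rarefaction depth of $10^4$ such loads are unobservable, so the default
  is chosen to be detectable. A shared per-sample log-normal jitter
  (sd 0.2) varies planted abundances without disturbing the fold ratio.
* **Phenotypes** — the 13 growth/metabolism variables as linear functions
  of day and the dominant log OTU abundances plus genetic, tank and
  residual terms; default regression coefficients plant the reported
  significant associations (e.g. a weight-gain slope of −1.352 per log
  unit of the *Sphingomonas*-like OTU3), and weight variables are kept
  internally consistent (final = initial + gain).

What the generator does **not** emulate: sequence-level errors, taxonomy,
chimeras, reagent contamination profiles, overdispersion beyond
multinomial counting, or selection on parental breeding values. Passing
recovery tests therefore demonstrates the statistical machinery is
correct under the stated model, not that real amplicon data meet that
model.

# Numerical choices and problem sizes

Dense $O(n^3)$ linear algebra per REML iteration is deliberate: the
target populations are hundreds of phenotyped animals, where a full
$n \times n$ solve takes milliseconds. The validation suites use 50-animal
instances against a grid-search likelihood oracle (agreement to
$10^{-3}$), balanced tank designs against closed-form ANOVA REML
estimators ($10^{-6}$), 500-animal/1,000-SNP replicates for heritability
recovery (mean within ±0.1 of the planted 0.4), 400-animal/2,000-SNP
scans for GWAS calibration and power, and 200 null replicates for the
association model's type-I error. The end-to-end pipeline demonstration
runs 100 animals and 500 SNPs and is byte-reproducible under a fixed
seed.

# Known limitations

* Heritability estimates from ~200 animals in a split-family tank design
  carry large standard errors; the delta-method SEs make that visible
  rather than fixing it. Tank and family are structurally confounded.
* The Wald $F$ denominator df are not Kenward–Roger/conditional adjusted.
* Per-sample viability classification is noisy for OTUs near the fold
  thresholds at low counts; the pseudocount biases ratios of rare OTUs
  toward 1, which is conservative for contaminant calls.
* The LR test for a variance component uses the conventional
  $\chi^2_1$ reference by default (see above).
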
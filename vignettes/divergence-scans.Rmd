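---
title: "Methods: additive-dominance and selective-sweep scans for two-population divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: additive-dominance and selective-sweep scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdivscan)
```

## The problem

When two populations of the same species — here the motivating case is two
commercial pig breeds kept under divergent selection for reproduction
traits — are compared genome-wide, the standard selection-signature
statistics (F\_ST, nucleotide-diversity ratios) respond to allele-frequency
differences. Allele-frequency differences are the footprint of *additive*
selection. A locus can, however, diverge without any frequency difference:
one population may be driven toward heterozygosity while the other segregates
the two homozygotes, leaving both with the same allele frequency. Such
*dominance-signature* loci are invisible to frequency-based statistics but
carry real between-population structure. This package implements two
complementary scans so that both signals can be measured, compared at the
set level, and validated against phenotype records.

## Scan 1: surrogate-phenotype mixed model with additive-dominance decomposition

No individual phenotype is needed. The first principal component of the
additive genomic relationship matrix (GRM) separates the two populations and
is used as a *surrogate phenotype* `y` (the EigenGWAS idea). The model is

$$ y = Xb + \sum_i Z_i u_i + e, \qquad
   u_i \sim N(0, K_i \sigma_i^2), \quad e \sim N(0, I\sigma_e^2), $$

with two genetic random effects: an additive kinship $K_a$ (VanRaden
method 1, $Z_aZ_a'/2\sum_j p_jq_j$ with $Z_a$ the dosage matrix centered at
$2p_j$) and a dominance kinship $K_d$ built from the heterozygosity
indicator centered at its Hardy-Weinberg expectation $2p_jq_j$ and scaled by
$\sum_j 2p_jq_j(1-2p_jq_j)$, its HWE variance. `reml_fit()` estimates
$(\sigma_a^2, \sigma_d^2, \sigma_e^2)$ by average-information REML with an
active set at the zero boundary and an EM fallback (see *Numerical choices*).
The percent shares $100\,\sigma_a^2/(\sigma_a^2+\sigma_d^2)$ and its
complement summarize how much of the captured genetic variance is additive
versus dominant.

Per SNP, `addo_scan()` compares three nested least-squares models of `y`:

* **M0** — intercept only;
* **MA** — intercept plus the centered additive dosage $x = g - 2p$;
* **MAD** — MA plus the dominance covariate $d_\perp$, the heterozygosity
  coding residualized on $x$ (computed through orthogonal factorizations, so
  $d_\perp'x = 0$ to machine precision).

`p_add` is the F-test of MA against M0 on $(1, n-2)$ degrees of freedom and
`p_dom` the F-test of MAD against MA on $(1, n-3)$; the orthogonalization
makes the dominance test a test of *pure* dominance deviation, uncorrelated
with the additive effect at that SNP. Significance uses the inclusive
Bonferroni rule $p \le \alpha/m$ over the m tested SNPs.

Two regression modes are provided. `mode = "gls"` whitens `y` and all
design columns by the inverse Cholesky factor of
$\hat V = \hat\sigma_a^2K_a + \hat\sigma_d^2K_d + \hat\sigma_e^2I$ (the
usual two-stage LMM-scan approximation: variance components are estimated
once, not refitted per SNP). `mode = "ols"` regresses on the raw columns.
Because the surrogate phenotype is itself an eigenvector of $K_a$ computed
from the same SNPs being tested, the GLS fit partially absorbs the very
signal the scan is looking for — a self-contamination property of
single-panel surrogate-phenotype scans that this package deliberately
exposes rather than hides. The package's own reproducible analyses
therefore use `ols` for planted-signal detection, and the test suite pins
the identity `gls(σ²=0) ≡ ols`. No leave-one-chromosome-out correction is
applied; with it, the surrogate phenotype and the kinship would no longer
be functions of the same marker panel, which is the situation the method is
defined for.

## Scan 2: joint z(F\_ST) / diversity-ratio sweep scan

For every site, `sweep_scan()` computes the Weir-Cockerham (1984) two-deme
estimator $\hat\theta = a/(a+b+c)$ from per-population diploid counts,
allele frequencies and observed heterozygote fractions. Estimates are kept
as-is: negative $\hat\theta$ values enter the genome-wide mean and standard
deviation used for the z-normalization, and sites where $a+b+c=0$ are
missing. Per-population nucleotide diversity at a site is the average
pairwise allele difference $\pi = 2c(N-c)/(N(N-1))$, and the contrast is
$\log_2(\pi_1/\pi_2)$, undefined (and excluded from the ratio tail) when
either diversity is zero — a pseudo-count would manufacture extreme ratios
from monomorphic chip sites. A locus is *selected* when its z(F\_ST)
strictly exceeds the genome-wide 95% quantile **and** its absolute log2
ratio strictly exceeds the 95% quantile of the absolute ratios (both
quantiles by linear interpolation, R type 7; the tail mass is the
`tail_fraction` parameter, default 0.05). Selected loci are assigned to the
lower-diversity population — the population the sweep presumably happened
in. Which population is the ratio's numerator is an explicit argument,
defaulting to the alphabetically-first label; per-site rather than windowed
statistics are used throughout.

## Comparison, annotation, validation

`venn_counts()` performs exact three-way set algebra over additive,
dominance and sweep hit sets; the headline quantities are the LMM+ADDO
union and the subset of it the sweep scan misses. The convention for the
"additive-and-sweep" count excludes the triple overlap, which is reported
separately. `annotate_snps()` reduces consequence annotation to interval
logic against a user-supplied gene model (GFF3/BED, via `rtracklayer`): a
SNP is `within` a gene, `upstream`/`downstream` of the nearest gene within
a 5 kb flank (the conventional neighborhood default; configurable), or
`intergenic`. Each SNP annotates to at most one gene (nearest, ties broken
alphabetically) so gene-level set counts are stable. `anova_fit()` validates
candidate genotypes against litter traits (total number born, number born
alive) with a fixed-effects multifactor ANOVA using Type II sums of squares
— order-invariant for main-effects models — and `group_letters()` renders
all pairwise Welch t-tests as a compact letter display via the
insertion-absorption algorithm. Welch rather than Tukey HSD because
genotype classes at a segregating locus are strongly unbalanced; repeated
litters per sow are treated as independent records, so sow-level
pseudo-replication is a known caveat of this validation design.

## The synthetic-data generator

`sim_config()` + `simulate_genotypes()` emulate the statistical structure
the scans consume, not real pig chromosomes. Background allele frequencies
follow the Balding-Nichols model: ancestral $p \sim U(0.05, 0.95)$, each
population drawing $p_i \sim \mathrm{Beta}(p\frac{1-F}{F},
(1-p)\frac{1-F}{F})$, so the expected per-site F\_ST equals the divergence
parameter `fst_param`. Genotypes are binomial (HWE within population).
Three kinds of loci can be planted: additive-divergent
(frequencies set directly, default contrast 0.05 vs 0.95),
dominance-signature (both populations at allele frequency 0.5; heterozygote
fraction 1 in one population, 0 in the other, remaining mass split evenly
between homozygotes), and sweep loci (0.01 vs 0.5: near-fixation erodes
diversity on one side while creating a frequency contrast). Phenotypes are
litter records: latent mean `intercept + a(g-1) + d·[g=1] + parity effect`,
total born = rounded truncated normal (floor 0, default intercept 12,
residual SD 3 — a realistic litter-size scale for commercial pigs), number
born alive = total minus a binomial loss (default rate 0.08), with 200 sows
contributing 2-5 litters each, mirroring the multi-litter sow structure of
real validation panels at reduced scale.

The default study conditions are 300+300 samples by 2000 SNPs at F = 0.05
with 2% missingness — small enough that the full pipeline, the test suite
and the reproduction script run in seconds at desk scale, large enough that
the planted signals are unambiguous. What the generator does **not**
emulate: linkage disequilibrium (all loci independent), recombination maps,
genotyping-platform ascertainment, and family structure. Passing tests
therefore demonstrate that each statistic measures what it claims on data
satisfying its own assumptions; they do not demonstrate robustness to LD
pruning choices or cryptic relatedness in real chip data.

## Numerical choices

* **REML.** Average-information updates with step-halving; components are
  floored at $10^{-8}\,\mathrm{var}(y)$, and a floored component with a
  negative gradient is constrained out of the AI system (active set) —
  joint Newton steps through the boundary are not ascent directions. When
  the AI step is still not accepted, a monotone EM-REML step is taken.
  Convergence: successive restricted log-likelihoods within 1e-6, at most
  200 iterations (error carrying the last iterate beyond that). If
  $(K_a, K_d, I)$ are numerically linearly dependent (Gram-matrix
  reciprocal condition below 1e-10) the decomposition is unidentifiable and
  the fit returns flagged as degenerate instead of arbitrary numbers.
* **Scan algebra.** Per-SNP F-tests come from residual-sum-of-squares
  differences of projections computed column-wise (equivalently, QR of each
  tiny design); RSS differences are clamped at 0 against roundoff, and a
  dominance column collinear with its additive column (squared norm below
  1e-10 of its pre-orthogonalization norm) yields a missing `p_dom` rather
  than an unstable F.
* **PCA sign.** Eigenvector signs are arbitrary; PC1 is oriented so the
  alphabetically-first population has negative mean score, and the
  surrogate phenotype is standardized to mean 0, variance 1, making
  variance-component shares scale-free.
* **Boundary conventions.** Call-rate and MAF filters implement strict
  "below threshold is removed" rules; significance thresholds are
  inclusive ($p \le \alpha$); sweep tails are strict ($>$ quantile).
  Coordinates are 1-based inclusive at every I/O surface; interval
  arithmetic happens inside `GenomicRanges`.

## Open design points, resolved

* The QC order (merge, then sample call-rate filter, then imputation, then
  MAF filter) is fixed; MAF is computed pooled across populations on the
  merged data. Haplotype-based imputation is out of scope: the default
  imputer draws missing genotypes from HWE at the population-specific
  allele frequency, preserving exactly the quantities (per-population
  frequencies and heterozygosities) every downstream statistic consumes.
* Both `ols` and `gls` scan modes are kept because a surrogate-phenotype
  regression can be run either way and the choice is consequential (see
  the self-contamination note above); the default is `gls`, the
  deterministic analyses in this package use `ols`.
* The constrained-least-squares dominance decomposition is implemented as
  orthogonalization of the dominance coding on the additive coding — the
  parameterization under which the dominance test is exactly the nested
  F-test of the combined model against the additive model.
* Sweep loci are reported per site; merging into regions is intentionally
  left out (windowing policy is a study-level choice, not a property of the
  statistic).

## Known limitations

* The surrogate phenotype is computed from the same SNPs that are tested;
  significant loci contribute to their own phenotype. This inflates
  genome-wide signal relative to an independent phenotype and is inherent
  to the design.
* Dominance-GRM scaling assumes HWE within the pooled sample; strong
  inbreeding would bias the dominance variance share.
* The fixed-effects phenotype validation ignores repeated measures per sow.
* Gene annotation is interval overlap only; regulatory-region and
  consequence-type annotation require external resources deliberately out
  of scope.

## Reproducing the analysis

`scripts/acceptance.R --seed N --out results.json` regenerates the default
study conditions from scratch, runs QC, both scans, the set comparison and
the phenotype validation, and writes every headline quantity it computed as
JSON. The worked example in the README shows the same pipeline run
interactively.
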
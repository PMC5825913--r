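---
title: "From multi-environment trials to GWAS-informed genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multi-environment trials to GWAS-informed genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`supergs` implements the analysis chain used in inbred crop diversity
panels phenotyped across several drought-prone field sites and genotyped by
whole-genome resequencing: spatially adjusted genotype means, population
structure and linkage disequilibrium, a mixed-model association scan with
pseudo-QTN kinship, and genomic prediction whose marker set is informed by
the scan's p-values. This vignette explains the models, the defaults, and
the choices made where the design was genuinely open. The numbered scripts
under `analysis/` run the whole chain on a simulated panel; every empirical
statement below is produced by those scripts or by the test suite.

## Two-stage phenotype analysis

Field plots are laid out on a row x column grid within each site, and
visual scores, emergence or yield all carry spatial trends. Stage 1 fits,
per site and trait,

$$y = X_g\beta_g + Z_r u_r + Z_c u_c + e,$$

with genotype fixed and independent Gaussian random row and column
intercepts (`fit_site_lmm()`, REML via lme4). The genotype BLUEs from this
model feed stage 2. We deliberately use independent row/column intercepts
rather than an AR1 x AR1 residual: nothing in the target designs
identifies an autocorrelation parameter at 3 replicates per site, and the
independent-intercept model already removes the dominant gradients (the
test suite verifies that its BLUEs beat raw means by mean squared error
under a simulated gradient).

Stage 2 (`fit_multienv_lmm()`) is fit twice, because one parameterisation
cannot serve both purposes:

* `genotype_fixed` - genotype fixed, environment (and, when cells are
  replicated, genotype x environment) random: combined BLUEs for GWAS and
  prediction, plus the Wald chi-square test of the genotypic effect on the
  contrast block (degrees of freedom = genotypes - 1).
* `genotype_random` - everything random: REML variance components
  $(\sigma^2_g, \sigma^2_{ge}, \sigma^2_e)$ for broad-sense heritability
  on the entry-mean basis,
  $$h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/t + \sigma^2_e/(rt)},$$
  with $t$ environments and $r$ the harmonic-mean replication (the
  balanced-design formula's standard plug-in under imbalance). Separating
  $\sigma^2_{ge}$ from $\sigma^2_e$ requires replication within cells, so
  this mode refuses one-record-per-cell data rather than silently
  confounding the two.

Variance components sit on a boundary under the null, so the
likelihood-ratio test for a random term uses the
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture. Both tests are checked by
simulation: 1,000 null data sets give empirical size within [0.03, 0.07]
at $\alpha = 0.05$. The Wald statistic is referred to $\chi^2$, which is
mildly liberal when the residual degrees of freedom are small; the
calibration suite therefore uses designs with resid. df $\gtrsim 10\times$
the contrast df, the regime in which the reference distribution is honest.

```{r pheno}
library(supergs)
pheno <- read_phenotypes("results/data/phenotypes.csv")
site1 <- fit_site_lmm(pheno, "site1", "GY")
ph <- subset(pheno, trait == "GY"); ph$env <- ph$site
vc <- fit_multienv_lmm(ph, mode = "genotype_random")
broad_sense_h2(vc)
```

## Kinship, ancestry, and linkage disequilibrium

`vanraden_kinship()` computes $G = WW^\top / 2\sum_j p_j(1-p_j)$ with
dosage columns centred at $2p_j$ and $p_j$ estimated from the sample
itself (the frequency source is unstated in most applications; the sample
estimate is the standard choice). On a fully inbred panel the mean
diagonal is close to 2 rather than 1 - a property of the centring, which
the tests assert as documented behaviour, not as biology.
`compress_kinship()` clusters genotypes by average linkage on
$\max(G) - G$ and averages within/between blocks; the scan picks its
compression level by null-model REML likelihood (`choose_compression()`).

Ancestry is estimated by maximum likelihood in the K-population admixture
model, $g_{ij} \sim \mathrm{Bin}(2, \sum_k q_{ik}p_{jk})$, with
multiplicative EM updates (`admixture_em()`). EM crawls near the simplex
boundary, so each fit starts from k-means clusters on the leading
principal components (plus random restarts) - the informed start converges
in a few hundred iterations where cold EM needs thousands. Frequencies are
clamped to $[10^{-6}, 1-10^{-6}]$ to keep the likelihood finite. `choose_k_cv()`
selects K by masking a random fold of genotype *entries* and scoring the
masked entries by binomial deviance, the model-selection device of the
ADMIXTURE software. Because the likelihood treats loci as independent, the
analysis scripts run it on an LD-thinned marker subset, as practitioners
do; on linked markers the Q estimates shrink away from the boundary (the
effect is visible in `analysis/03_popgen.R`, where the admixed panel's
mean $|\hat Q - Q|$ is ~0.13 on linked markers versus ~0.01 on effectively
unlinked ones).

LD is the squared Pearson correlation of dosages (`ld_r2()`), restricted
to calls passing the read-depth mask when one is present. The decay curve
fits the drift-equilibrium expectation of $r^2$ at recombination parameter
$C = c\,d$ (with the finite-sample adjustment for $n$ genotypes,
`ld_expected_r2()`) to distance-binned mean $r^2$ by nonlinear least
squares; binning (default 100 bins) stabilises the fit relative to raw
pairs, and both modes are exposed. LD extent is where the fitted curve
crosses $r^2 = 0.2$, interpolated on a fine grid, reported as infinite if
the curve never gets there.

## The association scan

The engine is the one-kinship mixed model
$y = X\beta + u + e$, $u \sim N(0, K\sigma^2_g)$, solved by spectral REML
over the single ratio $\delta = \sigma^2_e/\sigma^2_g$ (`emma_reml()`:
grid scan on $\log\delta$ plus Brent polish; the optimum is tested against
a 1,000-point grid oracle). `mlm_scan()` tests each marker by GLS in the
eigenspace of K. With `p3d = TRUE` (default) the null-model variance
components are reused for every marker; `p3d = FALSE` re-estimates them
per marker, and the two agree to within 0.2 on the $-\log_{10}p$ scale in
the null simulations. With `K = NULL` the scan reduces *exactly* to
ordinary least squares - the identity the tests exploit as an oracle.

The SUPER rescan replaces the genome-wide kinship with one built from a
few pseudo-QTNs. `select_pseudo_qtns()` takes the best marker per
equal-bp genome bin (default 100 bins, capped at 20 markers - GAPIT-like
magnitudes) and adds candidates in increasing-p order while the null REML
likelihood of a kinship built from the selected markers keeps improving.
`super_scan()` then tests each marker with a kinship from the pseudo-QTNs
*not* in LD with it ($r^2 \le 0.1$ by default, so a marker never sits in
its own covariance); if every pseudo-QTN is excluded the marker falls back
to an identity kinship, with a message. Two properties anchor the
implementation: with all markers as pseudo-QTNs and the LD cut at 1 the
rescan equals the plain kinship scan to $10^{-6}$, and on sparse simulated
architectures the causal markers' $-\log_{10}p$ rises relative to the
plain scan. The test statistic is a Wald t on the rotated GLS estimate;
we document this choice and verify calibration by simulation
($\lambda_{GC} \in [0.8, 1.2]$ on structured null panels) rather than
claiming numerical parity with any particular software's F/t mixture.

Multiple testing uses Bonferroni only, `alpha / m`; at the full panel's
144,777 SNPs and $\alpha = 0.05$ that is 3.45e-07 to three significant
figures. Reporting attaches the nearest gene on each side of a significant
SNP (`flanking_genes()`, with containment flagged) and pools significant
SNPs across traits into single-linkage regions (`pleiotropic_regions()`,
default merge distance 1 Mb); a region touched by two or more traits is
flagged pleiotropic.

## Genomic prediction and marker subsetting

`fit_rrblup()` solves $y = \mu + g + e$, $g \sim N(0, G\sigma^2_g)$ by the
same REML engine and back-solves both equivalent forms: genotype values
$\hat g = \sigma^2_g G V^{-1}(y-\hat\mu)$ and marker effects
$\hat\beta = \sigma^2_\beta W^\top V^{-1}(y-\hat\mu)$. Their predictions
agree to numerical precision, and both equal the ridge solution of
Henderson's equations at $\lambda = \sigma^2_e/\sigma^2_\beta$ - the
package's central equivalence oracle.

The Bayesian regressions run in compiled Gibbs samplers over the same
centred marker matrix. BRR puts one common Gaussian variance on all
effects (scaled-inverse-$\chi^2$ hyperpriors, scales set by the usual
heuristic that splits the phenotypic variance, default $R^2 = 0.5$, 5 df).
The Bayesian LASSO uses the double-exponential prior via its
normal-exponential mixture: per-marker $\tau^2_j$, inverse-Gaussian full
conditionals, and a Gamma(0.55, 1e-4) hyperprior on $\lambda^2$ - a
standard weakly informative choice, overridable. Chains default to 10,000
iterations, 2,000 burn-in, thinning 5; fits are reproducible from the
seed. Both samplers expose frozen-variance modes whose posterior means
must match the conjugate ridge closed form within Monte-Carlo error
(batch-means standard errors, 3-SD bands per marker with a simultaneous
bound for the maximum) - that is how the samplers are validated.

`cross_validate()` partitions genotypes into near-equal mutually exclusive
folds (sizes differ by at most 1, seeded permutation), refits on each
training complement and scores Pearson's correlation between predicted and
observed values of the held-out fold; 5 folds x 10 repeats = 50
evaluations. Predictive ability is that raw correlation - not divided by
$\sqrt{h^2}$.

`subset_prediction_experiment()` evaluates a descending ladder of GWAS
p-value thresholds (default all, 0.05, 0.01, 1e-3, 1e-4, 1e-5,
Bonferroni). The single most consequential open choice in this design is
whether marker selection sees the test genotypes. The default scheme,
`within_fold`, reruns the scan on each training set only - unbiased, and
the right choice for method evaluation. `full_data` runs one scan on
everything and reuses its subsets across folds; it mirrors the published
single-scan practice, is optimistically biased because test genotypes
inform the selection, and says so in a message every time it runs. A
threshold that selects no markers in some training set is recorded as an
undefined cell, never an exception. On sparse simulated architectures
(10 QTL among 5,000 SNPs, n = 200, $h^2 = 0.3$) the ability curve rises
from "all markers" to a plateau around p <= 0.05-0.01 and collapses at the
Bonferroni cut - the qualitative signature the acceptance suite asserts
across seeds.

```{r predict}
geno <- read_vcf("results/data/panel.vcf", maf_min = 0.05)
blues <- read.csv("results/blues.csv")
y <- setNames(blues$SW, blues$genotype)[geno$samples]
ex <- subset_prediction_experiment(y, geno, models = "rrblup",
                                   scheme = "within_fold", seed = 1)
ex$results
```

## The synthetic panel

`simulate_genotypes()` emulates the data a resequencing study delivers
after SNP calling: K ancestral populations with Balding-Nichols
divergence (default $F_{ST} = 0.15$; base frequencies uniform on the
requested MAF range), Dirichlet ancestry, and haplotypes built by
first-order Markov copying - the next allele equals the previous one with
probability $e^{-\rho d}$, otherwise it is redrawn from the individual's
admixture-weighted frequency. This gives a closed-form, tunable decay of
expected $r^2$ with distance without coalescent machinery; mean $r^2$ is
monotone non-increasing in distance by construction, and the acceptance
suite checks the fitted LD extent orders correctly across $\rho$ values.
Lines are selfed to full homozygosity by default (`het_rate = 0`),
mirroring inbred chickpea material. `simulate_trait()` draws sparse or
polygenic architectures (`n_qtl` standard-normal effects rescaled to unit
genetic variance), independent per-site GxE deviations
(`prop_ge` $\cdot\,\sigma^2_g$; the environments' covariance is unstated
in the motivating designs, so sites are exchangeable), independent row and
column gradients, and solves the residual variance so the expected
plot-level $h^2$ hits its target; ordinal scores are latent-Gaussian
values quantile-binned onto 1-9, matching the treatment of scored traits
as Gaussian responses. Several traits can share one physical field layout
via the `layout` argument.

What the generator does *not* contain - epistasis, dominance,
coalescent-exact genealogies, spatially autocorrelated residuals, shared
GxE structure across sites - bounds what passing tests show about real
data: they demonstrate correctness of the estimators under the stated
model, not robustness to every field pathology.

## Numerical choices and limitations

* REML convergence: $\delta$ searched on $\log_{10}\in[-6,6]$, 121-point
  grid + Brent; variance components floored at 0; kinships symmetrised and
  eigenvalues clipped at $-10^{-6}$ tolerance before use.
* Problem sizes in tests and the acceptance script (hundreds of genotypes,
  hundreds to a few thousand markers, 1,000-replicate calibration loops)
  are chosen so the full suite completes on a laptop-class single core
  while keeping every assertion at its stated statistical resolution.
* Missing dosages are mean-imputed only where a method needs a complete
  matrix (kinship, scans, prediction); I/O preserves them; LD and the
  admixture likelihood skip them.
* The analysis scripts run the `full_data` subsetting scheme to mirror the
  published design; its bias note is printed at run time. Method
  comparisons should use `within_fold`.
* Coordinates are 1-based inclusive throughout; chromosome labels are
  opaque strings, and unanchored contigs can be carried as a
  pseudo-chromosome but should be excluded from LD-decay fitting.
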
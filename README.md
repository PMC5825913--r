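# supergs

Mixed-model GWAS and genomic prediction for multi-environment crop trials.

`supergs` is an R package plus analysis workflow for quantitative
geneticists working with inbred diversity panels (chickpea-style selfing
crops) phenotyped in replicated field trials across several environments
and genotyped by whole-genome resequencing. It covers the full chain from
plot-level phenotypes and a VCF to GWAS-informed genomic prediction:

1. **Phenotype adjustment** — per-site linear mixed models with random row
   and column effects give genotype BLUEs; a multi-environment LMM gives
   combined BLUEs, Wald/likelihood-ratio tests, REML variance components
   and broad-sense heritability
   h² = σ²g / (σ²g + σ²ge/t + σ²e/(rt)).
2. **Population structure & LD** — VanRaden genomic relationships
   G = WWᵀ / 2Σp(1−p) with optional compression to groups; admixture-model
   ancestry by EM with cross-validated choice of K; LD decay fitted to the
   drift-equilibrium expectation of r² with extent at the r² = 0.2
   threshold.
3. **Association mapping** — spectral REML (EMMA-style) mixed-model scan
   with P3D reuse of variance components, the SUPER pseudo-QTN kinship
   construction with LD exclusion (r² ≤ 0.1), Bonferroni thresholding,
   flanking-gene reports and cross-trait pleiotropic regions.
4. **Genomic prediction** — RR-BLUP/GBLUP (provably identical predictions
   both ways), Bayesian ridge regression and the Bayesian LASSO (compiled
   Gibbs samplers), a repeated k-fold cross-validation engine, and the
   marker-subsetting experiment that feeds GWAS p-values into the
   prediction model.
5. **Synthetic data** — a simulator for admixed inbred panels with tunable
   LD decay and multi-environment traits of known architecture, so every
   stage is testable against ground truth without any restricted data.

## Worked example

The numbered scripts under `analysis/` run the whole chain on a simulated
132-genotype, 4,000-SNP, 8-chromosome panel with four traits (three sites
× three replicates, shared field layout, one ordinal 1–9 score):

```sh
Rscript analysis/01_simulate.R     # panel VCF, phenotype CSV, truth JSON
Rscript analysis/02_phenotypes.R   # BLUEs, variance components, h2
Rscript analysis/03_popgen.R       # kinship, ancestry, LD decay
Rscript analysis/04_gwas.R         # SUPER scan, regions, flanking genes
Rscript analysis/05_prediction.R   # CV abilities, subset curve
```

`02_phenotypes.R` prints the variance-component table; the entry-mean h²
estimates track the simulated truths:

```
 trait wald_chisq wald_df    wald_p sigma2_g sigma2_ge sigma2_e    h2 h2_truth
    GY      376.9     131  1.22e-25    0.919     0.232    3.632 0.656   0.6860
    SW     2131.8     131  0.00e+00    0.942     0.153    0.305 0.917   0.9425
   EPR      951.2     131 1.52e-124    0.967     0.150    1.126 0.847   0.8702
    EV     1251.2     131 5.10e-182    3.476     0.340    2.831 0.890   0.8893
```

`04_gwas.R` reports 54 SNP–trait associations below the panel's Bonferroni
cut-off (0.05 / 3,998 = 1.25e-05), every one within 500 kb of a planted
QTL, and merges them into regions. `05_prediction.R` traces predictive
ability against the GWAS p-value ladder; for the yield-like trait GY the
ability rises from 0.12 with all markers to a plateau of ~0.87/0.76 at
p ≤ 0.05/0.01 and collapses once the threshold starves the model of
markers — the rise–plateau–drop signature of GWAS-informed marker
selection (the single-scan scheme used here is optimistically biased, as
the script states; the unbiased `within_fold` scheme is the package
default).

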
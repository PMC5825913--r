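#!/usr/bin/env Rscript
# Stage 0 of the workflow: build the synthetic study panel.
#
# Emulates a resequenced inbred chickpea-style diversity panel: 132
# genotypes, two ancestral groups with admixture, eight chromosomes with
# distance-dependent LD, and four multi-environment traits (three sites,
# three replicates, row/column gradients) spanning low to high
# heritability, one of them an ordinal 1-9 score. Everything downstream
# (02-05) starts from the files written here.

suppressMessages(library(supergs))
dir.create("results", showWarnings = FALSE)
dir.create("results/data", showWarnings = FALSE)
seed <- 2024

chroms <- setNames(round(seq(70e6, 30e6, length.out = 8)), paste0("Ca", 1:8))
sim <- simulate_genotypes(
  n = 132, m = 4000, K = 2, alpha_admix = 0.2, chrom_lengths = chroms,
  rho_ld = 4e-6, maf_range = c(0.08, 0.5), fst = 0.2, seed = seed
)
write_vcf(sim$geno, "results/data/panel.vcf")
write.table(round(sim$Q_true, 4), "results/data/q_true.tsv", sep = "\t",
            quote = FALSE, row.names = sim$geno$samples,
            col.names = paste0("pop", 1:2))

traits <- list(
  GY  = list(h2 = 0.2, n_qtl = 60, ordinal = FALSE),  # yield-like, polygenic
  SW  = list(h2 = 0.7, n_qtl = 15, ordinal = FALSE),  # seed weight-like
  EPR = list(h2 = 0.45, n_qtl = 30, ordinal = FALSE),
  EV  = list(h2 = 0.5, n_qtl = 20, ordinal = TRUE)    # 1-9 vigour score
)
pheno <- NULL
truth <- list()
layout <- NULL                         # all traits share one field layout
for (tn in names(traits)) {
  tt <- traits[[tn]]
  tr <- simulate_trait(sim$geno, n_qtl = tt$n_qtl, h2_plot = tt$h2,
                       n_sites = 3, n_reps = 3, prop_ge = 0.15,
                       spatial_sd = 0.3, ordinal = tt$ordinal,
                       trait_name = tn, layout = layout,
                       seed = seed + match(tn, names(traits)))
  layout <- tr$truth$layout
  pheno <- rbind(pheno, tr$pheno)
  truth[[tn]] <- list(causal = tr$truth$causal,
                      effects = round(tr$truth$effects, 5),
                      h2_plot = tt$h2,
                      h2_line_mean = round(tr$truth$h2_line_mean, 4))
}
write_phenotypes(pheno, "results/data/phenotypes.csv")
writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, pretty = TRUE),
           "results/data/truth.json")

# synthetic gene annotation for flanking-gene reports: ~1.5 genes / 100 kb
set.seed(seed)
gff <- NULL
for (ch in names(chroms)) {
  n_g <- round(chroms[[ch]] / 7e4)
  start <- sort(sample.int(chroms[[ch]] - 5000, n_g))
  gff <- rbind(gff, data.frame(chrom = ch, start = start,
                               end = start + sample(500:4500, n_g, TRUE),
                               id = sprintf("%s.g%04d", ch, seq_len(n_g))))
}
writeLines(c("##gff-version 3",
             sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     gff$chrom, gff$start, gff$end, gff$id)),
           "results/data/genes_synthetic.gff3")

cat(sprintf("panel: %d genotypes x %d SNPs on %d chromosomes\n",
            nrow(sim$geno$calls), ncol(sim$geno$calls), length(chroms)))
cat(sprintf("phenotypes: %d plot records over %d traits, %d sites x 3 reps\n",
            nrow(pheno), length(traits), 3))
cat(sprintf("annotation: %d synthetic genes\n", nrow(gff)))
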
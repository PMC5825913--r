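#!/usr/bin/env Rscript
# Association mapping: compressed-kinship MLM scan (P3D), SUPER rescan with
# pseudo-QTN kinship, Bonferroni threshold, flanking genes for significant
# SNPs, and cross-trait pleiotropic regions.

suppressMessages(library(supergs))
geno <- read_vcf("results/data/panel.vcf", maf_min = 0.05)
blues <- read.csv("results/blues.csv")
genes <- read_gff("results/data/genes_synthetic.gff3")
truth <- jsonlite::fromJSON("results/data/truth.json")
traits <- setdiff(names(blues), "genotype")
m <- ncol(geno$calls)
cut_bonf <- bonferroni_threshold(0.05, m)
cat(sprintf("Bonferroni cut-off: 0.05 / %d = %.3g\n", m, cut_bonf))

kin <- vanraden_kinship(geno)
all_hits <- NULL
manhattan <- NULL
for (tn in traits) {
  y <- setNames(blues[[tn]], blues$genotype)
  y <- y[!is.na(y)]
  grid <- choose_compression(y, kin, group_grid = c(33, 66, 132))
  ng <- attr(grid, "best")
  K_use <- if (ng == length(y)) kin else compress_kinship(kin, ng)
  scan0 <- mlm_scan(y, geno, K = K_use)
  pq <- select_pseudo_qtns(scan0, geno, y, n_bins = 100, n_qtn_max = 20)
  scan <- suppressMessages(super_scan(y, geno, pq, ld_exclude_r2 = 0.1))
  cat(sprintf("%s: compression %d groups, %d pseudo-QTNs, min p = %.2g\n",
              tn, ng, length(pq$indices), min(scan$p, na.rm = TRUE)))
  manhattan <- rbind(manhattan, data.frame(
    trait = tn, chrom = scan$chrom, pos = scan$pos,
    neg_log10_p = round(-log10(scan$p), 3)
  ))
  hits <- significant_snps(scan, cut_bonf, trait = tn)
  if (nrow(hits) == 0) next
  fl <- lapply(seq_len(nrow(hits)), function(i)
    flanking_genes(hits$chrom[i], hits$pos[i], genes))
  hits$gene_left <- vapply(fl, function(x)
    if (is.null(x$left)) "" else x$left$gene_id, character(1))
  hits$gene_right <- vapply(fl, function(x)
    if (is.null(x$right)) "" else x$right$gene_id, character(1))
  hits$gene_containing <- vapply(fl, function(x)
    if (is.null(x$containing)) "" else x$containing$gene_id, character(1))
  # was the hit a (or near a) planted causal marker?
  causal_pos <- geno$map$pos[truth[[tn]]$causal]
  causal_chr <- geno$map$chrom[truth[[tn]]$causal]
  hits$near_causal <- vapply(seq_len(nrow(hits)), function(i)
    any(causal_chr == hits$chrom[i] &
          abs(causal_pos - hits$pos[i]) < 5e5), logical(1))
  all_hits <- rbind(all_hits, hits)
}
write.table(manhattan, "results/manhattan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

if (!is.null(all_hits)) {
  write.table(all_hits, "results/significant_snps.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("\n%d SNP-trait associations below %.3g (%d near a planted QTL)\n",
              nrow(all_hits), cut_bonf, sum(all_hits$near_causal)))
  reg <- pleiotropic_regions(all_hits, merge_dist_bp = 1e6)
  write.table(reg, "results/regions.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat("regions (pleiotropic = associated with >1 trait):\n")
  print(reg[, c("chrom", "start", "end", "width_bp", "n_snps", "traits",
                "pleiotropic")], row.names = FALSE)
} else {
  cat("no significant SNPs at the Bonferroni threshold\n")
}
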
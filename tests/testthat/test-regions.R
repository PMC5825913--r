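test_that("flanking genes report distances, containment and absent sides", {
  genes <- data.frame(
    chrom = "Ca1",
    start = c(1000, 5000, 20000),
    end = c(1900, 9000, 30000),
    strand = "+", gene_id = c("gA", "gB", "gC"),
    description = NA_character_, stringsAsFactors = FALSE
  )
  fl <- flanking_genes("Ca1", 9100, genes)          # 100 past gB's end
  expect_equal(fl$left$gene_id, "gB")
  expect_equal(fl$left$distance, 100)
  expect_equal(fl$right$gene_id, "gC")
  expect_equal(fl$right$distance, 20000 - 9100)
  expect_null(fl$containing)

  inside <- flanking_genes("Ca1", 6000, genes)
  expect_equal(inside$containing$gene_id, "gB")
  expect_equal(inside$left$gene_id, "gA")

  first <- flanking_genes("Ca1", 500, genes)
  expect_null(first$left)
  expect_equal(first$right$gene_id, "gA")
  expect_error(flanking_genes("Ca9", 100, genes), "absent")
})

test_that("flanking lookup agrees with a brute-force linear scan", {
  set.seed(30)
  n_g <- 150
  start <- sort(sample.int(5e6, n_g))
  genes <- data.frame(chrom = "c1", start = start,
                      end = start + sample.int(2000, n_g),
                      strand = "+", gene_id = paste0("g", seq_len(n_g)),
                      description = NA_character_, stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), ]
  for (pos in sample.int(5e6, 200)) {
    fl <- flanking_genes("c1", pos, genes)
    # oracle: straight linear search
    left <- NULL; best <- -Inf
    right <- NULL; bestr <- Inf
    cont <- NULL
    for (i in seq_len(n_g)) {
      if (genes$end[i] < pos && genes$end[i] > best) {
        best <- genes$end[i]; left <- genes$gene_id[i]
      }
      if (genes$start[i] > pos && genes$start[i] < bestr) {
        bestr <- genes$start[i]; right <- genes$gene_id[i]
      }
      if (is.null(cont) && genes$start[i] <= pos && genes$end[i] >= pos) {
        cont <- genes$gene_id[i]
      }
    }
    expect_identical(fl$left$gene_id, left)
    expect_identical(fl$right$gene_id, right)
    expect_identical(fl$containing$gene_id, cont)
  }
})

test_that("region widths from printed multi-trait coordinates", {
  snps <- data.frame(
    chrom = c("Ca4", "Ca4", "Ca5", "Ca5", "Ca2"),
    pos = c(35589599, 36026910, 11580061, 12166907, 5000),
    trait = c("EM", "PT", "100SW", "MA", "GY"),
    stringsAsFactors = FALSE
  )
  reg <- pleiotropic_regions(snps, merge_dist_bp = 1e6)
  ca4 <- reg[reg$chrom == "Ca4", ]
  ca5 <- reg[reg$chrom == "Ca5", ]
  expect_equal(ca4$width_bp, 437311)
  expect_equal(round(ca4$width_bp / 1000), 437)
  expect_equal(ca5$width_bp, 586846)
  expect_equal(round(ca5$width_bp / 1000), 587)
  expect_true(ca4$pleiotropic && ca5$pleiotropic)
  # single SNP -> zero-width, non-pleiotropic region
  ca2 <- reg[reg$chrom == "Ca2", ]
  expect_equal(ca2$width_bp, 0)
  expect_false(ca2$pleiotropic)
})

test_that("single-linkage merging respects the distance cut", {
  snps <- data.frame(chrom = "c1", pos = c(100, 900, 5000, 5900, 20000),
                     trait = c("a", "b", "a", "a", "c"),
                     stringsAsFactors = FALSE)
  reg <- pleiotropic_regions(snps, merge_dist_bp = 1000)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$n_snps, c(2, 2, 1))
  expect_equal(reg$pleiotropic, c(TRUE, FALSE, FALSE))
  # chain merging: consecutive gaps under the cut join one region
  reg2 <- pleiotropic_regions(snps, merge_dist_bp = 5000)
  expect_equal(nrow(reg2), 2)
})

test_that("significant SNP extraction respects the threshold and flags", {
  sim <- test_panel()
  tr <- gen_sparse_trait(sim$geno, n_qtl = 2, h2 = 0.6, seed = 8)
  scan <- mlm_scan(tr$y, sim$geno, K = NULL)
  cut <- 1e-4
  hits <- significant_snps(scan, cut, trait = "yield")
  expect_true(all(hits$p < cut))
  expect_true(all(hits$trait == "yield"))
  expect_equal(nrow(hits), sum(scan$p < cut & scan$tested, na.rm = TRUE))
})
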
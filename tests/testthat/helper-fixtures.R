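# shared fixtures, built in code at test time

# small admixed inbred panel reused across tests (cached per session)
test_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genotypes(
        n = 100, m = 400, K = 2, alpha_admix = 0.2,
        chrom_lengths = c(chr1 = 3e7, chr2 = 3e7),
        rho_ld = 5e-6, seed = 101
      )
    }
    cache
  }
})

# multi-environment records drawn directly from known variance components
gen_multienv <- function(s2g = 1, s2ge = 0.5, s2e = 2, ng = 100, t = 3,
                         r = 3, seed = 1) {
  set.seed(seed)
  d <- expand.grid(genotype = sprintf("g%03d", seq_len(ng)),
                   env = paste0("e", seq_len(t)), rep = seq_len(r),
                   stringsAsFactors = FALSE)
  g <- stats::rnorm(ng, 0, sqrt(s2g))
  ge <- stats::rnorm(ng * t, 0, sqrt(s2ge))
  cell <- as.integer(interaction(d$genotype, d$env))
  d$value <- g[as.integer(factor(d$genotype))] + ge[cell] +
    stats::rnorm(nrow(d), 0, sqrt(s2e))
  d
}

# single-site plot records on a grid with optional row/column gradients
gen_site_plots <- function(ng = 12, nr = 8, n_col = 12, geno_sd = 0,
                           spatial_sd = 0.5, resid_sd = 1, seed = 1) {
  set.seed(seed)
  n <- ng * nr
  n_row <- ceiling(n / n_col)
  d <- data.frame(genotype = rep(sprintf("g%02d", seq_len(ng)), nr),
                  site = "s1", trait = "t",
                  rep = rep(seq_len(nr), each = ng),
                  stringsAsFactors = FALSE)
  ord <- sample(n)
  d$row <- ((ord - 1) %/% n_col) + 1
  d$col <- ((ord - 1) %% n_col) + 1
  g <- stats::rnorm(ng, 0, geno_sd)
  re <- stats::rnorm(n_row, 0, spatial_sd)
  ce <- stats::rnorm(n_col, 0, spatial_sd)
  d$value <- g[as.integer(factor(d$genotype))] + re[d$row] + ce[d$col] +
    stats::rnorm(n, 0, resid_sd)
  attr(d, "genetic_values") <- stats::setNames(g, sprintf("g%02d",
                                                          seq_len(ng)))
  d
}

# write a VCF text fixture with explicit genotype strings (optionally DP)
write_vcf_text <- function(path, samples, records, with_dp = FALSE) {
  fmt <- if (with_dp) "GT:DP" else "GT"
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (with_dp)
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(records, function(r) {
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", fmt,
            r$calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# simple GFF3 writer for gene/mRNA features
write_gff_text <- function(path, rows) {
  lines <- c("##gff-version 3", vapply(seq_len(nrow(rows)), function(i) {
    paste(rows$chrom[i], "test", rows$type[i], rows$start[i], rows$end[i],
          ".", rows$strand[i], ".", paste0("ID=", rows$id[i]), sep = "\t")
  }, character(1)))
  writeLines(lines, path)
  path
}

# phenotype vector with a sparse genetic architecture on a panel
gen_sparse_trait <- function(geno, n_qtl = 5, h2 = 0.4, seed = 1) {
  set.seed(seed)
  M <- impute_dosages(geno)
  causal <- sort(sample(ncol(M), n_qtl))
  gv <- drop(scale(M[, causal, drop = FALSE] %*% stats::rnorm(n_qtl)))
  y <- gv + stats::rnorm(nrow(M), 0, sqrt(1 / h2 - 1))
  names(y) <- geno$samples
  list(y = y, causal = causal, genetic = gv)
}
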
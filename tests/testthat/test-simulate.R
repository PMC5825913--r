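test_that("genotype simulation is reproducible and respects its contract", {
  a <- simulate_genotypes(n = 30, m = 120, K = 2, seed = 5)
  b <- simulate_genotypes(n = 30, m = 120, K = 2, seed = 5)
  expect_identical(a$geno$calls, b$geno$calls)
  expect_identical(a$Q_true, b$Q_true)

  expect_true(all(rowSums(a$Q_true) - 1 < 1e-12))
  for (ch in unique(a$geno$map$chrom)) {
    expect_true(all(diff(a$geno$map$pos[a$geno$map$chrom == ch]) > 0))
  }
  # inbred default: no heterozygotes
  expect_true(all(a$geno$calls %in% c(0, 2)))
  k1 <- simulate_genotypes(n = 10, m = 50, K = 1, seed = 2)
  expect_equal(k1$Q_true, matrix(1, 10, 1))
  expect_error(simulate_genotypes(10, 50, maf_range = c(0, 0.6), seed = 1),
               "maf_range")
})

test_that("infinite decay rate gives adjacent-marker independence", {
  s <- simulate_genotypes(n = 150, m = 300, K = 1,
                          chrom_lengths = c(c1 = 3e7), rho_ld = 1,
                          seed = 9)
  M <- impute_dosages(s$geno)
  adj <- mean(vapply(seq_len(299), function(j)
    suppressWarnings(stats::cor(M[, j], M[, j + 1]))^2, numeric(1)),
    na.rm = TRUE)
  set.seed(1)
  Mp <- apply(M, 2, sample)              # permuted columns: true independence
  perm <- mean(vapply(seq_len(299), function(j)
    suppressWarnings(stats::cor(Mp[, j], Mp[, j + 1]))^2, numeric(1)),
    na.rm = TRUE)
  expect_lt(abs(adj - perm), 0.01)
})

test_that("strong divergence separates groups along the leading PC", {
  s <- simulate_genotypes(n = 200, m = 2000, K = 2, alpha_admix = 0.05,
                          fst = 0.45, chrom_lengths = c(c1 = 5e7),
                          rho_ld = 2e-5, seed = 13)
  pc <- stats::prcomp(impute_dosages(s$geno), rank. = 1)
  expect_gt(abs(stats::cor(pc$x[, 1], s$Q_true[, 1])), 0.9)
})

test_that("mean r2 decays monotonically with distance (binned)", {
  s <- simulate_genotypes(n = 120, m = 500, K = 1,
                          chrom_lengths = c(c1 = 2e7), rho_ld = 3e-6,
                          seed = 17)
  pr <- supergs:::ld_pairs(s$geno, max_dist = 2e6)
  expect_gt(length(pr$d), 1000)
  bins <- cut(pr$d, breaks = 5)
  means <- tapply(pr$r2, bins, mean)
  expect_true(all(diff(means) < 0.02))   # non-increasing up to noise
})

test_that("divergence knob raises an independently computed FST", {
  fst_hat <- function(fst_in) {
    s <- simulate_genotypes(n = 150, m = 500, K = 2, alpha_admix = 0.01,
                            fst = fst_in, chrom_lengths = c(c1 = 5e7),
                            rho_ld = 1e-4, seed = 31)
    grp <- apply(s$Q_true, 1, which.max)
    M <- impute_dosages(s$geno)
    p1 <- colMeans(M[grp == 1, , drop = FALSE]) / 2
    p2 <- colMeans(M[grp == 2, , drop = FALSE]) / 2
    pb <- (p1 + p2) / 2
    ok <- pb > 0 & pb < 1
    # Nei-style FST: between-group variance over total
    mean((p1[ok] - p2[ok])^2 / (4 * pb[ok] * (1 - pb[ok])), na.rm = TRUE)
  }
  expect_gt(fst_hat(0.4), fst_hat(0.05))
})

test_that("trait simulation honours heritability limits and additivity", {
  sim <- test_panel()
  # near-degenerate: h2 -> 1, no GxE, no spatial trend
  tr <- simulate_trait(sim$geno, n_qtl = 15, h2_plot = 0.999, n_sites = 1,
                       n_reps = 3, prop_ge = 0, spatial_sd = 0, seed = 3)
  spread <- tapply(tr$pheno$value, tr$pheno$genotype,
                   function(v) diff(range(v)))
  expect_lt(max(spread), 0.2 * stats::sd(tr$pheno$value))

  # single causal locus: class means monotone in coded dose
  tr1 <- simulate_trait(sim$geno, n_qtl = 1, h2_plot = 0.9, n_sites = 1,
                        n_reps = 3, prop_ge = 0, spatial_sd = 0, seed = 4)
  dose <- sim$geno$calls[, tr1$truth$causal]
  pm <- tapply(tr1$pheno$value, tr1$pheno$genotype, mean)[sim$geno$samples]
  cls <- tapply(pm, dose, mean)
  eff_sign <- sign(tr1$truth$effects)
  expect_equal(order(cls * eff_sign), seq_along(cls))

  expect_error(simulate_trait(sim$geno, n_qtl = 0, h2_plot = 0.5),
               "n_qtl")
})

test_that("realized plot-level heritability matches its target on average", {
  sim <- test_panel()
  h2 <- vapply(1:40, function(s) {
    tr <- simulate_trait(sim$geno, n_qtl = 25, h2_plot = 0.5, n_sites = 2,
                         n_reps = 3, prop_ge = 0.1, spatial_sd = 0.2,
                         seed = 500 + s)
    gv <- tr$truth$genetic_values[tr$pheno$genotype]
    stats::var(gv) / stats::var(tr$pheno$value)
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.5), 0.05)
})

test_that("ordinal traits are integer scores on the 1-9 scale", {
  sim <- test_panel()
  tr <- simulate_trait(sim$geno, n_qtl = 10, h2_plot = 0.5, n_sites = 1,
                       n_reps = 3, ordinal = TRUE, seed = 6)
  v <- tr$pheno$value
  expect_true(all(v == round(v)))
  expect_true(all(v >= 1 & v <= 9))
  expect_gt(length(unique(v)), 5)
})
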
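test_that("BLUEs collapse to raw genotype means when spatial variance is zero", {
  # data simulated without spatial trends; REML puts both spatial variances
  # on the boundary and the adjusted means reduce to the raw plot means
  d <- gen_site_plots(ng = 10, nr = 4, n_col = 8, spatial_sd = 0,
                      resid_sd = 1, geno_sd = 2, seed = 1)
  fit <- fit_site_lmm(d, "s1", "t")
  vcs <- fit$varcomp[setdiff(names(fit$varcomp), "residual")]
  expect_true(all(vcs < 1e-8))
  raw <- tapply(d$value, d$genotype, mean)
  expect_equal(fit$blues$blue, as.numeric(raw[fit$blues$genotype]),
               tolerance = 1e-6)
})

test_that("balanced two-genotype toy recovers the exact mean difference", {
  # genotypes crossed with rows and columns so the contrast is orthogonal
  # to the spatial terms
  d <- data.frame(genotype = c("a", "a", "b", "b"), site = "s1", trait = "t",
                  rep = c(1, 2, 1, 2), row = c(1, 2, 2, 1), col = c(1, 2, 1, 2),
                  value = c(10, 12, 22, 20), stringsAsFactors = FALSE)
  fit <- fit_site_lmm(d, "s1", "t")
  b <- stats::setNames(fit$blues$blue, fit$blues$genotype)
  expect_equal(unname(b["b"] - b["a"]), 10, tolerance = 1e-8)
})

test_that("spatial adjustment beats raw means under a strong row gradient", {
  wins <- vapply(1:60, function(s) {
    d <- gen_site_plots(ng = 15, nr = 3, n_col = 9, geno_sd = 1,
                        spatial_sd = 2, resid_sd = 0.5, seed = 900 + s)
    g_true <- attr(d, "genetic_values")
    fit <- fit_site_lmm(d, "s1", "t")
    blue <- stats::setNames(fit$blues$blue, fit$blues$genotype)
    raw <- tapply(d$value, d$genotype, mean)
    ids <- names(g_true)
    mse_blue <- mean((scale(blue[ids], scale = FALSE) -
                        scale(g_true, scale = FALSE))^2)
    mse_raw <- mean((scale(raw[ids], scale = FALSE) -
                       scale(g_true, scale = FALSE))^2)
    mse_blue < mse_raw
  }, logical(1))
  expect_gt(mean(wins), 0.8)
})

test_that("identical duplicated environments give near-zero GxE and error", {
  set.seed(8)
  g <- stats::rnorm(30)
  base <- expand.grid(genotype = sprintf("g%02d", 1:30), rep = 1:2,
                      stringsAsFactors = FALSE)
  # micro-jitter keeps the residual likelihood away from exact degeneracy
  base$value <- g[as.integer(factor(base$genotype))] +
    stats::rnorm(nrow(base), 0, 1e-4)
  d <- rbind(transform(base, env = "e1"), transform(base, env = "e2"))
  vc <- fit_multienv_lmm(d, mode = "genotype_random")
  expect_lt(vc$sigma2_ge, 1e-6)
  expect_lt(vc$sigma2_e, 1e-6)
  expect_gt(vc$sigma2_g, 0.5)
})

test_that("combined BLUEs equal the mean of site BLUEs on balanced data", {
  set.seed(9)
  g <- stats::rnorm(20)
  d <- expand.grid(genotype = sprintf("g%02d", 1:20),
                   env = paste0("e", 1:3), stringsAsFactors = FALSE)
  env_eff <- c(e1 = 1, e2 = -2, e3 = 0.5)
  d$value <- g[as.integer(factor(d$genotype))] + env_eff[d$env]
  fit <- fit_multienv_lmm(d, mode = "genotype_fixed")
  combined <- stats::setNames(fit$blues$blue, fit$blues$genotype)
  site_mean <- tapply(d$value, d$genotype, mean)
  expect_equal(as.numeric(combined[names(site_mean)]),
               as.numeric(site_mean), tolerance = 1e-4)
})

test_that("variance-component mode refuses unidentifiable designs", {
  d <- gen_multienv(ng = 20, t = 1, r = 3, seed = 1)
  expect_error(fit_multienv_lmm(d, mode = "genotype_random"),
               "one environment")
  d2 <- gen_multienv(ng = 20, t = 3, r = 1, seed = 1)
  expect_error(fit_multienv_lmm(d2, mode = "genotype_random"),
               "replication")
})

test_that("one-contrast Wald statistic equals the squared z statistic", {
  d <- gen_site_plots(ng = 2, nr = 8, n_col = 4, geno_sd = 1,
                      spatial_sd = 0.3, seed = 3)
  fit <- fit_site_lmm(d, "s1", "t")
  w <- wald_test_genotype(fit)
  dif <- fit$beta[2] - fit$beta[1]
  vd <- fit$vcov_beta[1, 1] + fit$vcov_beta[2, 2] - 2 * fit$vcov_beta[1, 2]
  expect_equal(w$statistic, unname(dif^2 / vd), tolerance = 1e-8)
  expect_equal(w$df, 1)
})

test_that("Wald test detects a strong genotype effect", {
  ps <- vapply(1:20, function(s) {
    d <- gen_site_plots(ng = 12, nr = 4, geno_sd = 2, spatial_sd = 0.3,
                        resid_sd = 1, seed = 40 + s)
    wald_test_genotype(fit_site_lmm(d, "s1", "t"))$p
  }, numeric(1))
  expect_gte(mean(ps < 0.001), 0.95)
})

test_that("boundary-mixture LRT handles identical and nested models", {
  d <- gen_site_plots(ng = 10, nr = 6, spatial_sd = 0.5, seed = 5)
  d$genotype <- factor(d$genotype)
  d$row_f <- factor(d$row); d$col_f <- factor(d$col)
  full <- supergs:::fit_lmm_fixed_genotype(d, c("(1 | row_f)", "(1 | col_f)"))
  expect_equal(lrt_random_term(full, full)$statistic, 0)
  expect_equal(lrt_random_term(full, full)$p, 1)
  red <- supergs:::fit_lmm_fixed_genotype(d, "(1 | col_f)")
  lr <- lrt_random_term(full, red)
  expect_gte(lr$statistic, 0)
  expect_true(lr$p > 0 && lr$p <= 1)
  expect_error(lrt_random_term(red, full), "optimizer failure")
})

test_that("LRT has high power against a large variance component", {
  ps <- vapply(1:11, function(s) {
    d <- gen_site_plots(ng = 10, nr = 8, n_col = 10, geno_sd = 0,
                        spatial_sd = 0, resid_sd = 1, seed = 60 + s)
    set.seed(600 + s)
    d$value <- d$value + stats::rnorm(max(d$row), 0, 3)[d$row]
    d$genotype <- factor(d$genotype)
    d$row_f <- factor(d$row); d$col_f <- factor(d$col)
    full <- supergs:::fit_lmm_fixed_genotype(d, c("(1 | row_f)",
                                                  "(1 | col_f)"))
    red <- supergs:::fit_lmm_fixed_genotype(d, "(1 | col_f)")
    lrt_random_term(full, red)$p
  }, numeric(1))
  expect_lt(stats::median(ps), 1e-4)
})

test_that("REML likelihood of a nesting model is never below the nested one", {
  for (s in 1:5) {
    d <- gen_site_plots(ng = 8, nr = 6, spatial_sd = 0.4, seed = 70 + s)
    d$genotype <- factor(d$genotype)
    d$row_f <- factor(d$row); d$col_f <- factor(d$col)
    full <- supergs:::fit_lmm_fixed_genotype(d, c("(1 | row_f)",
                                                  "(1 | col_f)"))
    red <- supergs:::fit_lmm_fixed_genotype(d, "(1 | row_f)")
    expect_gte(full$logLik_reml, red$logLik_reml - 1e-6)
  }
})

test_that("broad-sense heritability formula and monotonicity", {
  vc <- list(sigma2_g = 1, sigma2_ge = 0, sigma2_e = 0, t = 3, r = 3)
  expect_equal(broad_sense_h2(vc), 1)
  vc2 <- list(sigma2_g = 1, sigma2_ge = 1, sigma2_e = 1, t = 3, r = 3)
  expect_equal(broad_sense_h2(vc2), 1 / (1 + 1 / 3 + 1 / 9),
               tolerance = 1e-12)
  expect_error(broad_sense_h2(list(sigma2_g = 0, sigma2_ge = 0,
                                   sigma2_e = 0, t = 3, r = 3)),
               "undefined")
  base <- broad_sense_h2(vc2)
  up_g <- broad_sense_h2(modifyList(vc2, list(sigma2_g = 2)))
  up_e <- broad_sense_h2(modifyList(vc2, list(sigma2_e = 2)))
  up_ge <- broad_sense_h2(modifyList(vc2, list(sigma2_ge = 2)))
  expect_gt(up_g, base)
  expect_lt(up_e, base)
  expect_lt(up_ge, base)
})

test_that("trait correlations match the direct formula and edge cases", {
  set.seed(12)
  X <- matrix(stats::rnorm(40 * 6), 40, 6,
              dimnames = list(NULL, paste0("t", 1:6)))
  X[, 2] <- -X[, 1]
  out <- trait_correlations(X)
  expect_equal(diag(out$r), rep(1, 6), ignore_attr = TRUE)
  expect_equal(out$r["t1", "t2"], -1, tolerance = 1e-12)
  # brute-force covariance/sd oracle over all pairs
  for (a in 1:5) for (b in (a + 1):6) {
    xa <- X[, a]; xb <- X[, b]
    oracle <- mean((xa - mean(xa)) * (xb - mean(xb))) /
      (stats::sd(xa) * stats::sd(xb)) * length(xa) / (length(xa) - 1)
    expect_equal(out$r[a, b], oracle, tolerance = 1e-12)
  }
  # star coding matches the p matrix
  expect_true(all((out$stars != "") == (out$p < 0.05 & row(out$p) !=
                                          col(out$p))))
  # zero-variance trait reported missing
  X[, 3] <- 5
  out2 <- trait_correlations(X)
  expect_true(all(is.na(out2$r[3, -3])))
})
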
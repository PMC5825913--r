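test_that("VanRaden kinship matches hand arithmetic and a loop oracle", {
  # one marker, p = 0.5, doses 0/1/2 -> centered -1/0/1, denominator 0.5
  M1 <- matrix(c(0, 1, 2), 3, 1)
  k1 <- vanraden_kinship(M1)
  expect_equal(k1$denominator, 0.5)
  expect_equal(k1$G, outer(c(-1, 0, 1), c(-1, 0, 1)) / 0.5)

  set.seed(4)
  M <- matrix(stats::rbinom(50 * 200, 2, stats::runif(200, 0.1, 0.9)),
              50, 200, byrow = TRUE)
  kin <- vanraden_kinship(M)
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  G_loop <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50) {
    G_loop[i, j] <- sum((M[i, ] - 2 * p) * (M[j, ] - 2 * p)) / denom
  }
  expect_equal(kin$G, G_loop, tolerance = 1e-10)
})

test_that("kinship invariants: identical rows, PSD, inbred diagonal near 2", {
  sim <- test_panel()
  M <- impute_dosages(sim$geno)
  M2 <- rbind(M, M[1, ])                 # duplicate a genotype
  kin <- vanraden_kinship(M2)
  n <- nrow(M2)
  expect_equal(kin$G[n, ], kin$G[1, ], tolerance = 1e-12)
  ev <- eigen(kin$G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # fully inbred panel: mean diagonal ~ 2 with sample-frequency centering
  expect_lt(abs(mean(diag(vanraden_kinship(M)$G)) - 2), 0.1)
  expect_error(vanraden_kinship(matrix(2, 5, 4)), "monomorphic")
})

test_that("kinship compression identities and family recovery", {
  sim <- test_panel()
  kin <- vanraden_kinship(sim$geno)
  n <- nrow(kin$G)
  same <- compress_kinship(kin, n)
  expect_equal(expand_kinship(same), kin$G, tolerance = 1e-12,
               ignore_attr = TRUE)
  one <- compress_kinship(kin, 1)
  expect_equal(one$G_compressed[1, 1], mean(kin$G))
  expect_error(compress_kinship(kin, n + 1), "n_groups")

  # two highly diverged families: keep the unambiguous (pure-ancestry)
  # members and expect the clustering to recover them exactly
  fam <- simulate_genotypes(n = 44, m = 300, K = 2, alpha_admix = 1e-3,
                            fst = 0.5, chrom_lengths = c(c1 = 3e7),
                            rho_ld = 1e-4, seed = 77)
  pure <- which(apply(fam$Q_true, 1, max) > 0.99)
  expect_gt(length(pure), 30)
  geno_pure <- subset_genotypes(fam$geno, samples = pure)
  truth <- apply(fam$Q_true[pure, ], 1, which.max)
  comp <- compress_kinship(vanraden_kinship(geno_pure), 2)
  tab <- table(comp$groups, truth)
  expect_equal(min(nrow(tab), ncol(tab)), 2)
  expect_equal(sum(apply(tab, 1, max)), length(pure))   # pure blocks
})

test_that("compression level chooser reports the null REML ladder", {
  sim <- test_panel()
  tr <- gen_sparse_trait(sim$geno, n_qtl = 10, h2 = 0.5, seed = 3)
  kin <- vanraden_kinship(sim$geno)
  tab <- choose_compression(tr$y, kin, group_grid = c(5, 25, 100))
  expect_equal(nrow(tab), 3)
  expect_true(attr(tab, "best") %in% tab$n_groups)
  expect_true(all(is.finite(tab$logL)))
})

test_that("spectral REML beats a fine grid and recovers known variances", {
  sim <- test_panel()
  K <- vanraden_kinship(sim$geno)$G
  set.seed(10)
  n <- nrow(K)
  L <- t(chol(K + diag(1e-6, n)))
  y <- drop(L %*% stats::rnorm(n)) * sqrt(2) + stats::rnorm(n)
  fit <- emma_reml(y, K = K)

  # grid oracle: recompute restricted logL independently on 1,000 deltas
  X <- matrix(1, n, 1)
  P <- diag(n) - X %*% solve(crossprod(X), t(X))
  SKS <- P %*% K %*% P
  ed <- eigen((SKS + t(SKS)) / 2, symmetric = TRUE)
  xi <- ed$values[1:(n - 1)]
  eta <- drop(crossprod(ed$vectors[, 1:(n - 1)], y))
  rll <- function(delta) {
    s <- sum(eta^2 / (xi + delta))
    0.5 * ((n - 1) * (log((n - 1) / (2 * pi)) - 1 - log(s)) -
             sum(log(xi + delta)))
  }
  grid_ll <- vapply(10^seq(-6, 6, length.out = 1000), rll, numeric(1))
  expect_gte(fit$logL + 1e-6, max(grid_ll))

  # identity kinship sanity: total variance close to the sample variance
  fid <- emma_reml(y, K = diag(n))
  expect_lt(abs((fid$sigma2_g + fid$sigma2_e) /
                  (stats::var(y) * (n - 1) / n) - 1), 0.05)
  expect_error(emma_reml(rep(1, n), K = K), "constant")
})

test_that("REML recovers simulated variance components on average", {
  set.seed(22)
  n <- 300
  A <- matrix(stats::rnorm(n * n), n)
  K <- crossprod(A) / n
  K <- K / mean(diag(K))
  L <- t(chol(K + diag(1e-8, n)))
  est <- vapply(1:30, function(s) {
    set.seed(3000 + s)
    y <- drop(L %*% stats::rnorm(n)) * sqrt(2) + stats::rnorm(n, 0, 1)
    f <- emma_reml(y, K = K)
    c(f$sigma2_g, f$sigma2_e)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) / 2 - 1), 0.15)
  expect_lt(abs(mean(est[2, ]) / 1 - 1), 0.15)
})
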
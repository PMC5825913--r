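test_that("RR-BLUP equals ridge regression at the matched shrinkage", {
  set.seed(3)
  n <- 80; m <- 300
  M <- matrix(stats::rbinom(n * m, 2, 0.4), n, m)
  tr <- list(y = drop(scale(M[, 1:10] %*% stats::rnorm(10))) +
               stats::rnorm(n))
  fit <- fit_rrblup(tr$y, M)
  lam <- fit$sigma2_e / fit$sigma2_g * fit$denominator
  W <- sweep(M, 2, 2 * fit$p)
  mme <- ridge_closed_form(tr$y, W, lam)
  expect_equal(fit$mu, mme$mu, tolerance = 1e-8)
  expect_equal(fit$beta, mme$beta, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("marker-effect and kinship-row predictions agree", {
  set.seed(4)
  n <- 60; m <- 200
  M <- matrix(stats::rbinom(n * m, 2, 0.35), n, m)
  y <- drop(scale(M[, 1:5] %*% stats::rnorm(5))) + stats::rnorm(n)
  fit <- fit_rrblup(y, M)
  Mn <- matrix(stats::rbinom(25 * m, 2, 0.35), 25, m)
  expect_equal(predict(fit, Mn, route = "markers"),
               predict(fit, Mn, route = "kinship"), tolerance = 1e-8)
  # training-set identity too
  expect_equal(drop(sweep(M, 2, 2 * fit$p) %*% fit$beta), fit$ghat,
               tolerance = 1e-8)
})

test_that("degenerate responses are handled: constant y and noiseless traits", {
  set.seed(5)
  M <- matrix(stats::rbinom(40 * 100, 2, 0.4), 40, 100)
  cfit <- fit_rrblup(rep(7, 40), M)
  expect_equal(predict(cfit, M), rep(7, 40))
  # noiseless genetic trait: training predictions nearly interpolate
  g <- drop(scale(M[, 1:20] %*% stats::rnorm(20)))
  nfit <- fit_rrblup(g, M)
  expect_gt(stats::cor(nfit$mu + nfit$ghat, g), 0.999)
  expect_error(fit_rrblup(stats::rnorm(5), M[1:5, ]), "10 training")
})

test_that("BRR posterior means match the conjugate ridge solution", {
  set.seed(6)
  n <- 100; m <- 60
  M <- matrix(stats::rbinom(n * m, 2, 0.4), n, m)
  y <- drop(scale(M[, 1:6] %*% stats::rnorm(6))) + stats::rnorm(n)
  s2 <- 1; s2b <- 0.01
  fit <- fit_brr(y, M, n_iter = 8000, burn_in = 1000, thin = 5, seed = 7,
                 fix_sigma2 = s2, fix_sigma2_beta = s2b)
  X <- scale(M, center = TRUE, scale = FALSE)
  oracle <- ridge_closed_form(y, X, s2 / s2b)
  z <- abs(fit$beta - oracle$beta) / pmax(fit$beta_mcse, 1e-12)
  # per-marker 3-MC-SD band (a ~0.3% exceedance rate is Monte-Carlo noise),
  # plus a simultaneous bound for the maximum over m comparisons
  expect_gte(mean(z <= 3), 0.95)
  expect_lt(max(z), stats::qnorm(1 - 0.0005 / m))
})

test_that("Bayesian LASSO shrinks nulls and finds a planted large effect", {
  set.seed(8)
  n <- 120; m <- 300
  M <- matrix(stats::rbinom(n * m, 2, 0.4), n, m)
  # total-shrinkage limit
  y0 <- stats::rnorm(n)
  bl0 <- fit_bayesian_lasso(y0, M, n_iter = 3000, burn_in = 500, thin = 5,
                            seed = 9, fix_lambda2 = 1e8)
  expect_lt(max(abs(bl0$beta)), 1e-3)
  # planted signal detection across seeds
  hits <- vapply(1:3, function(s) {
    set.seed(100 + s)
    causal <- sample(m, 1)
    y <- drop(scale(M[, causal])) * 2 + stats::rnorm(n, 0, 0.5)
    fit <- fit_bayesian_lasso(y, M, n_iter = 4000, burn_in = 1000,
                              thin = 5, seed = 100 + s)
    r2_with_causal <- suppressWarnings(
      stats::cor(M[, which.max(abs(fit$beta))], M[, causal])^2)
    r2_with_causal > 0.8    # top effect at (or tagging) the causal locus
  }, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("BL with frozen equal variances matches ridge within MC error", {
  set.seed(10)
  n <- 90; m <- 50
  M <- matrix(stats::rbinom(n * m, 2, 0.45), n, m)
  y <- drop(scale(M[, 1:4] %*% stats::rnorm(4))) + stats::rnorm(n)
  tau2 <- 0.02
  fit <- fit_bayesian_lasso(y, M, n_iter = 8000, burn_in = 1000, thin = 5,
                            seed = 11, fix_tau2 = tau2)
  # with tau2 fixed, beta_j ~ N(0, tau2 * sigma2): ridge at lambda = 1/tau2
  X <- scale(M, center = TRUE, scale = FALSE)
  oracle <- ridge_closed_form(y, X, 1 / tau2)
  z <- abs(fit$beta - oracle$beta) / pmax(fit$beta_mcse, 1e-12)
  expect_gte(mean(z <= 3), 0.95)
  expect_lt(max(z), stats::qnorm(1 - 0.0005 / m))
})

test_that("exchangeable duplicate markers get equal posterior effects", {
  set.seed(12)
  n <- 80; m <- 40
  M <- matrix(stats::rbinom(n * m, 2, 0.4), n, m)
  M[, 2] <- M[, 1]
  y <- drop(scale(M[, 1])) + stats::rnorm(n, 0, 0.7)
  fit <- fit_brr(y, M, n_iter = 8000, burn_in = 1000, thin = 5, seed = 13)
  se12 <- sqrt(fit$beta_mcse[1]^2 + fit$beta_mcse[2]^2)
  expect_lt(abs(fit$beta[1] - fit$beta[2]), 4 * se12)
})

test_that("Bayesian fits are exactly reproducible from the seed", {
  set.seed(14)
  M <- matrix(stats::rbinom(50 * 80, 2, 0.4), 50, 80)
  y <- stats::rnorm(50)
  a <- fit_brr(y, M, n_iter = 1500, burn_in = 300, thin = 3, seed = 42)
  b <- fit_brr(y, M, n_iter = 1500, burn_in = 300, thin = 3, seed = 42)
  expect_identical(a$beta, b$beta)
  expect_identical(a$sigma2, b$sigma2)
  c1 <- fit_bayesian_lasso(y, M, n_iter = 1500, burn_in = 300, thin = 3,
                           seed = 43)
  c2 <- fit_bayesian_lasso(y, M, n_iter = 1500, burn_in = 300, thin = 3,
                           seed = 43)
  expect_identical(c1$beta, c2$beta)
})
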
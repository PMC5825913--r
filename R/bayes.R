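#' Bayesian ridge regression by Gibbs sampling
#'
#' Marker-effect regression \eqn{y = \mu + W\beta + e} with a common
#' Gaussian prior \eqn{\beta_j \sim N(0, \sigma^2_\beta)} - the same
#' shrinkage for every marker - and scaled-inverse-chi-square priors on
#' \eqn{\sigma^2_\beta} and \eqn{\sigma^2}. Hyperparameter scales follow the
#' usual heuristic of splitting the phenotypic variance (proportion `R2` to
#' markers). The sampler is compiled (per-coordinate updates with residual
#' maintenance) and deterministic given the R session seed set from `seed`.
#'
#' @param y phenotype vector.
#' @param M n x m dosage matrix; columns are centred internally.
#' @param n_iter,burn_in,thin chain settings (defaults 10000/2000/5).
#' @param seed RNG seed.
#' @param R2 prior proportion of variance attributed to markers (default
#'   0.5).
#' @param df_beta,df_e prior degrees of freedom (default 5 each).
#' @param fix_sigma2,fix_sigma2_beta freeze a variance at a given value
#'   (`NULL` = sampled); used for conjugate-oracle validation.
#' @return object of class `bayes_fit` with posterior means `mu`, `beta`,
#'   `sigma2`, `sigma2_beta`, sample matrices in `samples`, the Monte-Carlo
#'   standard errors `beta_mcse`, and the chain settings.
#' @export
fit_brr <- function(y, M, n_iter = 10000, burn_in = 2000, thin = 5,
                    seed = 1, R2 = 0.5, df_beta = 5, df_e = 5,
                    fix_sigma2 = NULL, fix_sigma2_beta = NULL) {
  stopifnot(n_iter > burn_in)
  M <- impute_dosages(M)
  X <- scale(M, center = TRUE, scale = FALSE)
  vy <- stats::var(y)
  msx <- sum(apply(X, 2, stats::var))
  S_b <- vy * R2 / max(msx, 1e-8) * (df_beta + 2) / df_beta
  S_e <- vy * (1 - R2) * (df_e + 2) / df_e
  set.seed(seed)
  out <- gibbs_brr_cpp(y, X, as.integer(n_iter), as.integer(burn_in),
                       as.integer(thin), df_beta, S_b, df_e, S_e,
                       ifelse(is.null(fix_sigma2), -1, fix_sigma2),
                       ifelse(is.null(fix_sigma2_beta), -1, fix_sigma2_beta))
  finalize_bayes_fit(out, "BRR", X, M, n_iter, burn_in, thin, seed,
                     extra = list(sigma2_beta = mean(out$sigma2_beta)))
}

#' Bayesian LASSO by Gibbs sampling
#'
#' Marker-effect regression with a double-exponential (Laplace) prior on
#' each effect, via the scale-mixture-of-normals representation: per-marker
#' variances \eqn{\tau^2_j} with exponential mixing at rate
#' \eqn{\lambda^2/2} and a Gamma hyperprior on \eqn{\lambda^2}. Small
#' effects are shrunk harder than large ones, giving the model its
#' variable-selection flavour.
#'
#' @inheritParams fit_brr
#' @param shape_lambda,rate_lambda Gamma hyperprior on `lambda^2` (defaults
#'   0.55 and 1e-4, weakly informative).
#' @param fix_lambda2 freeze `lambda^2` (for the total-shrinkage limit).
#' @param fix_tau2 freeze all per-marker variances at one value (degenerate
#'   equal-variance setting used to validate against ridge).
#' @return a `bayes_fit` (see [fit_brr()]) with posterior mean `lambda2`.
#' @export
fit_bayesian_lasso <- function(y, M, n_iter = 10000, burn_in = 2000,
                               thin = 5, seed = 1,
                               shape_lambda = 0.55, rate_lambda = 1e-4,
                               df_e = 5, R2 = 0.5,
                               fix_lambda2 = NULL, fix_tau2 = NULL) {
  stopifnot(n_iter > burn_in)
  M <- impute_dosages(M)
  X <- scale(M, center = TRUE, scale = FALSE)
  vy <- stats::var(y)
  S_e <- vy * (1 - R2) * (df_e + 2) / df_e
  set.seed(seed)
  out <- gibbs_bl_cpp(y, X, as.integer(n_iter), as.integer(burn_in),
                      as.integer(thin), shape_lambda, rate_lambda,
                      df_e, S_e,
                      ifelse(is.null(fix_lambda2), -1, fix_lambda2),
                      ifelse(is.null(fix_tau2), -1, fix_tau2))
  finalize_bayes_fit(out, "BL", X, M, n_iter, burn_in, thin, seed,
                     extra = list(lambda2 = mean(out$lambda2)))
}

# assemble the common bayes_fit structure from raw sampler output
finalize_bayes_fit <- function(out, model, X, M, n_iter, burn_in, thin,
                               seed, extra = list()) {
  beta_hat <- colMeans(out$beta)
  n_samp <- nrow(out$beta)
  # batch-means Monte-Carlo SE of each posterior-mean effect
  n_batch <- min(20, n_samp)
  bi <- cut(seq_len(n_samp), n_batch, labels = FALSE)
  bm <- apply(out$beta, 2, function(b) tapply(b, bi, mean))
  beta_mcse <- apply(bm, 2, stats::sd) / sqrt(n_batch)
  structure(
    c(list(model = model, mu = mean(out$mu), beta = beta_hat,
           sigma2 = mean(out$sigma2), beta_mcse = beta_mcse,
           center = attr(X, "scaled:center"),
           samples = out, n_samples = n_samp,
           chain = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                        seed = seed)),
      extra),
    class = "bayes_fit"
  )
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf(
    "bayes_fit [%s]: %d markers, %d posterior samples, sigma2 = %.4g\n",
    x$model, length(x$beta), x$n_samples, x$sigma2))
  invisible(x)
}

#' Predict from a Bayesian marker-effect fit
#'
#' @param object a `bayes_fit`.
#' @param M_new dosage matrix (training-mean centred internally).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.bayes_fit <- function(object, M_new, ...) {
  M_new <- impute_dosages(M_new)
  W <- sweep(M_new, 2, object$center)
  drop(object$mu + W %*% object$beta)
}

#' Ridge-regression closed form with unpenalised intercept
#'
#' Solves the mixed-model equations for \eqn{y = \mu + X\beta + e} with
#' penalty \eqn{\lambda\|\beta\|^2}; the conjugate posterior mean the Gibbs
#' samplers must match when their variances are frozen at
#' \eqn{\lambda = \sigma^2 / \sigma^2_\beta}.
#'
#' @param y response; `X` centred predictor matrix; `lambda` ridge penalty.
#' @return list with `mu` and `beta`.
#' @export
ridge_closed_form <- function(y, X, lambda) {
  n <- length(y); m <- ncol(X)
  A <- rbind(
    cbind(n, t(colSums(X))),
    cbind(colSums(X), crossprod(X) + diag(lambda, m))
  )
  b <- c(sum(y), drop(crossprod(X, y)))
  sol <- unname(solve(A, b))
  list(mu = sol[1], beta = sol[-1])
}
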
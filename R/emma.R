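#' Spectral REML for the one-kinship mixed model
#'
#' Restricted maximum likelihood for the model
#' \eqn{y = X\beta + u + e}, \eqn{u \sim N(0, K\sigma^2_g)},
#' \eqn{e \sim N(0, I\sigma^2_e)}, by the EMMA device: project y off X,
#' eigendecompose the projected kinship once, and maximise the profiled
#' restricted likelihood over the single variance ratio
#' \eqn{\delta = \sigma^2_e / \sigma^2_g} (grid scan on log-delta followed by
#' Brent polish in the best bracket).
#'
#' @param y numeric response (no missing values).
#' @param X fixed-effect design matrix (default intercept only); must have
#'   full column rank.
#' @param K n x n symmetric PSD kinship matrix.
#' @param delta_range log10 search range for delta (default -6..6).
#' @param n_grid number of grid points (default 121).
#' @return list with `sigma2_g`, `sigma2_e`, `delta`, `logL` (restricted
#'   log-likelihood at the optimum), `beta` (GLS fixed effects), and the
#'   eigen pieces (`U_full`, `lambda_full`) for reuse by scans.
#' @export
emma_reml <- function(y, X = NULL, K, delta_range = c(-6, 6), n_grid = 121) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (stats::sd(y) < 1e-12) stop("response is constant")
  if (max(abs(K - t(K))) > 1e-8) stop("kinship matrix is not symmetric")
  q <- qr(X)$rank
  if (q < ncol(X)) stop("fixed-effect design is rank deficient")

  # eigen of S(K+I)S with S the projector off X; shift keeps values positive
  XtXi <- solve(crossprod(X))
  SKS <- K + diag(n) - X %*% (XtXi %*% crossprod(X, K + diag(n)))
  SKS <- SKS - t(X %*% (XtXi %*% crossprod(X, t(SKS))))
  SKS <- (SKS + t(SKS)) / 2
  ed <- eigen(SKS, symmetric = TRUE)
  xi <- ed$values[seq_len(n - q)] - 1
  if (any(xi < -1e-6 * max(1, abs(xi[1])))) {
    stop("kinship matrix is not PSD within tolerance")
  }
  xi <- pmax(xi, 0)
  eta <- drop(crossprod(ed$vectors[, seq_len(n - q), drop = FALSE], y))

  rll <- function(log10_delta) {
    d <- 10^log10_delta
    denom <- xi + d
    s <- sum(eta^2 / denom)
    0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1 - log(s)) -
             sum(log(denom)))
  }
  grid <- seq(delta_range[1], delta_range[2], length.out = n_grid)
  ll <- vapply(grid, rll, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  opt <- stats::optimize(rll, c(lo, hi), maximum = TRUE, tol = 1e-10)
  best <- if (opt$objective >= ll[i]) opt else
    list(maximum = grid[i], objective = ll[i])
  delta <- 10^best$maximum
  sigma2_g <- sum(eta^2 / (xi + delta)) / (n - q)
  sigma2_e <- delta * sigma2_g

  # GLS fixed effects under the fitted covariance
  edK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  w <- 1 / (pmax(edK$values, 0) + delta)
  Xs <- crossprod(edK$vectors, X)
  ys <- drop(crossprod(edK$vectors, y))
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))

  list(sigma2_g = sigma2_g, sigma2_e = sigma2_e, delta = delta,
       logL = best$objective, beta = drop(beta),
       U_full = edK$vectors, lambda_full = pmax(edK$values, 0),
       n = n, q = q)
}
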
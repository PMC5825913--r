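#' Admixture-model ancestry estimation by EM
#'
#' Maximum-likelihood estimation of the K-population admixture model for
#' unrelated individuals: dosage \eqn{g_{ij} \sim Binomial(2, f_{ij})} with
#' \eqn{f_{ij} = \sum_k q_{ik} p_{jk}}, maximised over ancestry fractions Q
#' (rows on the simplex) and population allele frequencies P by the classic
#' multiplicative EM updates. Missing calls are skipped in the likelihood.
#' Several random restarts are run and the best log-likelihood kept; results
#' are deterministic given `seed`.
#'
#' @param geno a [genotype_matrix()] or dosage matrix.
#' @param K number of ancestral populations (>= 1). `K = 1` has the closed
#'   form Q = 1, P = sample frequencies.
#' @param seed RNG seed for the restarts.
#' @param n_restarts random initialisations (default 3).
#' @param max_iter EM iterations per restart (default 400).
#' @param tol stop when the log-likelihood gain per iteration falls below
#'   this (default 1e-6).
#' @return object of class `admixture_fit`: list with `Q` (n x K), `P`
#'   (m x K), `logL`, `n_iter`, `K`.
#' @export
admixture_em <- function(geno, K, seed = 1, n_restarts = 3,
                         max_iter = 400, tol = 1e-6) {
  G <- if (inherits(geno, "genotype_matrix")) geno$calls else as.matrix(geno)
  n <- nrow(G); m <- ncol(G)
  stopifnot(K >= 1)
  obs <- !is.na(G)
  G0 <- G; G0[!obs] <- 0              # contributions of NA cells zeroed
  eps <- 1e-6

  loglik <- function(Q, P) {
    FF <- Q %*% t(P)
    FF <- pmin(pmax(FF, eps), 1 - eps)
    sum((G0 * log(FF) + (2 - G0) * log(1 - FF))[obs])
  }

  if (K == 1) {
    P <- matrix(colSums(G0) / (2 * colSums(obs)), m, 1)
    P <- pmin(pmax(P, eps), 1 - eps)
    Q <- matrix(1, n, 1)
    return(structure(list(Q = Q, P = P, logL = loglik(Q, P),
                          n_iter = 0L, K = 1L),
                     class = "admixture_fit"))
  }

  set.seed(seed)
  # informed start: k-means on leading principal components, frequencies
  # from the implied clusters; EM then refines. Random restarts guard
  # against a poor clustering.
  inits <- vector("list", n_restarts + 1)
  inits[[1]] <- tryCatch({
    Mi <- G; for (j in seq_len(m)) {
      mu <- mean(G[, j], na.rm = TRUE)
      Mi[is.na(G[, j]), j] <- if (is.finite(mu)) mu else 0
    }
    pc <- stats::prcomp(Mi, rank. = min(K, 5))
    km <- stats::kmeans(pc$x[, seq_len(min(K, ncol(pc$x))), drop = FALSE],
                        centers = K, nstart = 5)
    Q0 <- matrix(0.5 / (K - 0.5), n, K)
    Q0[cbind(seq_len(n), km$cluster)] <- 1
    Q0 <- Q0 / rowSums(Q0)
    P0 <- vapply(seq_len(K), function(k) {
      idx <- km$cluster == k
      colSums(G0[idx, , drop = FALSE]) / pmax(2 * colSums(obs[idx, ,
                                                              drop = FALSE]), 1)
    }, numeric(m))
    list(Q = Q0, P = pmin(pmax(P0, eps), 1 - eps))
  }, error = function(e) NULL)
  for (r in seq_len(n_restarts)) {
    Qg <- matrix(stats::rgamma(n * K, 1), n, K)
    inits[[r + 1]] <- list(Q = Qg / rowSums(Qg),
                           P = matrix(stats::runif(m * K, 0.05, 0.95), m, K))
  }
  best <- NULL
  for (init in inits) {
    if (is.null(init)) next
    Q <- init$Q
    P <- init$P
    ll_prev <- -Inf
    it <- 0
    repeat {
      it <- it + 1
      FF <- Q %*% t(P)
      FF <- pmin(pmax(FF, eps), 1 - eps)
      A1 <- G0 / FF                    # n x m, zero where missing
      A0 <- (2 - G0) / (1 - FF); A0[!obs] <- 0
      Qn <- matrix(0, n, K); Pnum <- matrix(0, m, K); Pden <- matrix(0, m, K)
      for (k in seq_len(K)) {
        ak <- A1 * (Q[, k] %o% P[, k])       # expected alt-allele counts
        bk <- A0 * (Q[, k] %o% (1 - P[, k])) # expected ref-allele counts
        Qn[, k] <- rowSums(ak + bk)
        Pnum[, k] <- colSums(ak)
        Pden[, k] <- colSums(ak + bk)
      }
      Q <- Qn / rowSums(Qn)
      P <- pmin(pmax(Pnum / pmax(Pden, 1e-12), eps), 1 - eps)
      ll <- loglik(Q, P)
      if (ll < ll_prev - 1e-4) {
        stop("EM log-likelihood decreased (", ll_prev, " -> ", ll, ")")
      }
      if (it >= max_iter || ll - ll_prev < tol * max(1, abs(ll))) break
      ll_prev <- ll
    }
    if (is.null(best) || ll > best$logL) {
      best <- list(Q = Q, P = P, logL = ll, n_iter = it, K = as.integer(K))
    }
  }
  structure(best, class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, logL = %.2f (%d EM iterations)\n",
              x$K, x$logL, x$n_iter))
  invisible(x)
}

#' Align estimated ancestry columns to a reference by greedy matching
#'
#' Label switching makes Q columns arbitrary; this permutes columns of `Q`
#' to best match `Q_ref` (greedy on column correlations).
#'
#' @param Q,Q_ref n x K ancestry matrices.
#' @return column-permuted `Q`.
#' @export
align_ancestry <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K)
  cc <- suppressWarnings(stats::cor(Q, Q_ref))
  cc[!is.finite(cc)] <- 0
  perm <- integer(K)
  used <- logical(K)
  for (j in order(-apply(abs(cc), 2, max))) {
    i <- order(-cc[, j])
    i <- i[!used[i]][1]
    perm[j] <- i
    used[i] <- TRUE
  }
  Q[, perm, drop = FALSE]
}

#' Choose the number of populations by masked cross-validation
#'
#' The model-selection device of the ADMIXTURE software: hide a random fold
#' of the (individual, marker) genotype entries, fit the admixture model on
#' the remainder, and score the hidden entries by binomial deviance under
#' the fitted \eqn{\hat f_{ij}}. The K minimising the mean masked deviance
#' is selected.
#'
#' @param geno a [genotype_matrix()] or dosage matrix.
#' @param k_max largest K to consider.
#' @param n_folds number of entry folds (default 5).
#' @param seed RNG seed (masking and EM restarts).
#' @param ... passed to [admixture_em()].
#' @return data.frame with columns `K`, `cv_error` (mean per-entry masked
#'   deviance); attribute `best_k` is the argmin.
#' @export
choose_k_cv <- function(geno, k_max, n_folds = 5, seed = 1, ...) {
  G <- if (inherits(geno, "genotype_matrix")) geno$calls else as.matrix(geno)
  stopifnot(k_max >= 1, n_folds >= 2)
  obs_idx <- which(!is.na(G))
  set.seed(seed)
  for (attempt in 1:20) {
    fold <- sample(rep_len(seq_len(n_folds), length(obs_idx)))
    ok <- TRUE
    for (f in seq_len(n_folds)) {
      Gm <- G
      Gm[obs_idx[fold == f]] <- NA
      if (any(colSums(!is.na(Gm)) == 0)) { ok <- FALSE; break }
    }
    if (ok) break
    message("choose_k_cv: a fold emptied a marker; re-drawing mask")
  }
  eps <- 1e-6
  err <- matrix(NA_real_, n_folds, k_max)
  for (f in seq_len(n_folds)) {
    mask <- obs_idx[fold == f]
    Gm <- G
    Gm[mask] <- NA
    for (K in seq_len(k_max)) {
      fit <- admixture_em(Gm, K, seed = seed + 1000 * f + K, ...)
      FF <- fit$Q %*% t(fit$P)
      FF <- pmin(pmax(FF, eps), 1 - eps)
      g <- G[mask]
      err[f, K] <- mean(-2 * (g * log(FF[mask]) +
                                (2 - g) * log(1 - FF[mask])))
    }
  }
  out <- data.frame(K = seq_len(k_max), cv_error = colMeans(err))
  attr(out, "best_k") <- out$K[which.min(out$cv_error)]
  out
}
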
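#' Mixed-linear-model association scan (P3D)
#'
#' Tests each marker for association with a phenotype under the kinship
#' mixed model \eqn{y = \mu + x_j\beta_j + u + e}, \eqn{u \sim N(0,
#' K\sigma^2_g)}. With `p3d = TRUE` (the default) the variance components
#' are estimated once under the null model and reused for every marker
#' ("population parameters previously determined"); the marker test is then
#' generalized least squares in the eigenspace of K. With `p3d = FALSE` the
#' variance ratio is re-estimated per marker by [emma_reml()] (slower,
#' near-identical p-values). `K = NULL` drops the polygenic term entirely
#' and the scan reduces exactly to ordinary least squares.
#'
#' Markers with fewer than `min_obs` non-missing calls, or monomorphic
#' markers, are flagged untested (`tested = FALSE`, `p = NA`) rather than
#' dropped.
#'
#' @param y named phenotype vector (e.g. genotype BLUEs); names must be a
#'   subset of the panel's samples.
#' @param geno a [genotype_matrix()].
#' @param K kinship: a `kinship_matrix`, a plain matrix, or `NULL` for the
#'   OLS limit. A compressed `kinship_matrix` is expanded to individuals.
#' @param p3d reuse null-model variance components for every marker.
#' @param min_obs minimum non-missing calls for a marker to be tested
#'   (default 5).
#' @return data.frame of class `assoc_result`: chrom, pos, snp_id, effect,
#'   se, p, maf, tested; attributes `sigma2_g`, `sigma2_e`, `delta`, `p3d`,
#'   `kinship_mode`.
#' @export
mlm_scan <- function(y, geno, K = NULL, p3d = TRUE, min_obs = 5) {
  stopifnot(inherits(geno, "genotype_matrix"))
  ids <- names(y)
  if (is.null(ids)) {
    stopifnot(length(y) == length(geno$samples))
    ids <- geno$samples
  }
  if (!all(ids %in% geno$samples)) stop("phenotype IDs missing from panel")
  gsub <- subset_genotypes(geno, samples = ids)
  n <- length(y)

  Kmat <- NULL
  mode <- "none (OLS)"
  if (!is.null(K)) {
    if (inherits(K, "kinship_matrix")) {
      if (!is.null(K$groups)) {
        Kmat <- expand_kinship(K)
        mode <- sprintf("compressed (%d groups)", nrow(K$G_compressed))
      } else {
        Kmat <- K$G
        mode <- "full"
      }
    } else {
      Kmat <- as.matrix(K)
      mode <- "full"
    }
    stopifnot(nrow(Kmat) == n)
  }

  raw <- gsub$calls
  n_obs <- colSums(!is.na(raw))
  M <- impute_dosages(gsub)
  mono <- apply(M, 2, stats::sd) < 1e-12
  tested <- n_obs >= min_obs & !mono
  maf <- marker_maf(gsub)

  if (is.null(Kmat)) {
    U <- diag(n); w <- rep(1, n)
    s2g <- 0; s2e <- stats::var(y); delta <- Inf; null_fit <- NULL
  } else {
    null_fit <- emma_reml(y, K = Kmat)
    U <- null_fit$U_full
    w <- 1 / (null_fit$lambda_full + null_fit$delta)
    s2g <- null_fit$sigma2_g; s2e <- null_fit$sigma2_e
    delta <- null_fit$delta
  }

  eff <- se <- pv <- rep(NA_real_, ncol(M))
  if (p3d || is.null(Kmat)) {
    ys <- drop(crossprod(U, y))
    xs0 <- drop(crossprod(U, rep(1, n)))
    Ms <- crossprod(U, M)
    a11 <- sum(w * xs0^2)
    b1 <- sum(w * xs0 * ys)
    a12 <- drop(crossprod(Ms, w * xs0))
    a22 <- colSums(Ms^2 * w)
    b2 <- drop(crossprod(Ms, w * ys))
    det <- a11 * a22 - a12^2
    ok <- tested & det > 1e-12
    beta1 <- (a11 * b2 - a12 * b1) / det
    beta0 <- (b1 - a12 * beta1) / a11
    yy <- sum(w * ys^2)
    # RSS = sum_i w_i (ys_i - b0 xs0_i - b1 xm_i)^2, expanded
    rss <- yy - 2 * (beta0 * b1 + beta1 * b2) +
      beta0^2 * a11 + 2 * beta0 * beta1 * a12 + beta1^2 * a22
    dfres <- n - 2
    s2 <- rss / dfres
    vb <- s2 * a11 / det
    eff[ok] <- beta1[ok]
    se[ok] <- sqrt(vb[ok])
    tstat <- eff / se
    pv[ok] <- 2 * stats::pt(-abs(tstat[ok]), df = dfres)
  } else {
    for (j in which(tested)) {
      X <- cbind(1, M[, j])
      fit <- emma_reml(y, X = X, K = Kmat)
      Uj <- fit$U_full
      wj <- 1 / (fit$lambda_full + fit$delta)
      Xs <- crossprod(Uj, X)
      ysj <- drop(crossprod(Uj, y))
      XtWX <- crossprod(Xs, Xs * wj)
      XtWy <- crossprod(Xs, ysj * wj)
      bh <- solve(XtWX, XtWy)
      r <- ysj - drop(Xs %*% bh)
      s2 <- sum(wj * r^2) / (n - 2)
      vb <- s2 * solve(XtWX)[2, 2]
      eff[j] <- bh[2]
      se[j] <- sqrt(vb)
      pv[j] <- 2 * stats::pt(-abs(bh[2] / sqrt(vb)), df = n - 2)
    }
  }
  tested <- tested & !is.na(pv)
  pv[!is.na(pv)] <- pmin(pmax(pv[!is.na(pv)], .Machine$double.xmin), 1)

  out <- data.frame(
    chrom = gsub$map$chrom, pos = gsub$map$pos, snp_id = gsub$map$id,
    effect = eff, se = se, p = pv, maf = maf, tested = tested,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "sigma2_g") <- s2g
  attr(out, "sigma2_e") <- s2e
  attr(out, "delta") <- delta
  attr(out, "p3d") <- p3d
  attr(out, "kinship_mode") <- mode
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Bonferroni family-wise significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests (>= 1).
#' @return the per-test p-value cut-off `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Genomic inflation factor lambda_GC
#'
#' Median observed association chi-square (from two-sided p-values, 1 df)
#' divided by the median of the chi-square(1) distribution; 1 indicates a
#' well-calibrated null scan.
#'
#' @param p vector of p-values (NAs ignored).
#' @return lambda estimate.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}
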
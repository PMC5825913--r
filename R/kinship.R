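#' VanRaden genomic relationship matrix
#'
#' \eqn{G = W W^T / (2\sum_j p_j(1-p_j))} where W is the 0/1/2 dosage matrix
#' with column j centered by \eqn{2p_j} and \eqn{p_j} is the sample allele
#' frequency of the counted allele. Missing calls are mean-imputed before
#' centering.
#'
#' @param geno a [genotype_matrix()] or plain n x m dosage matrix.
#' @param p optional allele frequencies to center with (e.g. training-set
#'   frequencies when relating new material to a reference panel); defaults
#'   to the sample frequencies of `geno`.
#' @return object of class `kinship_matrix`: list with `G` (n x n),
#'   `denominator`, `p`, and `NULL` compression fields.
#' @export
vanraden_kinship <- function(geno, p = NULL) {
  M <- impute_dosages(geno)
  if (is.null(p)) p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: VanRaden denominator is zero")
  W <- sweep(M, 2, 2 * p)
  G <- tcrossprod(W) / denom
  structure(
    list(G = (G + t(G)) / 2, denominator = denom, p = p,
         groups = NULL, G_compressed = NULL),
    class = "kinship_matrix"
  )
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d x %d (denominator %.4g)%s\n",
              nrow(x$G), ncol(x$G), x$denominator,
              if (is.null(x$groups)) "" else
                sprintf(", compressed to %d groups",
                        nrow(x$G_compressed))))
  invisible(x)
}

#' Compress a kinship matrix to group level
#'
#' Clusters genotypes by average-linkage hierarchical clustering on the
#' kinship-derived distance `max(G) - G` and replaces individual
#' relationships by the mean relationship between (and within) groups - the
#' compressed mixed-model device used to cut the dimension of the random
#' genetic effect.
#'
#' @param kin a `kinship_matrix` (or plain n x n matrix).
#' @param n_groups number of groups, 1..n.
#' @return a `kinship_matrix` carrying `groups` (genotype -> group index) and
#'   `G_compressed` (n_groups x n_groups); `G` is the original matrix.
#' @export
compress_kinship <- function(kin, n_groups) {
  G <- if (inherits(kin, "kinship_matrix")) kin$G else as.matrix(kin)
  n <- nrow(G)
  if (n_groups > n || n_groups < 1) stop("n_groups must be in 1..n")
  if (n_groups == n) {
    grp <- seq_len(n)
  } else {
    d <- stats::as.dist(max(G) - G)
    hc <- stats::hclust(d, method = "average")
    grp <- stats::cutree(hc, k = n_groups)
  }
  Gc <- matrix(0, n_groups, n_groups)
  for (a in seq_len(n_groups)) {
    for (b in a:n_groups) {
      Gc[a, b] <- Gc[b, a] <- mean(G[grp == a, grp == b, drop = FALSE])
    }
  }
  structure(
    list(G = G,
         denominator = if (inherits(kin, "kinship_matrix"))
           kin$denominator else NA_real_,
         p = if (inherits(kin, "kinship_matrix")) kin$p else NULL,
         groups = grp, G_compressed = Gc),
    class = "kinship_matrix"
  )
}

#' Expand a compressed kinship back to individual level
#'
#' Maps the group-level matrix onto individuals (entry i,j = relationship of
#' group(i) with group(j)), the covariance actually used by a compressed
#' mixed-model scan.
#'
#' @param kin a compressed `kinship_matrix`.
#' @return n x n numeric matrix.
#' @export
expand_kinship <- function(kin) {
  stopifnot(inherits(kin, "kinship_matrix"), !is.null(kin$groups))
  kin$G_compressed[kin$groups, kin$groups]
}

#' Pick a compression level by null-model restricted likelihood
#'
#' Fits the null mixed model (intercept + kinship) at each candidate group
#' count and returns the REML log-likelihoods; the scan then uses the best
#' count.
#'
#' @param y phenotype vector aligned with the kinship.
#' @param kin a `kinship_matrix`.
#' @param group_grid candidate group counts (default a small ladder up to n).
#' @return data.frame with columns `n_groups`, `logL`; attribute `best` gives
#'   the argmax count.
#' @export
choose_compression <- function(y, kin, group_grid = NULL) {
  n <- nrow(kin$G)
  if (is.null(group_grid)) {
    group_grid <- unique(pmin(n, c(ceiling(n / 8), ceiling(n / 4),
                                   ceiling(n / 2), n)))
  }
  ll <- vapply(group_grid, function(gk) {
    Ke <- if (gk == n) kin$G else expand_kinship(compress_kinship(kin, gk))
    emma_reml(y, K = Ke)$logL
  }, numeric(1))
  out <- data.frame(n_groups = group_grid, logL = ll)
  attr(out, "best") <- group_grid[which.max(ll)]
  out
}
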
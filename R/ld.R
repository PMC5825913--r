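#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between the dosage vectors of two markers,
#' computed over genotypes with non-missing calls at both markers and, when
#' a read-depth mask is present, calls passing the mask at both markers
#' (the "high confidence" restriction).
#'
#' @param geno a [genotype_matrix()].
#' @param j,k marker indices.
#' @param use_mask honour the depth mask when present (default TRUE).
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(geno, j, k, use_mask = TRUE) {
  x <- geno$calls[, j]
  y <- geno$calls[, k]
  ok <- !is.na(x) & !is.na(y)
  if (use_mask && !is.null(geno$depth_mask)) {
    ok <- ok & geno$depth_mask[, j] & geno$depth_mask[, k]
  }
  if (sum(ok) < 2) stop("fewer than 2 complete observations for the pair")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("marker monomorphic among usable genotypes: r2 undefined")
  }
  stats::cor(x[ok], y[ok])^2
}

#' Hill-Weir expected r-squared under mutation-drift equilibrium
#'
#' The drift-equilibrium expectation of r-squared between two loci separated
#' by population recombination parameter `C`, with the finite-sample
#' adjustment for `n` sampled individuals:
#' \deqn{E[r^2] = \frac{10 + C}{(2 + C)(11 + C)}\left[1 +
#'   \frac{(3 + C)(12 + 12C + C^2)}{n(2 + C)(11 + C)}\right].}
#' At C = 0 and large n this tends to 10/22.
#'
#' @param C population recombination parameter (>= 0), typically `c * d` for
#'   distance d in bp.
#' @param n sample size (number of genotypes); `Inf` drops the adjustment.
#' @return expected r-squared.
#' @export
ld_expected_r2 <- function(C, n = Inf) {
  base <- (10 + C) / ((2 + C) * (11 + C))
  adj <- (3 + C) * (12 + 12 * C + C^2) / ((2 + C) * (11 + C))
  base * (1 + adj / n)   # n = Inf drops the finite-sample term
}

#' Collect intra-chromosomal marker pairs with distance and r-squared
#'
#' @keywords internal
ld_pairs <- function(geno, max_dist, use_mask = TRUE, max_pairs = 200000) {
  M <- geno$calls
  if (use_mask && !is.null(geno$depth_mask)) {
    M[!geno$depth_mask] <- NA
  }
  out_d <- list(); out_r <- list(); k <- 0
  for (ch in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == ch)
    pos <- geno$map$pos[idx]
    Mc <- M[, idx, drop = FALSE]
    mm <- length(idx)
    if (mm < 2) next
    for (a in seq_len(mm - 1)) {
      b <- which(pos > pos[a] & pos - pos[a] <= max_dist)
      b <- b[b > a]
      if (length(b) == 0) next
      xa <- Mc[, a]
      r <- suppressWarnings(
        stats::cor(xa, Mc[, b, drop = FALSE], use = "pairwise.complete.obs")
      )
      k <- k + 1
      out_d[[k]] <- pos[b] - pos[a]
      out_r[[k]] <- drop(r)^2
    }
  }
  d <- unlist(out_d); r2 <- unlist(out_r)
  keep <- is.finite(r2)
  d <- d[keep]; r2 <- r2[keep]
  if (length(d) > max_pairs) {        # deterministic thinning
    pick <- round(seq(1, length(d), length.out = max_pairs))
    d <- d[pick]; r2 <- r2[pick]
  }
  list(d = d, r2 = r2)
}

#' Fit the LD-decay curve and report LD extent
#'
#' Bins intra-chromosomal pairwise r-squared by distance, fits the Hill-Weir
#' drift-equilibrium expectation [ld_expected_r2()] with `C = c * d` by
#' nonlinear least squares for the per-bp recombination coefficient `c`, and
#' reports the LD extent: the smallest distance at which the fitted curve
#' falls to `r2_threshold` (0.2 by convention), by linear interpolation on a
#' fine grid.
#'
#' @param geno a [genotype_matrix()].
#' @param max_dist maximum pair distance in bp.
#' @param n_bins number of equal-width distance bins (default 100); set
#'   `bin = FALSE` to fit raw pairs.
#' @param r2_threshold extent threshold (default 0.2).
#' @param bin fit binned means (default) or raw pairs.
#' @param use_mask honour the depth mask (default TRUE).
#' @return object of class `ld_decay_fit`: list with `c_per_bp`, `n`,
#'   `bins` (data.frame distance/mean r2/pair count), `extent_bp` (`Inf` if
#'   the curve never crosses the threshold), `extent_kb`, `n_pairs`.
#' @export
ld_decay_fit <- function(geno, max_dist = 1e6, n_bins = 100,
                         r2_threshold = 0.2, bin = TRUE, use_mask = TRUE) {
  pr <- ld_pairs(geno, max_dist, use_mask = use_mask)
  if (length(pr$d) < 100) {
    stop("need at least 100 intra-chromosomal pairs within max_dist, got ",
         length(pr$d))
  }
  n <- length(geno$samples)
  br <- seq(0, max_dist, length.out = n_bins + 1)
  bi <- cut(pr$d, breaks = br, include.lowest = TRUE, labels = FALSE)
  bins <- data.frame(
    distance = (br[-1] + br[-length(br)]) / 2,
    r2 = as.numeric(tapply(pr$r2, factor(bi, levels = seq_len(n_bins)), mean)),
    n_pairs = as.integer(table(factor(bi, levels = seq_len(n_bins))))
  )
  fit_df <- if (bin) bins[!is.na(bins$r2), c("distance", "r2")] else
    data.frame(distance = pr$d, r2 = pr$r2)

  start_c <- 1 / max(1, stats::median(fit_df$distance))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r2 ~ ld_expected_r2(cc * distance, n),
      data = cbind(fit_df, n = n),
      start = list(cc = start_c), lower = 0,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("LD-decay fit did not converge: ",
                             conditionMessage(e))
  )
  c_hat <- max(0, stats::coef(fit)[["cc"]])

  grid <- seq(1, max_dist, length.out = 10000)
  fitted_r2 <- ld_expected_r2(c_hat * grid, n)
  below <- which(fitted_r2 < r2_threshold)
  extent <- if (length(below) == 0) Inf else if (below[1] == 1) 0 else {
    i <- below[1]
    grid[i - 1] + (grid[i] - grid[i - 1]) *
      (fitted_r2[i - 1] - r2_threshold) / (fitted_r2[i - 1] - fitted_r2[i])
  }
  structure(
    list(c_per_bp = c_hat, n = n, bins = bins,
         extent_bp = extent, extent_kb = extent / 1000,
         n_pairs = length(pr$d)),
    class = "ld_decay_fit"
  )
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf(
    "ld_decay_fit: c = %.3g /bp over %d pairs; extent(r2=0.2) = %s kb\n",
    x$c_per_bp, x$n_pairs,
    if (is.infinite(x$extent_bp)) "Inf" else sprintf("%.1f", x$extent_kb)))
  invisible(x)
}
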
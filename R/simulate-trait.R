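#' Simulate a multi-environment plot-level trait with known architecture
#'
#' Builds additive genetic values from `n_qtl` causal markers, adds per-site
#' genotype-by-environment deviations, independent row and column spatial
#' effects per site, and a residual whose variance is solved so that the
#' expected plot-level heritability equals `h2_plot`:
#' \deqn{h^2_{plot} = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge} +
#'       2\,\sigma^2_{spatial} + \sigma^2_e).}
#' Genetic variance is standardised to 1. Ordinal traits are produced by
#' quantile-binning the latent Gaussian plot values onto a 1-9 score, the
#' field convention for visually scored traits.
#'
#' @param geno a [genotype_matrix()] (or output list of
#'   [simulate_genotypes()]).
#' @param n_qtl number of causal markers (must be >= 1 when `h2_plot` > 0).
#' @param h2_plot target plot-level heritability in (0, 1).
#' @param n_sites number of environments (field sites).
#' @param n_reps replicates per site (default 3, the usual trial design).
#' @param prop_ge genotype-by-environment variance as a fraction of the
#'   genetic variance (default 0.2).
#' @param spatial_sd standard deviation of the row and of the column random
#'   effects within each site, on the trait scale (default 0.3).
#' @param ordinal map plot values onto a 1-9 ordinal score.
#' @param trait_name label used in the output records.
#' @param layout optional field layout returned by a previous call (in
#'   `truth$layout`); reuse it to measure several traits on the same
#'   physical plots.
#' @param seed integer RNG seed.
#' @return list with `pheno` (long plot-level data.frame: genotype, site,
#'   rep, row, col, trait, value) and `truth` (causal indices and effects,
#'   the variance components used, per-site spatial draws, targets).
#' @export
simulate_trait <- function(geno, n_qtl = 20, h2_plot = 0.5, n_sites = 3,
                           n_reps = 3, prop_ge = 0.2, spatial_sd = 0.3,
                           ordinal = FALSE, trait_name = "trait",
                           layout = NULL, seed = 1) {
  if (is.list(geno) && !inherits(geno, "genotype_matrix") &&
      !is.null(geno$geno)) geno <- geno$geno
  stopifnot(inherits(geno, "genotype_matrix"),
            h2_plot > 0, h2_plot < 1, n_reps >= 1, n_sites >= 1)
  m <- ncol(geno$calls)
  if (n_qtl < 1) stop("n_qtl = 0 cannot produce h2_plot > 0")
  if (n_qtl > m) stop("n_qtl exceeds the number of markers")
  set.seed(seed)

  W <- scale(impute_dosages(geno), center = TRUE, scale = FALSE)
  causal <- sort(sample.int(m, n_qtl))
  beta <- stats::rnorm(n_qtl)
  g <- drop(W[, causal, drop = FALSE] %*% beta)
  sdg <- stats::sd(g)
  if (sdg < 1e-12) stop("causal markers carry no variation; increase n_qtl or MAF")
  beta <- beta / sdg
  g <- g / sdg                          # realized var(g) = 1 on this panel
  sigma2_g <- 1
  sigma2_ge <- prop_ge * sigma2_g
  sigma2_e <- sigma2_g * (1 - h2_plot) / h2_plot -
    sigma2_ge - 2 * spatial_sd^2
  if (sigma2_e < 0) {
    stop("h2_plot = ", h2_plot, " unattainable with prop_ge = ", prop_ge,
         " and spatial_sd = ", spatial_sd, " (residual variance negative)")
  }

  n <- length(geno$samples)
  n_plots <- n * n_reps
  n_row <- ceiling(sqrt(n_plots))
  n_col <- ceiling(n_plots / n_row)
  if (is.null(layout)) {
    layout <- lapply(seq_len(n_sites), function(s) {
      ord <- sample.int(n_plots)        # randomised field layout per site
      data.frame(gi = rep(seq_len(n), times = n_reps)[ord],
                 ri = rep(seq_len(n_reps), each = n)[ord],
                 plot_row = ((seq_len(n_plots) - 1) %/% n_col) + 1,
                 plot_col = ((seq_len(n_plots) - 1) %% n_col) + 1)
    })
  } else {
    stopifnot(length(layout) >= n_sites,
              all(vapply(layout[seq_len(n_sites)], nrow,
                         integer(1)) == n_plots))
  }

  rows_list <- list()
  spatial <- list()
  for (s in seq_len(n_sites)) {
    site_id <- sprintf("site%d", s)
    lay <- layout[[s]]
    gi <- lay$gi; ri <- lay$ri
    plot_row <- lay$plot_row; plot_col <- lay$plot_col
    ge <- stats::rnorm(n, 0, sqrt(sigma2_ge))
    row_eff <- stats::rnorm(max(plot_row), 0, spatial_sd)
    col_eff <- stats::rnorm(max(plot_col), 0, spatial_sd)
    val <- g[gi] + ge[gi] + row_eff[plot_row] + col_eff[plot_col] +
      stats::rnorm(n_plots, 0, sqrt(sigma2_e))
    rows_list[[s]] <- data.frame(
      genotype = geno$samples[gi], site = site_id, rep = ri,
      row = plot_row, col = plot_col, trait = trait_name, value = val,
      stringsAsFactors = FALSE
    )
    spatial[[site_id]] <- list(row = row_eff, col = col_eff, ge = ge)
  }
  pheno <- do.call(rbind, rows_list)

  if (ordinal) {
    br <- stats::quantile(pheno$value, probs = seq(0, 1, length.out = 10),
                          names = FALSE)
    br[1] <- -Inf; br[10] <- Inf
    pheno$value <- as.numeric(cut(pheno$value, breaks = unique(br),
                                  labels = FALSE))
  }

  truth <- list(
    causal = causal, effects = beta,
    sigma2_g = sigma2_g, sigma2_ge = sigma2_ge, sigma2_e = sigma2_e,
    spatial_sd = spatial_sd, h2_plot_target = h2_plot,
    genetic_values = stats::setNames(g, geno$samples),
    spatial = spatial, layout = layout,
    h2_line_mean = sigma2_g /
      (sigma2_g + sigma2_ge / n_sites + sigma2_e / (n_reps * n_sites))
  )
  list(pheno = pheno, truth = truth)
}
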
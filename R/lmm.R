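#' Stage-1 spatial mixed model for one site
#'
#' Fits, for one trait at one field site, the plot-level linear mixed model
#' with genotype as a fixed effect and independent Gaussian random row and
#' column intercepts (the spatial adjustment), by REML via \pkg{lme4}. The
#' genotype BLUEs are the estimated genotype means under this model. Random
#' terms whose factor has fewer than two observed levels are dropped.
#'
#' @param pheno long phenotype data.frame (columns genotype, site, rep, row,
#'   col, trait, value).
#' @param site site ID to analyse.
#' @param trait trait name to analyse.
#' @return object of class `lmm_fit` with elements `blues` (data.frame
#'   genotype/blue/se), `beta`, `vcov_beta`, `varcomp` (named vector of
#'   variance components incl. residual), `logLik_reml`, `n_obs`, `terms`.
#' @export
fit_site_lmm <- function(pheno, site, trait) {
  d <- pheno[pheno$site == site & pheno$trait == trait & !is.na(pheno$value), ]
  if (nrow(d) < 2 || length(unique(d$genotype)) < 2) {
    stop("need at least 2 genotypes with observations at site ", site)
  }
  d$genotype <- factor(d$genotype)
  d$row_f <- factor(d$row)
  d$col_f <- factor(d$col)
  rand <- c(
    if (nlevels(droplevels(d$row_f)) > 1) "(1 | row_f)",
    if (nlevels(droplevels(d$col_f)) > 1) "(1 | col_f)"
  )
  fit_lmm_fixed_genotype(d, rand, extra_terms = NULL)
}

# shared core: genotype fixed (cell-mean coding) + random terms by REML
fit_lmm_fixed_genotype <- function(d, rand, extra_terms = NULL) {
  rhs <- paste(c("0 + genotype", rand, extra_terms), collapse = " + ")
  form <- stats::as.formula(paste("value ~", rhs))
  if (length(c(rand, extra_terms)) == 0) {
    lmf <- stats::lm(form, data = d)
    beta <- stats::coef(lmf)
    V <- stats::vcov(lmf)
    vc <- c(residual = summary(lmf)$sigma^2)
    ll <- as.numeric(stats::logLik(lmf, REML = TRUE))
  } else {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore",
                                             calc.derivs = FALSE))
    ))
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    vcdf <- as.data.frame(lme4::VarCorr(fit))
    vc <- stats::setNames(vcdf$vcov, ifelse(is.na(vcdf$grp) |
                                              vcdf$grp == "Residual",
                                            "residual", vcdf$grp))
    ll <- as.numeric(stats::logLik(fit))
  }
  gnames <- sub("^genotype", "", names(beta))
  blues <- data.frame(genotype = gnames, blue = as.numeric(beta),
                      se = sqrt(pmax(diag(V), 0)), stringsAsFactors = FALSE)
  rownames(blues) <- NULL
  structure(
    list(blues = blues, beta = beta, vcov_beta = V, varcomp = vc,
         logLik_reml = ll, n_obs = nrow(d),
         terms = c("genotype (fixed)", rand, extra_terms)),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("lmm_fit:", paste(x$terms, collapse = " + "),
      sprintf("| n = %d, REML logLik = %.2f\n", x$n_obs, x$logLik_reml))
  invisible(x)
}

#' Stage-2 multi-environment mixed model
#'
#' Combines per-site data (stage-1 BLUEs or spatially simple plot records)
#' across environments. Two parameterisations serve two purposes:
#' `genotype_fixed` keeps genotype fixed (random environment and, when the
#' data carry replication within genotype-by-environment cells, a random
#' interaction) and returns the combined cross-environment BLUEs;
#' `genotype_random` makes genotype random and returns the REML variance
#' components \eqn{(\sigma^2_g, \sigma^2_{ge}, \sigma^2_e)} for
#' heritability. Separating \eqn{\sigma^2_{ge}} from \eqn{\sigma^2_e}
#' requires replication within cells, so `genotype_random` refuses data with
#' one record per (genotype, environment).
#'
#' @param data data.frame with columns `genotype`, `env`, `value` (an
#'   optional `rep` column is ignored by the model but allowed).
#' @param mode `"genotype_fixed"` or `"genotype_random"`.
#' @return An `lmm_fit` (genotype_fixed) or a `variance_components` object
#'   (genotype_random): list with `sigma2_g`, `sigma2_ge`, `sigma2_e`, `t`
#'   (environments), `r` (harmonic-mean replication), `logLik_reml`.
#' @export
fit_multienv_lmm <- function(data,
                             mode = c("genotype_fixed", "genotype_random")) {
  mode <- match.arg(mode)
  d <- data[!is.na(data$value), ]
  d$genotype <- factor(d$genotype)
  d$env <- factor(d$env)
  t_env <- nlevels(droplevels(d$env))
  if (t_env < 2) {
    if (mode == "genotype_random") {
      stop("one environment: sigma2_ge is unidentifiable")
    }
  }
  cell_n <- table(d$genotype, d$env)
  replicated <- max(cell_n) > 1

  if (mode == "genotype_fixed") {
    rand <- c(
      if (t_env > 1) "(1 | env)",
      if (replicated && t_env > 1) "(1 | genotype:env)"
    )
    return(fit_lmm_fixed_genotype(d, rand))
  }

  if (!replicated) {
    stop("genotype_random mode needs replication within genotype x ",
         "environment cells to separate sigma2_ge from sigma2_e")
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ 1 + (1 | genotype) + (1 | env) + (1 | genotype:env),
               data = d, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE))
  ))
  vcdf <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g) {
    v <- vcdf$vcov[vcdf$grp == g]
    if (length(v) == 0) 0 else v
  }
  r_cells <- as.vector(cell_n[cell_n > 0])
  structure(
    list(sigma2_g = get_vc("genotype"),
         sigma2_ge = get_vc("genotype:env"),
         sigma2_e = get_vc("Residual"),
         t = t_env,
         r = length(r_cells) / sum(1 / r_cells),  # harmonic mean
         logLik_reml = as.numeric(stats::logLik(fit))),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance_components: g = %.4g, gxe = %.4g, e = %.4g (t = %d, r = %.2f)\n",
    x$sigma2_g, x$sigma2_ge, x$sigma2_e, x$t, x$r))
  invisible(x)
}

#' Wald chi-square test for the genotype fixed effect
#'
#' Tests equality of all genotype means in a genotype-fixed `lmm_fit` by the
#' Wald statistic on the contrast block (differences from the first
#' genotype), \eqn{W = (L\hat\beta)^T (L V L^T)^{-1} L\hat\beta}, referred
#' to the upper tail of \eqn{\chi^2} with (number of genotypes - 1) degrees
#' of freedom.
#'
#' @param fit an `lmm_fit` from [fit_site_lmm()] or genotype-fixed
#'   [fit_multienv_lmm()].
#' @return list with `statistic`, `df`, `p`.
#' @export
wald_test_genotype <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  g_idx <- grep("^genotype", names(fit$beta))
  ng <- length(g_idx)
  if (ng < 2) stop("fit has fewer than 2 genotype levels")
  L <- cbind(-1, diag(ng - 1))
  b <- fit$beta[g_idx]
  V <- fit$vcov_beta[g_idx, g_idx, drop = FALSE]
  Lb <- drop(L %*% b)
  LVL <- L %*% V %*% t(L)
  W <- tryCatch(drop(crossprod(Lb, solve(LVL, Lb))),
                error = function(e) stop("contrast covariance not invertible"))
  list(statistic = W, df = ng - 1,
       p = stats::pchisq(W, df = ng - 1, lower.tail = FALSE))
}

#' Likelihood-ratio test for one variance component
#'
#' Compares two REML fits where the reduced model drops one random term from
#' the full model (same fixed effects). Because the null puts the variance
#' on the boundary of its parameter space, the statistic
#' \eqn{2\Delta \log L_R} is referred to the mixture
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1}.
#'
#' @param fit_full,fit_reduced `lmm_fit` / `variance_components` objects (or
#'   anything with `logLik_reml`).
#' @param tol tolerance for a negative statistic before declaring optimizer
#'   failure (default 1e-4; boundary fits carry optimizer noise of this
#'   order).
#' @return list with `statistic`, `p`.
#' @export
lrt_random_term <- function(fit_full, fit_reduced, tol = 1e-4) {
  llf <- fit_full$logLik_reml
  llr <- fit_reduced$logLik_reml
  stat <- 2 * (llf - llr)
  if (stat < -tol) {
    stop("full-model REML logLik below reduced model (", llf, " < ", llr,
         "): optimizer failure")
  }
  stat <- max(stat, 0)
  p <- if (stat <= tol) 1 else
    0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p = p)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/t + \sigma^2_e/(rt))}
#' for t environments and r replicates per environment (harmonic mean under
#' imbalance).
#'
#' @param vc a `variance_components` object, or a list with fields
#'   `sigma2_g`, `sigma2_ge`, `sigma2_e`, `t`, `r`.
#' @return heritability in `[0, 1]`.
#' @export
broad_sense_h2 <- function(vc) {
  s <- vc$sigma2_g + vc$sigma2_ge / vc$t + vc$sigma2_e / (vc$r * vc$t)
  if (s <= 0) stop("all variance components are zero: h2 undefined")
  vc$sigma2_g / s
}

#' Pairwise trait correlations with significance stars
#'
#' Pearson correlations between trait BLUEs over genotypes, pairwise
#' complete, with two-sided t-test p-values and the conventional star codes
#' (* 0.05, ** 0.01, *** 0.001). Traits with zero variance give missing
#' entries.
#'
#' @param blues genotype x trait numeric matrix (rownames = genotypes).
#' @return list with matrices `r`, `p`, `stars`, `n`.
#' @export
trait_correlations <- function(blues) {
  blues <- as.matrix(blues)
  k <- ncol(blues)
  r <- p <- n <- matrix(NA_real_, k, k,
                        dimnames = list(colnames(blues), colnames(blues)))
  for (a in seq_len(k)) {
    for (b in a:k) {
      ok <- stats::complete.cases(blues[, c(a, b)])
      n[a, b] <- n[b, a] <- sum(ok)
      if (a == b) {
        if (stats::sd(blues[ok, a]) > 0) { r[a, a] <- 1; p[a, a] <- 0 }
        next
      }
      if (sum(ok) < 3 || stats::sd(blues[ok, a]) == 0 ||
          stats::sd(blues[ok, b]) == 0) next
      ct <- stats::cor.test(blues[ok, a], blues[ok, b])
      r[a, b] <- r[b, a] <- unname(ct$estimate)
      p[a, b] <- p[b, a] <- ct$p.value
    }
  }
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  diag(stars) <- ""
  list(r = r, p = p, stars = stars, n = n)
}
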
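#' Select pseudo-QTNs from an initial scan
#'
#' The settlement step of the SUPER association method: divide the genome
#' into `n_bins` equal-bp bins, take the smallest-p tested marker of each
#' bin as a candidate, then add candidates in increasing-p order (ties by
#' position) for as long as the null-model restricted likelihood of the
#' phenotype under a kinship built from the selected markers keeps
#' improving. The selected markers act as surrogate causal loci whose
#' relationship matrix replaces the genome-wide kinship.
#'
#' @param scan an `assoc_result` from [mlm_scan()] covering all markers.
#' @param geno the [genotype_matrix()] the scan was run on.
#' @param y the phenotype vector used for the scan (names = genotype IDs).
#' @param n_bins number of equal-bp genome bins (default 100).
#' @param n_qtn_max cap on the number of pseudo-QTNs (default 20).
#' @return list of class `pseudo_qtn_set`: `indices` (marker column indices,
#'   sorted by genome position), `snp_id`, `n_bins`, `bin_of_candidate`,
#'   `logL` (null REML logL with the final kinship).
#' @export
select_pseudo_qtns <- function(scan, geno, y, n_bins = 100, n_qtn_max = 20) {
  stopifnot(nrow(scan) == ncol(geno$calls))
  ids <- names(y)
  gsub <- if (is.null(ids)) geno else subset_genotypes(geno, samples = ids)

  # global bp coordinate: chromosomes laid end to end
  chrs <- unique(scan$chrom)
  offs <- c(0, cumsum(vapply(chrs, function(ch)
    max(scan$pos[scan$chrom == ch]), numeric(1))))
  gpos <- scan$pos + offs[match(scan$chrom, chrs)]
  bin <- cut(gpos, breaks = seq(0, max(gpos), length.out = n_bins + 1),
             include.lowest = TRUE, labels = FALSE)

  cand <- integer(0)
  for (b in sort(unique(bin))) {
    in_bin <- which(bin == b & scan$tested)
    if (length(in_bin) == 0) next
    o <- in_bin[order(scan$p[in_bin], scan$pos[in_bin])]
    cand <- c(cand, o[1])
  }
  if (length(cand) == 0) stop("no tested candidate markers in any bin")
  cand <- cand[order(scan$p[cand], gpos[cand])]
  cand <- cand[seq_len(min(length(cand), n_qtn_max))]

  M <- impute_dosages(gsub)
  sel <- cand[1]
  ll <- emma_reml(y, K = vanraden_kinship(M[, sel, drop = FALSE])$G)$logL
  for (cd in cand[-1]) {
    trial <- c(sel, cd)
    ll2 <- tryCatch(
      emma_reml(y, K = vanraden_kinship(M[, trial, drop = FALSE])$G)$logL,
      error = function(e) -Inf
    )
    if (ll2 > ll + 1e-8) {
      sel <- trial
      ll <- ll2
    } else break
  }
  sel <- sel[order(gpos[sel])]
  structure(
    list(indices = sel, snp_id = scan$snp_id[sel], n_bins = n_bins,
         n_candidates = length(cand), logL = ll),
    class = "pseudo_qtn_set"
  )
}

#' @export
print.pseudo_qtn_set <- function(x, ...) {
  cat(sprintf("pseudo_qtn_set: %d markers from %d bins (logL %.2f)\n",
              length(x$indices), x$n_bins, x$logL))
  invisible(x)
}

#' SUPER association scan with marker-specific pseudo-QTN kinship
#'
#' For each test marker, the genetic covariance is a VanRaden relationship
#' matrix built from the pseudo-QTNs that are *not* in LD with the marker
#' under test (r-squared at most `ld_exclude_r2`; the marker itself, at
#' r-squared 1, is always excluded). Variance components are re-estimated
#' under the null for each distinct kinship, and the marker is tested by the
#' same rotated GLS as [mlm_scan()]. When every pseudo-QTN is excluded the
#' scan falls back to an identity kinship for that marker (reported in a
#' message).
#'
#' @param y named phenotype vector.
#' @param geno a [genotype_matrix()].
#' @param pseudo_qtns a `pseudo_qtn_set` or integer vector of marker
#'   indices.
#' @param ld_exclude_r2 LD exclusion threshold in (0, 1], default 0.1 (the
#'   standard SUPER setting).
#' @param min_obs minimum non-missing calls per tested marker.
#' @return an `assoc_result` data.frame (see [mlm_scan()]).
#' @export
super_scan <- function(y, geno, pseudo_qtns, ld_exclude_r2 = 0.1,
                       min_obs = 5) {
  stopifnot(ld_exclude_r2 > 0, ld_exclude_r2 <= 1)
  qtn <- if (inherits(pseudo_qtns, "pseudo_qtn_set")) pseudo_qtns$indices
         else as.integer(pseudo_qtns)
  if (length(qtn) == 0) stop("pseudo-QTN set is empty")
  ids <- names(y)
  gsub <- if (is.null(ids)) geno else subset_genotypes(geno, samples = ids)
  n <- length(y)
  M <- impute_dosages(gsub)
  m <- ncol(M)
  n_obs <- colSums(!is.na(gsub$calls))
  mono <- apply(M, 2, stats::sd) < 1e-12
  tested <- n_obs >= min_obs & !mono
  maf <- marker_maf(gsub)

  # r2 between every marker and every pseudo-QTN
  r2 <- suppressWarnings(stats::cor(M, M[, qtn, drop = FALSE]))^2
  r2[!is.finite(r2)] <- 0
  include <- r2 <= ld_exclude_r2            # m x |qtn|

  key <- apply(include, 1, function(z) paste(which(z), collapse = ","))
  eff <- se <- pv <- rep(NA_real_, m)
  n_fallback <- 0
  for (k in unique(key[tested])) {
    members <- which(key == k & tested)
    inc <- which(include[members[1], ])
    if (length(inc) == 0) {
      n_fallback <- n_fallback + length(members)
      Kk <- diag(n)
    } else {
      Kk <- vanraden_kinship(M[, qtn[inc], drop = FALSE])$G
    }
    nf <- emma_reml(y, K = Kk)
    U <- nf$U_full
    w <- 1 / (nf$lambda_full + nf$delta)
    ys <- drop(crossprod(U, y))
    xs0 <- drop(crossprod(U, rep(1, n)))
    Ms <- crossprod(U, M[, members, drop = FALSE])
    a11 <- sum(w * xs0^2)
    b1 <- sum(w * xs0 * ys)
    a12 <- drop(crossprod(Ms, w * xs0))
    a22 <- colSums(Ms^2 * w)
    b2 <- drop(crossprod(Ms, w * ys))
    det <- a11 * a22 - a12^2
    beta1 <- (a11 * b2 - a12 * b1) / det
    beta0 <- (b1 - a12 * beta1) / a11
    yy <- sum(w * ys^2)
    rss <- yy - 2 * (beta0 * b1 + beta1 * b2) +
      beta0^2 * a11 + 2 * beta0 * beta1 * a12 + beta1^2 * a22
    s2 <- rss / (n - 2)
    vb <- s2 * a11 / det
    good <- det > 1e-12
    eff[members[good]] <- beta1[good]
    se[members[good]] <- sqrt(vb[good])
    pv[members[good]] <- 2 * stats::pt(-abs(beta1[good] / sqrt(vb[good])),
                                       df = n - 2)
  }
  if (n_fallback > 0) {
    message("super_scan: ", n_fallback,
            " marker(s) fell back to identity kinship (all pseudo-QTNs in LD)")
  }
  tested <- tested & !is.na(pv)

  out <- data.frame(
    chrom = gsub$map$chrom, pos = gsub$map$pos, snp_id = gsub$map$id,
    effect = eff, se = se, p = pv, maf = maf, tested = tested,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "p3d") <- TRUE
  attr(out, "kinship_mode") <-
    sprintf("SUPER (%d pseudo-QTNs, LD exclusion r2 <= %g)",
            length(qtn), ld_exclude_r2)
  class(out) <- c("assoc_result", "data.frame")
  out
}
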
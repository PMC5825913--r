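#' Simulate an admixed inbred genotype panel with LD
#'
#' Generates a diploid 0/1/2 dosage panel that mimics a resequenced crop
#' diversity panel: K ancestral populations with Balding-Nichols allele-
#' frequency divergence, individual ancestry drawn from a Dirichlet, and
#' intra-chromosomal linkage disequilibrium produced by first-order Markov
#' haplotype copying so that expected r-squared decays with physical distance
#' at a tunable rate. Lines are selfed to (near-)homozygosity by default,
#' matching an inbred chickpea-style panel.
#'
#' The copying mechanism: walking along a chromosome, the allele at the next
#' marker equals the previous allele with probability `exp(-rho_ld * d)`
#' (d = inter-marker distance in bp), otherwise it is redrawn from the
#' individual's admixture-weighted population frequency. Large `rho_ld`
#' means fast decay (less LD).
#'
#' @param n number of genotypes (>= 2).
#' @param m number of markers (>= 2).
#' @param K number of ancestral populations.
#' @param alpha_admix Dirichlet concentration for ancestry proportions; a
#'   scalar or length-K vector. Small values give near-pure assignments.
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param rho_ld copying decay rate per bp (> 0); `Inf` gives independent
#'   markers.
#' @param maf_range length-2 vector inside (0, 0.5]; base allele frequencies
#'   are drawn uniformly from this range (randomly assigned to either allele).
#' @param fst divergence of population frequencies around the base frequency
#'   (Balding-Nichols F), default 0.15.
#' @param het_rate probability a genotype call is made heterozygous, default
#'   0 (fully inbred).
#' @param seed integer RNG seed; all output is reproducible given the seed.
#' @return list with `geno` (a [genotype_matrix()]), `Q_true` (n x K ancestry
#'   fractions) and `P` (m x K population allele frequencies).
#' @export
simulate_genotypes <- function(n, m, K = 2, alpha_admix = 0.2,
                               chrom_lengths = c(chr1 = 50e6, chr2 = 50e6),
                               rho_ld = 5e-6,
                               maf_range = c(0.1, 0.5),
                               fst = 0.15, het_rate = 0, seed = 1) {
  stopifnot(n >= 2, m >= 2, K >= 1, rho_ld > 0)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  set.seed(seed)
  if (length(alpha_admix) == 1) alpha_admix <- rep(alpha_admix, K)

  # marker map: markers spread over chromosomes proportionally to length
  n_chr <- length(chrom_lengths)
  chr_names <- names(chrom_lengths)
  if (is.null(chr_names)) chr_names <- paste0("chr", seq_len(n_chr))
  m_per <- pmax(1L, round(m * chrom_lengths / sum(chrom_lengths)))
  while (sum(m_per) != m) {            # fix rounding drift
    i <- which.max(m_per)
    m_per[i] <- m_per[i] + (m - sum(m_per))
  }
  map <- do.call(rbind, lapply(seq_len(n_chr), function(ci) {
    pos <- sort(sample.int(chrom_lengths[ci], m_per[ci]))
    data.frame(chrom = chr_names[ci], pos = pos,
               id = paste0(chr_names[ci], "_", pos),
               ref = "A", alt = "T", stringsAsFactors = FALSE)
  }))
  rownames(map) <- NULL

  # base frequencies, then Balding-Nichols divergence between populations
  p0 <- stats::runif(m, maf_range[1], maf_range[2])
  flip <- stats::runif(m) < 0.5
  p0[flip] <- 1 - p0[flip]
  if (K == 1 || fst <= 0) {
    P <- matrix(p0, m, K)
  } else {
    a <- p0 * (1 - fst) / fst
    b <- (1 - p0) * (1 - fst) / fst
    P <- matrix(stats::rbeta(m * K, rep(a, K), rep(b, K)), m, K)
  }
  P <- pmin(pmax(P, 1e-4), 1 - 1e-4)

  Q <- if (K == 1) matrix(1, n, 1) else {
    g <- matrix(stats::rgamma(n * K, shape = rep(alpha_admix, each = n)), n, K)
    zero <- rowSums(g) == 0            # tiny alpha can underflow all draws
    if (any(zero)) g[cbind(which(zero), sample.int(K, sum(zero),
                                                   replace = TRUE))] <- 1
    g / rowSums(g)
  }

  # individual-specific expected frequency, then Markov copying along chrom
  Fi <- Q %*% t(P)                      # n x m
  copy_p <- exp(-rho_ld * unlist(lapply(split(map$pos, map$chrom)[unique(map$chrom)],
                                        function(p) c(NA, diff(p)))))
  copy_p[is.na(copy_p)] <- 0            # chromosome starts: always redraw
  hap <- matrix(0L, n, m)
  prev <- stats::rbinom(n, 1, Fi[, 1])
  hap[, 1] <- prev
  if (m > 1) {
    for (j in 2:m) {
      keep <- stats::runif(n) < copy_p[j]
      redraw <- stats::rbinom(n, 1, Fi[, j])
      prev <- ifelse(keep, prev, redraw)
      hap[, j] <- prev
    }
  }
  dose <- 2L * hap                      # selfed: homozygous at every locus
  if (het_rate > 0) {
    h <- matrix(stats::runif(n * m) < het_rate, n, m)
    dose[h] <- 1L
  }
  rownames(dose) <- sprintf("G%03d", seq_len(n))
  list(
    geno = genotype_matrix(dose, map, samples = rownames(dose)),
    Q_true = Q,
    P = P
  )
}
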
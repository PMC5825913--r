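#' Genes flanking a SNP
#'
#' Reports the nearest annotated gene ending before the SNP and the nearest
#' gene starting after it; a gene containing the position is additionally
#' returned, flagged. Either side may be absent (`NULL`).
#'
#' @param chrom,pos SNP coordinate (1-based).
#' @param genes gene table from [read_gff()] (sorted by chrom, start).
#' @return list with `left`, `right`, `containing` (each a one-row
#'   data.frame with a `distance` column, or `NULL`).
#' @export
flanking_genes <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) stop("chromosome ", chrom, " absent from annotation")
  pick <- function(df, dist) {
    if (nrow(df) == 0) return(NULL)
    out <- df[1, , drop = FALSE]
    out$distance <- dist
    rownames(out) <- NULL
    out
  }
  left_cand <- g[g$end < pos, , drop = FALSE]
  left <- if (nrow(left_cand) == 0) NULL else {
    i <- which.max(left_cand$end)
    pick(left_cand[i, , drop = FALSE], pos - left_cand$end[i])
  }
  right_cand <- g[g$start > pos, , drop = FALSE]
  right <- if (nrow(right_cand) == 0) NULL else {
    i <- which.min(right_cand$start)
    pick(right_cand[i, , drop = FALSE], right_cand$start[i] - pos)
  }
  cont_cand <- g[g$start <= pos & g$end >= pos, , drop = FALSE]
  containing <- if (nrow(cont_cand) == 0) NULL else
    pick(cont_cand[1, , drop = FALSE], 0)
  list(left = left, right = right, containing = containing)
}

#' Pool significant SNPs across traits into genomic regions
#'
#' Single-linkage merging of significant SNPs (from any trait) that lie
#' within `merge_dist_bp` of each other on the same chromosome. Each region
#' spans the min..max member position; regions whose members come from two
#' or more distinct traits are flagged pleiotropic.
#'
#' @param snps data.frame with columns `chrom`, `pos`, `trait` (and
#'   optionally `p`, `snp_id`).
#' @param merge_dist_bp linkage distance in bp (default 1e6).
#' @return data.frame with one row per region: chrom, start, end, width_bp,
#'   n_snps, n_traits, traits (comma-joined), pleiotropic.
#' @export
pleiotropic_regions <- function(snps, merge_dist_bp = 1e6) {
  if (nrow(snps) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), width_bp = integer(),
                      n_snps = integer(), n_traits = integer(),
                      traits = character(), pleiotropic = logical()))
  }
  out <- list()
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(s$pos) > merge_dist_bp))
    for (gidx in unique(grp)) {
      mem <- s[grp == gidx, , drop = FALSE]
      traits <- sort(unique(mem$trait))
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(mem$pos), end = max(mem$pos),
        width_bp = max(mem$pos) - min(mem$pos),
        n_snps = nrow(mem), n_traits = length(traits),
        traits = paste(traits, collapse = ","),
        pleiotropic = length(traits) >= 2,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Significant SNPs from a scan
#'
#' @param scan an `assoc_result`.
#' @param threshold p-value cut-off (e.g. [bonferroni_threshold()]).
#' @param trait optional trait label to attach.
#' @return subset of the scan rows with `trait` column added.
#' @export
significant_snps <- function(scan, threshold, trait = NA_character_) {
  hits <- scan[scan$tested & !is.na(scan$p) & scan$p < threshold, ,
               drop = FALSE]
  hits$trait <- rep(trait, nrow(hits))
  rownames(hits) <- NULL
  hits
}
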
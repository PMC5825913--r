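#' Genotype matrix container
#'
#' Bundles an n x m matrix of biallelic SNP dosages (minor-allele counts coded
#' 0/1/2, `NA` for missing) with its marker map and, optionally, a read-depth
#' confidence mask. Inbred panels are expected to be almost entirely 0/2;
#' heterozygous calls are kept and coded 1.
#'
#' @param calls integer/numeric n x m matrix with values in \{0, 1, 2, NA\}.
#'   Row names, if present, are used as sample IDs.
#' @param map data.frame with one row per marker: columns `chrom`, `pos`
#'   (1-based bp), `id`, `ref`, `alt`. Positions must be strictly increasing
#'   within a chromosome.
#' @param samples character vector of sample IDs (defaults to rownames).
#' @param depth_mask optional n x m logical matrix, `TRUE` where the call is
#'   supported by at least the depth threshold used at read time. `NULL` means
#'   no depth information (all calls trusted).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, map, samples = NULL, depth_mask = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(samples)) {
    samples <- rownames(calls)
    if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  }
  stopifnot(length(samples) == nrow(calls), nrow(map) == ncol(calls))
  req <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(req, names(map))
  if (length(missing_cols) > 0) {
    stop("marker map lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  map <- as.data.frame(map)[, req]
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  bad <- calls[!is.na(calls) & !(calls %in% c(0, 1, 2))]
  if (length(bad) > 0) stop("calls must be 0, 1, 2 or NA")
  if (any(map$pos < 1L)) stop("positions must be >= 1")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on ", ch)
  }
  if (!is.null(depth_mask)) {
    depth_mask <- as.matrix(depth_mask)
    stopifnot(identical(dim(depth_mask), dim(calls)), is.logical(depth_mask))
  }
  rownames(calls) <- samples
  colnames(calls) <- map$id
  structure(
    list(samples = as.character(samples), map = map,
         calls = calls, depth_mask = depth_mask),
    class = "genotype_matrix"
  )
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x$calls)
  het <- mean(x$calls == 1, na.rm = TRUE)
  miss <- mean(is.na(x$calls))
  cat(sprintf(
    "genotype_matrix: %d samples x %d markers on %d chromosome(s)\n",
    d[1], d[2], length(unique(x$map$chrom))
  ))
  cat(sprintf("  heterozygosity %.4f, missingness %.4f, depth mask: %s\n",
              het, miss, if (is.null(x$depth_mask)) "none" else "present"))
  invisible(x)
}

#' @export
as.matrix.genotype_matrix <- function(x, ...) x$calls

#' Minor-allele frequency per marker
#'
#' Allele frequency of the counted (alt) allele per marker, folded to the
#' minor side. Computed over non-missing calls only.
#'
#' @param geno a `genotype_matrix` or plain dosage matrix.
#' @param fold fold frequencies above 0.5 to `1 - p` (default `TRUE`).
#' @return numeric vector of length m.
#' @export
marker_maf <- function(geno, fold = TRUE) {
  calls <- if (inherits(geno, "genotype_matrix")) geno$calls else as.matrix(geno)
  p <- colMeans(calls, na.rm = TRUE) / 2
  if (fold) p <- pmin(p, 1 - p)
  p
}

#' Mean-impute missing dosages
#'
#' Replaces `NA` calls by the marker mean dosage (the standard pre-processing
#' for relationship matrices and regression scans). Monomorphic all-missing
#' columns become 0.
#'
#' @param geno a `genotype_matrix` or dosage matrix.
#' @return numeric dosage matrix without missing values.
#' @export
impute_dosages <- function(geno) {
  m <- if (inherits(geno, "genotype_matrix")) geno$calls else as.matrix(geno)
  m <- apply(m, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  m[is.na(m)] <- 0
  m
}

#' Subset a genotype matrix
#'
#' @param geno a `genotype_matrix`.
#' @param samples sample index or ID vector (`NULL` keeps all).
#' @param markers marker index vector (`NULL` keeps all).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(geno, samples = NULL, markers = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(geno$samples) else samples
  if (is.character(si)) si <- match(si, geno$samples)
  mi <- if (is.null(markers)) seq_len(nrow(geno$map)) else markers
  genotype_matrix(
    geno$calls[si, mi, drop = FALSE],
    geno$map[mi, , drop = FALSE],
    samples = geno$samples[si],
    depth_mask = if (is.null(geno$depth_mask)) NULL else
      geno$depth_mask[si, mi, drop = FALSE]
  )
}

#' Filter markers by minor-allele frequency
#'
#' Keeps markers with sample-estimated MAF strictly greater than `maf_min`,
#' the usual pre-GWAS filter. Idempotent: filtering twice equals filtering
#' once.
#'
#' @param geno a `genotype_matrix`.
#' @param maf_min threshold in `[0, 0.5)`.
#' @return filtered `genotype_matrix`.
#' @export
filter_maf <- function(geno, maf_min = 0.05) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  keep <- which(marker_maf(geno) > maf_min)
  if (length(keep) == 0) stop("no markers survive the MAF filter")
  subset_genotypes(geno, markers = keep)
}
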
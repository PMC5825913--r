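#' Read biallelic SNPs from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeps biallelic SNP records, codes
#' genotypes as alt-allele dosages 0/1/2 (`NA` for missing) and applies a
#' minor-allele-frequency filter. When the FORMAT field carries per-genotype
#' read depth (`DP`), a confidence mask marks calls supported by at least
#' `depth_min` reads; downstream LD computations can restrict themselves to
#' masked-in calls.
#'
#' @param path VCF file (plain text or gzipped).
#' @param maf_min keep markers with sample MAF strictly above this (default
#'   0.05, the conventional GWAS panel filter). Must lie in `[0, 0.5)`.
#' @param depth_min minimum per-genotype read depth for a call to count as
#'   high-confidence (default 5). Ignored when the VCF has no DP field.
#' @return a [genotype_matrix()] with `depth_mask` set if DP was present.
#' @export
read_vcf <- function(path, maf_min = 0.05, depth_min = 5) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1 & nchar(alt) == 1
  if (!any(biallelic)) stop("no biallelic SNP records in '", path, "'")

  gt <- vcfR::extract.gt(vcf, element = "GT")[biallelic, , drop = FALSE]
  dose <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt))
  gt_clean <- gsub("\\|", "/", gt)
  dose_of <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
               "0" = 0, "1" = 2)  # haploid-style calls doubled
  dose <- t(matrix(dose_of[gt_clean], nrow = nrow(gt)))
  n_het <- sum(dose == 1, na.rm = TRUE)
  if (n_het > 0) {
    message(sprintf("read_vcf: %d heterozygous calls retained (coded 1), rate %.4g",
                    n_het, n_het / sum(!is.na(dose))))
  }

  map <- data.frame(
    chrom = as.character(fix[biallelic, "CHROM"]),
    pos = as.integer(fix[biallelic, "POS"]),
    id = as.character(fix[biallelic, "ID"]),
    ref = ref[biallelic], alt = alt[biallelic],
    stringsAsFactors = FALSE
  )
  no_id <- is.na(map$id) | map$id == "."
  map$id[no_id] <- paste0(map$chrom[no_id], "_", map$pos[no_id])

  mask <- NULL
  if ("DP" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID ||
      grepl("DP", vcf@gt[1, "FORMAT"])) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    )[biallelic, , drop = FALSE]
    mask <- t(!is.na(dp) & dp >= depth_min)
  }

  geno <- genotype_matrix(dose, map, samples = colnames(gt),
                          depth_mask = mask)
  keep <- which(marker_maf(geno) > maf_min)
  if (length(keep) == 0) {
    stop("no markers pass MAF > ", maf_min, " in '", path, "'")
  }
  subset_genotypes(geno, markers = keep)
}

#' Write a genotype matrix as a VCF file
#'
#' Emits a minimal plain-text VCF 4.2 file with GT (and DP-free) genotype
#' columns, suitable for round-tripping simulated panels through [read_vcf()].
#'
#' @param geno a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  gt_of <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(geno$map)), function(j) {
    d <- geno$calls[, j]
    gt <- ifelse(is.na(d), "./.", gt_of[d + 1])
    paste(c(geno$map$chrom[j], geno$map$pos[j], geno$map$id[j],
            geno$map$ref[j], geno$map$alt[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=supergs",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}
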
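#' Read a plot-level phenotype table
#'
#' Reads a delimited file with one row per field plot and columns
#' `genotype, site, rep, row, col` followed by one column per trait, and
#' returns the long-format phenotype table used throughout the pipeline.
#' Non-numeric trait cells (including blanks) become missing values and are
#' counted in a message.
#'
#' @param path CSV/TSV file (delimiter sniffed from the header line).
#' @param ordinal_traits character vector of trait names measured on a 1-9
#'   ordinal scale (scored traits); recorded in the `ordinal` attribute.
#' @return data.frame with columns `genotype, site, rep, row, col, trait,
#'   value` and attribute `ordinal` naming the ordinal traits.
#' @export
read_phenotypes <- function(path, ordinal_traits = character()) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  wide <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character")
  key_cols <- c("genotype", "site", "rep", "row", "col")
  if (!all(key_cols %in% names(wide))) {
    stop("phenotype file must have header columns: ",
         paste(key_cols, collapse = ", "))
  }
  dup <- duplicated(wide[, c("genotype", "site", "rep")])
  if (any(dup)) {
    d <- wide[dup, c("genotype", "site", "rep")]
    stop("duplicated (genotype, site, rep) rows: ",
         paste(apply(d, 1, paste, collapse = "/"), collapse = "; "))
  }
  traits <- setdiff(names(wide), key_cols)
  if (length(traits) == 0) stop("no trait columns found")
  long <- do.call(rbind, lapply(traits, function(tr) {
    data.frame(
      genotype = wide$genotype, site = wide$site,
      rep = as.integer(wide$rep),
      row = as.integer(wide$row), col = as.integer(wide$col),
      trait = tr,
      value = suppressWarnings(as.numeric(wide[[tr]])),
      stringsAsFactors = FALSE
    )
  }))
  n_miss <- sum(is.na(long$value))
  if (n_miss > 0) {
    message(sprintf("read_phenotypes: %d missing/non-numeric cells of %d",
                    n_miss, nrow(long)))
  }
  bad_ord <- long$trait %in% ordinal_traits & !is.na(long$value) &
    (long$value < 1 | long$value > 9)
  if (any(bad_ord)) stop("ordinal trait values outside [1, 9]")
  attr(long, "ordinal") <- ordinal_traits
  long
}

#' Write a phenotype table back to wide CSV
#'
#' Inverse of [read_phenotypes()]: pivots the long table to one row per plot
#' and writes a comma-separated file. A write -> read -> write cycle is
#' byte-identical.
#'
#' @param pheno long phenotype data.frame as returned by [read_phenotypes()]
#'   or [simulate_trait()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  traits <- unique(pheno$trait)
  key <- unique(pheno[, c("genotype", "site", "rep", "row", "col")])
  key <- key[order(key$site, key$genotype, key$rep), ]
  out <- key
  for (tr in traits) {
    sub <- pheno[pheno$trait == tr, ]
    idx <- match(paste(key$genotype, key$site, key$rep),
                 paste(sub$genotype, sub$site, sub$rep))
    out[[tr]] <- sub$value[idx]
  }
  lines <- c(
    paste(names(out), collapse = ","),
    do.call(paste, c(lapply(out, function(x) {
      x <- as.character(x)
      x[is.na(x)] <- ""
      x
    }), sep = ","))
  )
  writeLines(lines, path)
  invisible(path)
}
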
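#' Read gene models from a GFF3 file
#'
#' Extracts `gene`-type features (via \code{ape::read.gff}) and returns them
#' sorted by chromosome then start, the layout expected by
#' [flanking_genes()]. Non-gene features (mRNA, exon, ...) are ignored.
#' Records with `end < start` are dropped with a warning.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `chrom, start, end, strand, gene_id,
#'   description` (1-based inclusive coordinates).
#' @export
read_gff <- function(path) {
  gff <- ape::read.gff(path, GFF3 = TRUE)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features in '", path, "'")
  bad <- genes$end < genes$start
  if (any(bad)) {
    warning(sum(bad), " gene record(s) with end < start dropped")
    genes <- genes[!bad, , drop = FALSE]
  }
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- grepl(paste0(key, "="), attrs)
    out[hit] <- sub(paste0(key, "="), "", m)
    out
  }
  ids <- attr_field(genes$attributes, "ID")
  ids[is.na(ids)] <- paste0("gene_", which(is.na(ids)))
  out <- data.frame(
    chrom = as.character(genes$seqid),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = as.character(genes$strand),
    gene_id = ids,
    description = attr_field(genes$attributes, "description"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}
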
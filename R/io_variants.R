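## Variant-table TSV dialect (VCF-like, but with explicit empty alleles):
##   chrom pos ref alt type region gene effect
## - SNP: ref and alt are single bases, pos is the substituted site.
## - DEL: alt is empty, pos is the first deleted base, ref the deleted run.
## - INS: ref is empty, pos is the reference base immediately LEFT of the
##   insertion point, alt the inserted run.
## Indels are left-normalized against the reference. Missing region/gene/
## effect fields are written as ".". Output is bit-stable across runs.

#' Construct a variant table
#'
#' @param pos Integer vector of 1-based reference positions.
#' @param ref,alt Character vectors of reference/alternate alleles (empty
#'   string for the absent side of an indel).
#' @param type `"SNP"`, `"INS"`, `"DEL"` (or `"MNP"` after merging).
#' @param region,gene,effect Optional annotation columns.
#' @param chrom Reference sequence name.
#' @return A data frame of class `variant_table`, sorted by position.
#' @export
variant_table <- function(pos = integer(), ref = character(), alt = character(),
                          type = character(), region = NA_character_,
                          gene = NA_character_, effect = NA_character_,
                          chrom = "ref") {
  n <- length(pos)
  df <- data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   type = rep_len(type, n), region = rep_len(region, n),
                   gene = rep_len(gene, n), effect = rep_len(effect, n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    ok_snp <- df$type != "SNP" | (nchar(df$ref) == 1L & nchar(df$alt) == 1L)
    ok_ins <- df$type != "INS" | (nchar(df$ref) == 0L & nchar(df$alt) >= 1L)
    ok_del <- df$type != "DEL" | (nchar(df$alt) == 0L & nchar(df$ref) >= 1L)
    if (!all(ok_snp & ok_ins & ok_del))
      stop("malformed variant record at row ", which(!(ok_snp & ok_ins & ok_del))[1L])
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Write a variant table to TSV
#'
#' @param variants A [variant_table()] (must be sorted by position).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  if (nrow(variants) && is.unsorted(variants$pos))
    stop("variants must be sorted by position before writing")
  out <- as.data.frame(variants)
  for (col in c("region", "gene", "effect"))
    out[[col]][is.na(out[[col]])] <- "."
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant table from TSV
#'
#' @param path Path written by [write_variant_table()].
#' @return A [variant_table()].
#' @export
read_variant_table <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character", pos = "integer",
                                 ref = "character", alt = "character",
                                 type = "character", region = "character",
                                 gene = "character", effect = "character"),
                  na.strings = character(0))
  d$ref[is.na(d$ref)] <- ""
  d$alt[is.na(d$alt)] <- ""
  for (col in c("region", "gene", "effect")) d[[col]][d[[col]] == "."] <- NA
  variant_table(d$pos, d$ref, d$alt, d$type, d$region, d$gene, d$effect,
                chrom = if (nrow(d)) d$chrom else "ref")
}

#' Write a newick tree string to file
#'
#' @param newick Newick string (as returned by [nj_tree()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(newick, path) {
  writeLines(newick, path)
  invisible(path)
}
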
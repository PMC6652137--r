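#' Normalize chromosome identifiers
#'
#' Genotype collections, reference genomes and variant callers disagree on
#' chromosome naming (the soybean reference uses `Gm01` while callers emit
#' `chr1`, `01` or `1`).  Panel and query sites are matched on a canonical
#' form: an optional alias table is applied first, then a leading `chr` or
#' `Gm` prefix (any case) is stripped, and purely numeric remainders lose
#' leading zeros.  Non-numeric names (scaffolds) are returned unchanged after
#' alias lookup.
#'
#' @param chrom character vector of chromosome names.
#' @param aliases optional named character vector mapping raw names to
#'   canonical ones, applied before the built-in rules.
#' @return character vector of canonical chromosome names.
#' @examples
#' normalize_chrom(c("Gm01", "chr1", "01", "1", "scaffold_22"))
#' @export
normalize_chrom <- function(chrom, aliases = NULL) {
  x <- as.character(chrom)
  if (!is.null(aliases)) {
    hit <- x %in% names(aliases)
    x[hit] <- unname(aliases[x[hit]])
  }
  x <- sub("^(chr|gm)", "", x, ignore.case = TRUE)
  num <- grepl("^[0-9]+$", x)
  x[num] <- as.character(as.integer(x[num]))
  x
}

# canonical site identity used to match panel, table and query records
site_key <- function(chrom, pos, ref, alt, aliases = NULL) {
  paste(normalize_chrom(chrom, aliases), pos, ref, alt, sep = ":")
}
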
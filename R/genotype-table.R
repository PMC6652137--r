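#' Construct a genotype table
#'
#' The central container for a multi-accession genotype collection: an ordered
#' set of biallelic SNP sites, an ordered set of uniquely labelled accessions,
#' and a sites x accessions matrix of alternate-allele dosages in `{0, 1, 2}`
#' with `NA` marking missing calls.  Optional group tags (e.g. wild /
#' cultivar / breeding line) annotate accessions.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`; one row
#'   per biallelic SNP.  `chrom` is normalized on construction (see
#'   [normalize_chrom()]); `pos` is 1-based per VCF convention.
#' @param accessions character vector of unique accession labels.
#' @param dosages integer/numeric matrix, `nrow(sites)` x `length(accessions)`,
#'   entries in `{0, 1, 2, NA}`.
#' @param groups optional character vector of group tags, one per accession
#'   (or a named vector matched by label).
#' @param aliases optional chromosome alias table, see [normalize_chrom()].
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(sites, accessions, dosages, groups = NULL,
                           aliases = NULL) {
  sites <- as.data.frame(sites)[, c("chrom", "pos", "ref", "alt")]
  rownames(sites) <- NULL
  sites$chrom <- normalize_chrom(sites$chrom, aliases)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- toupper(as.character(sites$ref))
  sites$alt <- toupper(as.character(sites$alt))
  accessions <- as.character(accessions)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"

  if (anyDuplicated(accessions))
    err_input("accession labels must be unique")
  if (!all(nrow(dosages) == nrow(sites), ncol(dosages) == length(accessions)))
    err_input(sprintf(
      "dosage matrix is %d x %d but %d sites and %d accessions were given",
      nrow(dosages), ncol(dosages), nrow(sites), length(accessions)))
  if (any(sites$pos < 1L))
    err_input("site positions must be >= 1 (1-based VCF convention)")
  if (any(sites$ref == sites$alt))
    err_input("ref and alt alleles must differ at every site")
  if (any(grepl(",", sites$alt, fixed = TRUE)))
    err_input("multiallelic sites are not allowed in a genotype table")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    err_input("non-missing dosages must be in {0, 1, 2}")

  if (!is.null(groups)) {
    groups <- if (!is.null(names(groups))) {
      unname(groups[accessions])
    } else {
      if (length(groups) != length(accessions))
        err_input("groups must have one tag per accession")
      as.character(groups)
    }
  }

  dimnames(dosages) <- list(
    site_key(sites$chrom, sites$pos, sites$ref, sites$alt), accessions)
  structure(
    list(sites = sites, accessions = accessions, dosages = dosages,
         groups = groups),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("genotype_table: %d sites x %d accessions (%.1f%% missing)\n",
              nrow(x$sites), length(x$accessions), 100 * miss))
  if (!is.null(x$groups))
    cat("  groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                                   table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosages)

# subset by site index and/or accession index, preserving metadata
subset_table <- function(table, site_idx = NULL, acc_idx = NULL) {
  if (is.null(site_idx)) site_idx <- seq_len(nrow(table$sites))
  if (is.null(acc_idx)) acc_idx <- seq_along(table$accessions)
  genotype_table(
    sites = table$sites[site_idx, , drop = FALSE],
    accessions = table$accessions[acc_idx],
    dosages = table$dosages[site_idx, acc_idx, drop = FALSE],
    groups = if (!is.null(table$groups)) table$groups[acc_idx])
}

#' Read a genotype table from TSV
#'
#' Expected dialect: a header row; first four columns `chrom`, `pos`, `ref`,
#' `alt`; remaining columns are accessions with cells in `{0, 1, 2, NA}`.
#'
#' @param path file path (plain or gzip).
#' @param groups optional named character vector of group tags by accession,
#'   or a path to a two-column TSV (label, group) without header requirement.
#' @param aliases chromosome alias table, see [normalize_chrom()].
#' @return a [genotype_table()].
#' @export
read_genotypes_tsv <- function(path, groups = NULL, aliases = NULL) {
  if (!file.exists(path)) err_missing(paste("genotype file not found:", path))
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = 1L))
  if (ncol(dt) < 5L)
    err_input("genotype TSV needs chrom, pos, ref, alt plus >=1 accession column")
  names(dt)[1:4] <- tolower(names(dt)[1:4])
  if (!identical(names(dt)[1:4], c("chrom", "pos", "ref", "alt")))
    err_input("genotype TSV columns 1-4 must be chrom, pos, ref, alt")
  acc <- names(dt)[-(1:4)]
  dos <- as.matrix(dt[, -(1:4), with = FALSE])
  genotype_table(dt[, 1:4], acc, dos, groups = resolve_groups(groups),
                 aliases = aliases)
}

#' Write a genotype table as TSV
#'
#' Inverse of [read_genotypes_tsv()].
#'
#' @param table a [genotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(table, path) {
  out <- data.table::data.table(table$sites)
  for (i in seq_along(table$accessions))
    out[[table$accessions[i]]] <- table$dosages[, i]
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

# groups may be a named vector or a path to a two-column TSV (label, group)
resolve_groups <- function(groups) {
  if (is.character(groups) && length(groups) == 1L && is.null(names(groups)) &&
      file.exists(groups)) {
    g <- data.table::fread(groups, header = FALSE, sep = "\t")
    groups <- stats::setNames(as.character(g[[2]]), as.character(g[[1]]))
  }
  groups
}

# Decode a vector of GT strings against a per-record allele list.
# alleles: list of character vectors, alleles[[i]][1] = REF, rest = ALTs.
# Returns the two called allele strings per record, or NA for no-calls,
# half-calls and non-diploid GTs.
decode_gt <- function(gt, alleles) {
  gt <- sub(":.*$", "", gt)            # tolerate full sample strings
  parts <- strsplit(gt, "[/|]")
  vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) != 2L || any(p == ".")) return(c(NA_character_, NA_character_))
    idx <- suppressWarnings(as.integer(p))
    if (anyNA(idx) || any(idx < 0L) || any(idx >= length(alleles[[i]])))
      return(c(NA_character_, NA_character_))
    alleles[[i]][idx + 1L]
  }, character(2L))
}

# Parse the record table of a VCF (plain or gzip/bgzip) into a data.table
# with CHROM, POS, REF, ALT and raw sample columns.  Only these fields are
# consulted anywhere in the package.
parse_vcf_records <- function(path) {
  if (!file.exists(path)) err_missing(paste("VCF not found:", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  header <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) err_input(paste("no #CHROM header line in", path))
    if (startsWith(line, "#CHROM")) { header <- line; break }
    if (!startsWith(line, "##"))
      err_input(paste("malformed VCF header in", path))
  }
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  body <- readLines(con)
  if (length(body) == 0L) {
    dt <- data.table::as.data.table(
      stats::setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    dt <- data.table::fread(text = body, header = FALSE, sep = "\t",
                            colClasses = "character")
    data.table::setnames(dt, cols[seq_len(ncol(dt))])
  }
  dt$POS <- as.integer(dt$POS)
  dt
}

#' Read a genotype table from a multi-sample VCF
#'
#' Ingests the GT field of a VCF v4.x.  Only biallelic SNP records (single
#' one-base REF and ALT) are kept; multiallelic and indel records are dropped
#' with a message.  GT values `0/0`, `0/1`, `1/1` (either phasing separator)
#' map to dosages 0, 1, 2; no-calls, half-calls and non-diploid GTs become
#' `NA`.
#'
#' @inheritParams read_genotypes_tsv
#' @return a [genotype_table()].
#' @export
read_genotypes_vcf <- function(path, groups = NULL, aliases = NULL) {
  dt <- parse_vcf_records(path)
  fixed <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT")
  samples <- setdiff(names(dt), fixed)
  if (length(samples) < 1L) err_input("VCF has no sample columns")

  snp <- nchar(dt$REF) == 1L & nchar(dt$ALT) == 1L &
    dt$REF %in% c("A", "C", "G", "T") & dt$ALT %in% c("A", "C", "G", "T")
  if (any(!snp))
    message(sprintf("dropped %d non-biallelic-SNP record(s)", sum(!snp)))
  dt <- dt[snp]
  if (nrow(dt) == 0L) err_input("VCF contains no biallelic SNP records")

  gt_field <- vapply(strsplit(dt$FORMAT, ":", fixed = TRUE),
                     function(f) match("GT", f), integer(1))
  if (anyNA(gt_field)) err_input("VCF records lack a GT FORMAT subfield")

  one_field <- length(unique(gt_field)) == 1L
  dos <- matrix(NA_integer_, nrow(dt), length(samples))
  for (j in seq_along(samples)) {
    raw <- dt[[samples[j]]]
    gt <- if (one_field) {
      data.table::tstrsplit(raw, ":", fixed = TRUE,
                            keep = gt_field[1])[[1]]
    } else {
      vapply(seq_along(raw), function(i) {
        strsplit(raw[i], ":", fixed = TRUE)[[1]][gt_field[i]]
      }, character(1))
    }
    called <- decode_gt(gt, alleles = Map(c, dt$REF, dt$ALT))
    dos[, j] <- ifelse(is.na(called[1, ]) | is.na(called[2, ]), NA_integer_,
                       (called[1, ] == dt$ALT) + (called[2, ] == dt$ALT))
  }
  sites <- data.frame(chrom = dt$CHROM, pos = dt$POS, ref = dt$REF,
                      alt = dt$ALT)
  dup <- duplicated(site_key(sites$chrom, sites$pos, sites$ref, sites$alt,
                             aliases))
  if (any(dup)) {
    message(sprintf("dropped %d duplicated site record(s)", sum(dup)))
    sites <- sites[!dup, , drop = FALSE]
    dos <- dos[!dup, , drop = FALSE]
  }
  genotype_table(sites, samples, dos, groups = resolve_groups(groups),
                 aliases = aliases)
}

# dispatch on file extension / content
read_genotypes <- function(path, groups = NULL, aliases = NULL) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE))
    read_genotypes_vcf(path, groups = groups, aliases = aliases)
  else
    read_genotypes_tsv(path, groups = groups, aliases = aliases)
}
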
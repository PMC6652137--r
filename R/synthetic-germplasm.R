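#' Simulation configuration for a structured germplasm collection
#'
#' Defaults describe a desk-scale stand-in for a real crop validation
#' collection: several diverged populations (wild vs cultivated material
#' separates at FST around 0.2 in soybean-like collections), pedigree-derived
#' offspring, and redundant (duplicate) accessions, with a few percent of
#' missing calls.
#'
#' @param n_populations number of diverged populations, default 3.
#' @param fst divergence parameter in (0, 1) of the Balding-Nichols
#'   construction, default 0.2.
#' @param n_sites number of independent biallelic SNPs, default 5000.
#' @param n_accessions_per_pop accessions per population, default 20.
#' @param n_redundant exact-copy accessions appended, default 2.
#' @param n_cross_offspring offspring of random panel crosses appended,
#'   default 2.
#' @param ancestral_maf_range uniform range (lo, hi) in (0, 0.5] for
#'   ancestral minor-allele frequencies, default c(0.1, 0.5).
#' @param missing_rate per-call missing probability in [0, 1), default 0.02.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_populations = 3, fst = 0.2, n_sites = 5000,
                       n_accessions_per_pop = 20, n_redundant = 2,
                       n_cross_offspring = 2,
                       ancestral_maf_range = c(0.1, 0.5),
                       missing_rate = 0.02, seed = 42) {
  cfg <- list(n_populations = as.integer(n_populations), fst = fst,
              n_sites = as.integer(n_sites),
              n_accessions_per_pop = as.integer(n_accessions_per_pop),
              n_redundant = as.integer(n_redundant),
              n_cross_offspring = as.integer(n_cross_offspring),
              ancestral_maf_range = as.numeric(ancestral_maf_range),
              missing_rate = missing_rate, seed = as.integer(seed))
  with(cfg, {
    if (fst <= 0 || fst >= 1) err_parameter("fst must be in (0, 1)")
    if (missing_rate < 0 || missing_rate >= 1)
      err_parameter("missing_rate must be in [0, 1)")
    if (length(ancestral_maf_range) != 2L ||
        ancestral_maf_range[1] >= ancestral_maf_range[2] ||
        ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5)
      err_parameter("ancestral_maf_range must be (lo, hi) within (0, 0.5]")
    if (any(c(n_populations, n_sites, n_accessions_per_pop) < 1L) ||
        any(c(n_redundant, n_cross_offspring) < 0L))
      err_parameter("counts must be positive (populations, sites, accessions)")
  })
  structure(cfg, class = "sim_config")
}

# Balding-Nichols population frequency: Beta with mean p and parameter F
bn_freq <- function(p, fst) {
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  stats::rbeta(length(p), a, b)
}

#' Simulate a structured germplasm collection
#'
#' Ancestral allele frequencies are drawn uniformly in
#' `ancestral_maf_range`; each population's frequencies follow the
#' Balding-Nichols construction (Beta around the ancestral frequency with
#' divergence `fst`); genotypes are Binomial(2, p).  Pedigree offspring
#' receive one random allele from each of two random parents per site;
#' redundant accessions are exact copies (including the missingness pattern,
#' applied before copying).  Sites are independent — no linkage
#' disequilibrium is modelled.  Fully reproducible from `seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `germplasm_sim`: `table` (a
#'   [genotype_table()] whose `groups` carry population tags), `truth` (list
#'   with `populations` named vector, `parents` named list, `freqs` sites x
#'   populations matrix, `ancestral` frequency vector), and `config`.
#' @export
simulate_collection <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n_pop <- config$n_populations
    n_sites <- config$n_sites
    n_per <- config$n_accessions_per_pop
    pops <- sprintf("POP%d", seq_len(n_pop))

    anc <- runif(n_sites, config$ancestral_maf_range[1],
                 config$ancestral_maf_range[2])
    freqs <- vapply(seq_len(n_pop), function(k) bn_freq(anc, config$fst),
                    numeric(n_sites))
    colnames(freqs) <- pops

    dos <- matrix(NA_integer_, n_sites, 0)
    labels <- character(0); pop_of <- character(0)
    for (k in seq_len(n_pop)) {
      g <- matrix(rbinom(n_sites * n_per, 2L, freqs[, k]), n_sites, n_per)
      dos <- cbind(dos, g)
      labels <- c(labels, sprintf("%s_ACC%02d", pops[k], seq_len(n_per)))
      pop_of <- c(pop_of, rep(pops[k], n_per))
    }

    parents <- list()
    if (config$n_cross_offspring > 0L) {
      for (i in seq_len(config$n_cross_offspring)) {
        pr <- sample(length(labels), 2L)
        gamete <- function(parent)
          rbinom(n_sites, 1L, ifelse(is.na(dos[, parent]), 0.5,
                                     dos[, parent] / 2))
        child <- gamete(pr[1]) + gamete(pr[2])
        lab <- sprintf("CROSS%02d_%s_x_%s", i, labels[pr[1]], labels[pr[2]])
        parents[[lab]] <- labels[pr]
        dos <- cbind(dos, child)
        labels <- c(labels, lab); pop_of <- c(pop_of, "cross")
      }
    }

    # missing mask before duplication so copies match their source exactly
    if (config$missing_rate > 0) {
      mask <- matrix(runif(length(dos)) < config$missing_rate,
                     nrow(dos), ncol(dos))
      dos[mask] <- NA_integer_
    }

    if (config$n_redundant > 0L) {
      src <- sample(length(labels), config$n_redundant, replace = FALSE)
      for (i in seq_len(config$n_redundant)) {
        dos <- cbind(dos, dos[, src[i]])
        lab <- paste0(labels[src[i]], "_dup")
        parents[[lab]] <- labels[src[i]]
        labels <- c(labels, lab)
        pop_of <- c(pop_of, pop_of[src[i]])
      }
    }

    # vary chromosome naming styles to exercise normalization downstream
    chrom_pool <- c("Gm01", "Gm02", "chr3", "4")
    sites <- data.frame(
      chrom = rep(chrom_pool, length.out = n_sites),
      pos = 100L * seq_len(n_sites),
      ref = "A", alt = "G")
    bases <- c("A", "C", "G", "T")
    sites$ref <- sample(bases, n_sites, replace = TRUE)
    sites$alt <- vapply(sites$ref,
                        function(r) sample(setdiff(bases, r), 1L),
                        character(1))

    table <- genotype_table(sites, labels, dos,
                            groups = stats::setNames(pop_of, labels))
    structure(
      list(table = table,
           truth = list(populations = stats::setNames(pop_of, labels),
                        parents = parents, freqs = freqs, ancestral = anc),
           config = config),
      class = "germplasm_sim")
  })
}

#' @export
print.germplasm_sim <- function(x, ...) {
  cat(sprintf(
    "germplasm_sim: %d populations (fst = %g), %d sites, %d accessions, seed %d\n",
    x$config$n_populations, x$config$fst, x$config$n_sites,
    length(x$table$accessions), x$config$seed))
  invisible(x)
}

#' Draw held-out query accessions from a simulated collection
#'
#' New samples are drawn from the stored population allele frequencies (the
#' same Balding-Nichols populations the panel accessions came from) but are
#' not part of the collection — they play the role of freshly resequenced
#' unknown samples.
#'
#' @param sim a `germplasm_sim`.
#' @param n_per_pop held-out samples per population.
#' @param seed RNG seed (independent of the collection's seed).
#' @param missing_rate per-call missing probability; defaults to the
#'   collection's.
#' @return a list with `table` (a [genotype_table()] over the same sites)
#'   and `truth` (named vector query label -> population).
#' @export
simulate_queries <- function(sim, n_per_pop = 10, seed = 1,
                             missing_rate = NULL) {
  stopifnot(inherits(sim, "germplasm_sim"))
  missing_rate <- missing_rate %||% sim$config$missing_rate
  withr::with_seed(as.integer(seed), {
    freqs <- sim$truth$freqs
    n_sites <- nrow(freqs)
    pops <- colnames(freqs)
    dos <- matrix(NA_integer_, n_sites, 0)
    labels <- character(0); pop_of <- character(0)
    for (k in seq_along(pops)) {
      g <- matrix(rbinom(n_sites * n_per_pop, 2L, freqs[, k]),
                  n_sites, n_per_pop)
      dos <- cbind(dos, g)
      labels <- c(labels, sprintf("QRY_%s_%02d", pops[k], seq_len(n_per_pop)))
      pop_of <- c(pop_of, rep(pops[k], n_per_pop))
    }
    if (missing_rate > 0) {
      mask <- matrix(runif(length(dos)) < missing_rate, nrow(dos), ncol(dos))
      dos[mask] <- NA_integer_
    }
    list(table = genotype_table(sim$table$sites, labels, dos,
                                groups = stats::setNames(pop_of, labels)),
         truth = stats::setNames(pop_of, labels))
  })
}

#' Write one accession as a single-sample variant-only VCF
#'
#' Emulates the output of a standard variant-only calling pipeline: records
#' are emitted ONLY for sites where the accession carries the alternate
#' allele (dosage 1 -> GT 0/1, dosage 2 -> GT 1/1); homozygous-reference
#' sites are omitted entirely; missing calls appear as GT `./.`.  The header
#' declares the contigs.
#'
#' @param table a [genotype_table()].
#' @param accession label of the accession to export.
#' @param path output VCF path.
#' @param chrom_style chromosome naming style in the written file: `"asis"`
#'   (the table's canonical names), `"chr"` (`chr`-prefixed), `"Gm"`
#'   (zero-padded `Gm` prefix) — varied in fixtures to exercise the
#'   normalization table.
#' @return `path`, invisibly.
#' @export
write_query_vcf <- function(table, accession, path, chrom_style = "asis") {
  stopifnot(inherits(table, "genotype_table"))
  j <- match(accession, table$accessions)
  if (is.na(j))
    err_parameter(sprintf("unknown accession '%s'", accession))
  d <- table$dosages[, j]
  chrom <- table$sites$chrom
  chrom <- switch(chrom_style,
    asis = chrom,
    chr = paste0("chr", chrom),
    Gm = ifelse(grepl("^[0-9]+$", chrom),
                sprintf("Gm%02d", as.integer(chrom)), chrom),
    err_parameter(paste("unknown chrom_style:", chrom_style)))

  keep <- which(is.na(d) | d >= 1L)
  gt <- ifelse(is.na(d[keep]), "./.", ifelse(d[keep] == 1L, "0/1", "1/1"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=germplacer-simulated",
    sprintf("##contig=<ID=%s>", unique(chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accession), collapse = "\t"))
  body <- if (length(keep)) {
    paste(chrom[keep], table$sites$pos[keep], ".", table$sites$ref[keep],
          table$sites$alt[keep], ".", "PASS", ".", "GT", gt, sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
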
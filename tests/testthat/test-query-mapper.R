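# a tiny fixed panel over 4 sites for the GT-decoding contract tests
tiny_model <- function() {
  sites <- data.frame(chrom = "1", pos = c(1000L, 2000L, 3000L, 4000L),
                      ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"))
  tab <- genotype_table(sites, c("X", "Y", "Z"),
                        rbind(c(0, 1, 2), c(2, 1, 0), c(0, 2, 1),
                              c(1, 0, 2)))
  fit_panel(tab, maf_threshold = 0.2, n_components = 2)$model
}

query_vcf_lines <- function(records, sample = "Q") {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t"),
    records)
}

read_lines_as_vcf <- function(lines, model, ...) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  read_query_vcf(path, model, ...)
}

test_that("record-free VCF gives all-zero dosages, all assumed hom-ref", {
  model <- tiny_model()
  prof <- suppressWarnings(
    read_lines_as_vcf(query_vcf_lines(character(0)), model))
  expect_equal(unname(prof$dosages), rep(0L, 4))
  expect_equal(prof$n_assumed_ref, 4L)
  expect_equal(prof$n_matched_variant_records, 0L)
  expect_equal(prof$n_missing, 0L)
})

test_that("GT decoding: hom-alt, het, no-call, half-call, conflicts", {
  model <- tiny_model()
  recs <- c(
    "chr1\t1000\t.\tA\tG\t.\tPASS\t.\tGT\t1/1",  # dosage 2
    "Gm01\t2000\t.\tC\tT\t.\tPASS\t.\tGT\t0|1",  # dosage 1, phased, alias
    "1\t3000\t.\tG\tA\t.\tPASS\t.\tGT\t./.",     # no-call -> NA
    "1\t4000\t.\tT\tA\t.\tPASS\t.\tGT\t0/1")     # alt-allele conflict -> NA
  prof <- suppressWarnings(read_lines_as_vcf(query_vcf_lines(recs), model))
  expect_equal(unname(prof$dosages), c(2L, 1L, NA, NA))
  expect_equal(prof$n_matched_variant_records, 2L)
  expect_equal(prof$n_assumed_ref, 0L)
  expect_equal(prof$n_missing, 2L)
  expect_warning(read_lines_as_vcf(query_vcf_lines(recs), model,
                                   min_record_fraction = 0),
                 "conflicted with panel alleles")
})

test_that("ref mismatch and half-calls are missing, never zero", {
  model <- tiny_model()
  recs <- c(
    "1\t1000\t.\tT\tG\t.\tPASS\t.\tGT\t1/1",   # REF mismatch -> NA
    "1\t2000\t.\tC\tT\t.\tPASS\t.\tGT\t./1",   # half-call -> NA
    "1\t3000\t.\tG\tA\t.\tPASS\t.\tGT\t1",     # haploid -> NA
    "1\t4000\t.\tT\tC,A\t.\tPASS\t.\tGT\t1/2") # 2nd alt off-panel -> NA
  prof <- suppressWarnings(read_lines_as_vcf(query_vcf_lines(recs), model))
  expect_equal(unname(prof$dosages), c(NA_integer_, NA, NA, NA))
  expect_equal(prof$n_missing, 4L)
  # multiallelic record whose called alleles are all panel-legal still scores
  rec2 <- "1\t1000\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1"
  prof2 <- suppressWarnings(read_lines_as_vcf(query_vcf_lines(rec2), model))
  expect_equal(unname(prof2$dosages[1]), 1L)
})

test_that("multi-sample query VCFs are rejected", {
  model <- tiny_model()
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "A", "B"), collapse = "\t"),
             "1\t1000\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path)
  expect_error(read_query_vcf(path, model), class = "v2g_input_error")
})

test_that("coverage counters partition the site index under random record deletion", {
  sim <- small_sim(seed = 3, n_sites = 400, per_pop = 5)
  panel <- fit_panel(sim$table, n_components = 5)
  full <- withr::local_tempfile(fileext = ".vcf")
  write_query_vcf(sim$table, sim$table$accessions[1], full)
  lines <- readLines(full)
  hdr <- grep("^#", lines)
  body <- lines[-hdr]
  for (seed in 1:5) {
    keep <- withr::with_seed(seed, runif(length(body)) > 0.5)
    path <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(lines[hdr], body[keep]), path)
    prof <- suppressWarnings(read_query_vcf(path, panel$model))
    expect_equal(prof$n_matched_variant_records + prof$n_assumed_ref +
                   prof$n_missing, nrow(panel$model$sites))
  }
})

test_that("projection reproduces training scores and hand arithmetic", {
  sim <- small_sim(seed = 5, n_sites = 500, per_pop = 6)
  filt <- filter_by_maf(sim$table, 0.2)
  panel <- fit_panel(sim$table, n_components = 8)
  i <- 7L
  sc <- project_query(panel$model, filt$dosages[, i])$scores
  expect_equal(unname(sc), unname(panel$scores[, i]), tolerance = 1e-8)

  # all-missing profile collapses to the site means -> zero scores
  allna <- rep(NA_real_, nrow(filt$sites))
  expect_equal(unname(project_query(panel$model, allna)$scores),
               rep(0, 8), tolerance = 1e-12)

  # 3-site toy with hand-set loadings
  model <- structure(list(
    sites = data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "G"),
    site_means = c(1, 0.5, 1.5),
    loadings = rbind(c(1, 0, 0), c(0, 0.6, 0.8)),
    evr = c(0.6, 0.4), maf_threshold = 0.2, n_components = 2L,
    min_call_rate = 0.5), class = "panel_model")
  sc <- project_query(model, c(2, 1, 0))$scores
  # centered = (1, 0.5, -1.5); PC1 = 1; PC2 = 0.3 - 1.2 = -0.9
  expect_equal(unname(sc), c(1, -0.9), tolerance = 1e-12)

  expect_error(project_query(model, c(1, 2)), class = "v2g_input_error")
})

test_that("projection is affine on imputation-free profiles", {
  sim <- small_sim(seed = 9, n_sites = 300, per_pop = 5)
  panel <- fit_panel(sim$table, n_components = 6)
  n <- nrow(panel$model$sites)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      x <- sample(0:2, n, replace = TRUE)
      y <- sample(0:2, n, replace = TRUE)
      a <- runif(1)
    })
    lhs <- project_query(panel$model, a * x + (1 - a) * y)$scores
    rhs <- a * project_query(panel$model, x)$scores +
      (1 - a) * project_query(panel$model, y)$scores
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("synthetic VCF round-trip recovers dosages exactly (absent site => 0)", {
  sim <- small_sim(seed = 12, n_sites = 600, per_pop = 6)
  panel <- fit_panel(sim$table, n_components = 10)
  filt <- filter_by_maf(sim$table, 0.2)
  for (acc in sim$table$accessions[c(1, 10, 20)]) {
    for (style in c("asis", "chr", "Gm")) {
      path <- withr::local_tempfile(fileext = ".vcf")
      write_query_vcf(sim$table, acc, path, chrom_style = style)
      prof <- suppressWarnings(read_query_vcf(path, panel$model))
      expect_identical(unname(prof$dosages),
                       unname(filt$dosages[, acc]))
    }
  }
})

test_that("zero site overlap raises a malformed-input error", {
  model <- tiny_model()
  recs <- "9\t99999\t.\tA\tG\t.\tPASS\t.\tGT\t1/1"
  expect_error(read_lines_as_vcf(query_vcf_lines(recs), model),
               class = "v2g_input_error")
})
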
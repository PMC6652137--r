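#' Read a single-sample variant-only VCF against a panel's site index
#'
#' A variant-only VCF (e.g. `bcftools call -v` output) records only sites
#' that differ from the reference genome, so a panel site with no VCF record
#' is scored 0 (assumed homozygous reference) — the rule that makes a
#' variant-only file interpretable at all, and the single most consequential
#' convention in this package.  Panel sites with a matching record are scored
#' by the GT call's count of the panel's alternate allele.  Conflicts (REF
#' mismatch, or a called allele that is neither the panel REF nor the panel
#' ALT), no-calls, half-calls and non-diploid GTs become missing, never
#' silently 0, which protects against queries called on the wrong reference.
#'
#' @param path single-sample VCF, plain or gzip/bgzip compressed.  Only
#'   CHROM, POS, REF, ALT and the GT subfield are consulted.
#' @param model a `panel_model` (the `model` element of a `reference_panel`).
#' @param aliases chromosome alias table, see [normalize_chrom()].
#' @param min_record_fraction low-coverage guard: warn (do not fail) if fewer
#'   than this fraction of panel sites appear as usable variant records;
#'   queries should come from >= 10x resequencing.  Default 0.1.
#' @return an object of class `query_profile`: `label` (the VCF sample
#'   name), `dosages` (vector over panel sites, `NA` = missing),
#'   `n_matched_variant_records`, `n_assumed_ref`, `n_missing` (which
#'   partition the site index), and `scores` (`NULL` until
#'   [project_query()]).
#' @export
read_query_vcf <- function(path, model, aliases = NULL,
                           min_record_fraction = 0.1) {
  stopifnot(inherits(model, "panel_model"))
  dt <- parse_vcf_records(path)
  fixed <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT")
  samples <- setdiff(names(dt), fixed)
  if (length(samples) != 1L)
    err_input(sprintf(
      "query VCF must have exactly one sample column, found %d (%s); split multi-sample files per sample first",
      length(samples), paste(head(samples, 5), collapse = ", ")))
  label <- samples[1]

  n_sites <- nrow(model$sites)
  panel_loc <- paste(model$sites$chrom, model$sites$pos, sep = ":")
  dosages <- rep(0L, n_sites)   # absent record => assumed homozygous ref

  if (nrow(dt) > 0L) {
    dt$loc <- paste(normalize_chrom(dt$CHROM, aliases), dt$POS, sep = ":")
    dt <- dt[!duplicated(dt$loc)]           # first record wins at a position
    hit <- match(panel_loc, dt$loc)
  } else {
    hit <- rep(NA_integer_, n_sites)
  }
  matched <- which(!is.na(hit))
  n_conflict <- 0L
  if (length(matched)) {
    rec <- dt[hit[matched]]
    gt_field <- vapply(strsplit(rec$FORMAT, ":", fixed = TRUE),
                       function(f) match("GT", f), integer(1))
    gt <- vapply(seq_len(nrow(rec)), function(i) {
      strsplit(rec[[label]][i], ":", fixed = TRUE)[[1]][gt_field[i]]
    }, character(1))
    alleles <- Map(c, rec$REF, strsplit(rec$ALT, ",", fixed = TRUE))
    called <- decode_gt(gt, alleles)

    pref <- model$sites$ref[matched]
    palt <- model$sites$alt[matched]
    ref_ok <- toupper(rec$REF) == pref
    no_call <- is.na(called[1, ]) | is.na(called[2, ])
    legal <- (toupper(called[1, ]) == pref | toupper(called[1, ]) == palt) &
             (toupper(called[2, ]) == pref | toupper(called[2, ]) == palt)
    d <- (toupper(called[1, ]) == palt) + (toupper(called[2, ]) == palt)
    miss <- no_call | !ref_ok | (!no_call & !legal)
    n_conflict <- sum((!ref_ok | (!no_call & !legal)) & !is.na(ref_ok))
    dosages[matched] <- ifelse(miss, NA_integer_, d)
  }
  if (length(matched) == 0L && n_sites > 0L && nrow(dt) > 0L)
    err_input(
      "no query record matches any panel site: wrong reference genome or chromosome naming?")
  if (n_conflict > 0L)
    warning(sprintf(
      "%d record(s) conflicted with panel alleles and were scored missing (wrong reference genome?)",
      n_conflict), call. = FALSE)

  n_missing <- sum(is.na(dosages))
  n_matched <- length(matched) - sum(is.na(dosages[matched]))
  n_assumed <- n_sites - length(matched)
  if (n_sites > 0L && n_matched / n_sites < min_record_fraction)
    warning(sprintf(
      "only %d/%d panel sites usable as variant records (< %.0f%%); queries need >= 10x resequencing coverage",
      n_matched, n_sites, 100 * min_record_fraction), call. = FALSE)

  structure(
    list(label = label,
         dosages = stats::setNames(dosages, site_key(
           model$sites$chrom, model$sites$pos, model$sites$ref,
           model$sites$alt)),
         n_matched_variant_records = n_matched,
         n_assumed_ref = n_assumed,
         n_missing = n_missing,
         scores = NULL),
    class = "query_profile")
}

#' Project a query profile through pre-trained PCA parameters
#'
#' Missing dosages are imputed with the panel's stored site means, the vector
#' is centered by those means, and the frozen component loadings map it into
#' PC space.  Deterministic; no refitting occurs.
#'
#' @param model a `panel_model`.
#' @param profile a `query_profile` aligned to `model$sites` (from
#'   [read_query_vcf()]), or a bare dosage vector of the right length.
#' @return the profile with `scores` filled (length `n_components`).
#' @export
project_query <- function(model, profile) {
  stopifnot(inherits(model, "panel_model"))
  bare <- !inherits(profile, "query_profile")
  d <- if (bare) as.numeric(profile) else as.numeric(profile$dosages)
  if (length(d) != length(model$site_means))
    err_input(sprintf(
      "profile has %d sites but panel expects %d: panel/profile incompatibility",
      length(d), length(model$site_means)))
  d[is.na(d)] <- model$site_means[is.na(d)]
  scores <- drop(model$loadings %*% (d - model$site_means))
  names(scores) <- paste0("PC", seq_along(scores))
  if (bare) {
    structure(list(label = NA_character_, dosages = profile,
                   n_matched_variant_records = NA_integer_,
                   n_assumed_ref = NA_integer_, n_missing = sum(is.na(profile)),
                   scores = scores),
              class = "query_profile")
  } else {
    profile$scores <- scores
    profile
  }
}

#' @export
print.query_profile <- function(x, ...) {
  n <- x$n_matched_variant_records + x$n_assumed_ref + x$n_missing
  cat(sprintf(
    "query_profile '%s': %d panel sites (%d variant records, %d assumed hom-ref, %d missing)%s\n",
    x$label, n, x$n_matched_variant_records, x$n_assumed_ref, x$n_missing,
    if (is.null(x$scores)) " [not projected]" else " [projected]"))
  invisible(x)
}
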
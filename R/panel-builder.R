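#' Per-site minor-allele frequency
#'
#' For each site the alternate-allele frequency is the sum of non-missing
#' dosages over twice the non-missing call count; the MAF folds it to
#' `min(f, 1 - f)`.  A site with zero non-missing calls has no defined MAF
#' and is reported as `NA`.
#'
#' @param table a [genotype_table()].
#' @return numeric vector in `[0, 0.5]`, `NA` for all-missing sites.
#' @export
compute_maf <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  n_called <- rowSums(!is.na(table$dosages))
  f <- rowSums(table$dosages, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(f, 1 - f)
  maf[n_called == 0L] <- NA_real_
  unname(maf)
}

#' Filter sites by minor-allele frequency and call rate
#'
#' Retains sites whose MAF is defined and at or above `threshold` (sites with
#' strictly lower MAF are removed) and whose call rate is at least
#' `min_call_rate`; rare alleles carry little clustering signal and sites
#' genotyped in only a handful of accessions give unstable MAF estimates.
#' Site order and the accession set are unchanged.
#'
#' @param table a [genotype_table()].
#' @param threshold MAF cutoff in `(0, 0.5]`; default 0.2, a deliberately
#'   strong criterion keeping only common alleles.
#' @param min_call_rate minimum fraction of non-missing calls per site,
#'   default 0.5.
#' @return a [genotype_table()] with the retained sites.
#' @export
filter_by_maf <- function(table, threshold = 0.2, min_call_rate = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 0.5)
    err_parameter("MAF threshold must be a single value in (0, 0.5]")
  maf <- compute_maf(table)
  call_rate <- rowMeans(!is.na(table$dosages))
  keep <- !is.na(maf) & maf >= threshold & call_rate >= min_call_rate
  if (!any(keep))
    err_empty_panel(sprintf(
      "no site passes MAF >= %g and call rate >= %g: cannot build a panel",
      threshold, min_call_rate))
  subset_table(table, site_idx = which(keep))
}

#' Mean-impute missing calls and center by site means
#'
#' Missing dosages are replaced by the site's mean dosage over non-missing
#' calls (preserving the site mean without adding structure), then every site
#' is centered by subtracting that mean.  No unit-variance scaling is applied.
#'
#' @param table a [genotype_table()]; every site needs at least one
#'   non-missing call.
#' @return list with `matrix` (sites x accessions, centered, zero row means)
#'   and `site_means` (pre-centering means, in `[0, 2]`).
#' @export
impute_and_center <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  x <- table$dosages
  storage.mode(x) <- "double"
  n_called <- rowSums(!is.na(x))
  if (any(n_called == 0L))
    err_input("sites with zero non-missing calls cannot be imputed")
  site_means <- rowSums(x, na.rm = TRUE) / n_called
  miss <- which(is.na(x), arr.ind = TRUE)
  if (nrow(miss)) x[miss] <- site_means[miss[, 1L]]
  list(matrix = x - site_means, site_means = unname(site_means))
}

# Deterministic sign convention: flip each component so its largest-magnitude
# loading is positive; exact ties resolved to the lowest site index (which.max
# returns the first maximum).
apply_sign_convention <- function(loadings, scores = NULL) {
  flip <- apply(loadings, 1L, function(v) v[which.max(abs(v))] < 0)
  loadings[flip, ] <- -loadings[flip, , drop = FALSE]
  if (!is.null(scores)) scores[flip, ] <- -scores[flip, , drop = FALSE]
  list(loadings = loadings, scores = scores)
}

#' Fit a reference panel
#'
#' The full pipeline: MAF/call-rate filtering, mean imputation, centering,
#' then a deterministic full-SVD PCA with accessions as observations and
#' sites as features.  The result bundles the frozen projection parameters
#' (site index, site means, loadings, explained-variance ratios) with the
#' accessions' PC score matrix — the reference genotype matrix a query is
#' placed into.
#'
#' @param table a [genotype_table()].
#' @param maf_threshold MAF cutoff, default 0.2 (see [filter_by_maf()]).
#' @param n_components number of principal components retained, default 20.
#' @param min_call_rate per-site call-rate floor, default 0.5.
#' @param provenance free-text build metadata stored in the panel.
#' @return an object of class `reference_panel` with elements `model`
#'   (class `panel_model`: `sites`, `site_means`, `loadings`
#'   (`n_components` x n_sites), `evr`, `maf_threshold`, `n_components`,
#'   `min_call_rate`), `scores` (`n_components` x n_accessions), `labels`,
#'   `groups`, `provenance`.
#' @export
fit_panel <- function(table, maf_threshold = 0.2, n_components = 20,
                      min_call_rate = 0.5, provenance = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  filtered <- filter_by_maf(table, maf_threshold, min_call_rate)
  n_sites <- nrow(filtered$sites)
  n_acc <- length(filtered$accessions)
  n_components <- as.integer(n_components)
  if (length(n_components) != 1L || is.na(n_components) || n_components < 1L ||
      n_components > min(n_sites, n_acc))
    err_parameter(sprintf(
      "n_components must be in [1, min(retained sites = %d, accessions = %d)], got %s",
      n_sites, n_acc, paste(n_components, collapse = ",")))

  ic <- impute_and_center(filtered)
  X <- t(ic$matrix)                       # accessions x sites
  sv <- svd(X)                            # full, non-randomized
  evr_all <- sv$d^2 / sum(sv$d^2)
  loadings <- t(sv$v[, seq_len(n_components), drop = FALSE])
  scores <- loadings %*% ic$matrix        # n_components x n_accessions
  sgn <- apply_sign_convention(loadings, scores)
  dimnames(sgn$scores) <- list(paste0("PC", seq_len(n_components)),
                               filtered$accessions)

  model <- structure(
    list(sites = filtered$sites,
         site_means = ic$site_means,
         loadings = sgn$loadings,
         evr = evr_all[seq_len(n_components)],
         maf_threshold = maf_threshold,
         n_components = n_components,
         min_call_rate = min_call_rate),
    class = "panel_model")
  structure(
    list(model = model,
         scores = sgn$scores,
         labels = filtered$accessions,
         groups = filtered$groups,
         provenance = provenance %||%
           sprintf("built %s from %d x %d genotype table",
                   format(Sys.time(), "%Y-%m-%d"), nrow(table$sites),
                   length(table$accessions))),
    class = "reference_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf(
    "reference_panel: %d accessions x %d PCs (from %d sites, MAF >= %g)\n",
    length(x$labels), x$model$n_components, nrow(x$model$sites),
    x$model$maf_threshold))
  cat(sprintf("  summed explained-variance ratio: %.3f\n", sum(x$model$evr)))
  invisible(x)
}
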
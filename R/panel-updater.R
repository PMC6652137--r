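#' Integrate new accessions into an existing panel without refitting
#'
#' Each new accession's genotypes are matched to the panel's site index by
#' (chrom, pos, ref, alt), projected through the frozen PCA parameters
#' exactly as a query would be (site-mean imputation for panel sites the
#' table lacks), and appended as new score columns.  The model — loadings,
#' site means, explained-variance ratios — is untouched; refitting is a
#' separate, explicit rebuild.  Duplicate labels are suffixed `_2`, `_3`, ...
#' with a warning (near-duplicate cultivar names are common in germplasm
#' collections).
#'
#' @param panel a `reference_panel`.
#' @param table a [genotype_table()] of new accessions; table-only sites are
#'   ignored with a message.
#' @return a `reference_panel` with the new score columns appended.
#' @export
integrate_accessions <- function(panel, table) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(table, "genotype_table"))
  if (length(table$accessions) == 0L) return(panel)

  ps <- panel$model$sites
  pkey <- site_key(ps$chrom, ps$pos, ps$ref, ps$alt)
  tkey <- site_key(table$sites$chrom, table$sites$pos, table$sites$ref,
                   table$sites$alt)
  hit <- match(pkey, tkey)
  if (all(is.na(hit)))
    err_input("no site overlap between table and panel: incompatible inputs")
  n_ignored <- sum(!(tkey %in% pkey))
  if (n_ignored > 0L)
    message(sprintf("%d table site(s) absent from the panel were ignored",
                    n_ignored))

  # panel-site-aligned dosages; unmatched panel sites -> missing
  aligned <- matrix(NA_real_, length(pkey), length(table$accessions))
  ok <- !is.na(hit)
  aligned[ok, ] <- table$dosages[hit[ok], , drop = FALSE]

  new_scores <- vapply(seq_len(ncol(aligned)), function(j)
    project_query(panel$model, aligned[, j])$scores,
    numeric(panel$model$n_components))
  new_scores <- matrix(new_scores, nrow = panel$model$n_components)

  labels <- panel$labels
  new_labels <- table$accessions
  for (i in seq_along(new_labels)) {
    if (new_labels[i] %in% labels) {
      base <- new_labels[i]; n <- 2L
      while (paste0(base, "_", n) %in% c(labels, new_labels[-i])) n <- n + 1L
      new_labels[i] <- paste0(base, "_", n)
      warning(sprintf("duplicate accession label '%s' renamed to '%s'",
                      base, new_labels[i]), call. = FALSE)
    }
    labels <- c(labels, new_labels[i])
  }
  colnames(new_scores) <- new_labels
  rownames(new_scores) <- rownames(panel$scores)

  groups <- panel$groups
  if (!is.null(groups) || !is.null(table$groups)) {
    old <- groups %||% rep(NA_character_, length(panel$labels))
    add <- table$groups %||% rep(NA_character_, length(new_labels))
    groups <- c(old, add)
  }
  structure(
    list(model = panel$model,
         scores = cbind(panel$scores, new_scores),
         labels = c(panel$labels, new_labels),
         groups = groups,
         provenance = paste0(panel$provenance, "; integrated ",
                             length(new_labels), " accession(s)")),
    class = "reference_panel")
}
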
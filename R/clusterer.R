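#' Rank panel accessions by distance to a query
#'
#' Euclidean distance in PC space between the query's score vector and every
#' accession's score column; the top `k` are returned.  PCs form a Euclidean
#' embedding of the centered genotype space, so this is the natural metric.
#' Ties are ordered lexicographically by accession label.
#'
#' @param panel a `reference_panel`.
#' @param scores query PC vector (length `n_components`) or a projected
#'   `query_profile`.
#' @param k number of rows to report, default 10.
#' @return an object of class `distance_report`: data.frame with columns
#'   `rank`, `label`, `distance`, `group`, plus attributes `query_label`
#'   and `k`.
#' @export
rank_distances <- function(panel, scores, k = 10) {
  stopifnot(inherits(panel, "reference_panel"))
  qlab <- "query"
  if (inherits(scores, "query_profile")) {
    if (is.null(scores$scores))
      err_input("query profile has no scores; run project_query() first")
    qlab <- scores$label
    scores <- scores$scores
  }
  scores <- as.numeric(scores)
  if (length(scores) != nrow(panel$scores))
    err_input(sprintf("query has %d score dimensions but panel has %d",
                      length(scores), nrow(panel$scores)))
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    err_parameter("k must be a positive integer")
  k <- min(as.integer(k), length(panel$labels))

  d <- sqrt(colSums((panel$scores - scores)^2))
  ord <- order(d, panel$labels)[seq_len(k)]
  out <- data.frame(
    rank = seq_len(k),
    label = panel$labels[ord],
    distance = unname(d[ord]),
    group = if (is.null(panel$groups)) NA_character_ else panel$groups[ord],
    stringsAsFactors = FALSE)
  structure(out, class = c("distance_report", "data.frame"),
            query_label = qlab, k = k)
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("distance_report for '%s' (top %d):\n",
              attr(x, "query_label"), attr(x, "k")))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Write a distance report as TSV
#'
#' @param report a `distance_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_report <- function(report, path) {
  data.table::fwrite(as.data.frame(report), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Complete-linkage tree of panel accessions (optionally with a query)
#'
#' Agglomerative hierarchical clustering of the PC score columns under
#' Euclidean distance with complete linkage (inter-cluster distance = maximum
#' pairwise member distance), the clustering the placement dendrogram is
#' built from.  Complete linkage is monotone, so merge heights never
#' decrease.
#'
#' @param panel a `reference_panel`.
#' @param query optional projected `query_profile` (or bare score vector)
#'   added as an extra leaf.
#' @param query_label leaf label for a bare score vector, default "query".
#' @param method linkage method passed to [stats::hclust()]; default
#'   `"complete"`.
#' @return an object of class `linkage_tree`: the merge matrix, heights and
#'   labels of the clustering (a thin wrapper around `hclust`).
#' @export
build_tree <- function(panel, query = NULL, query_label = "query",
                       method = "complete") {
  stopifnot(inherits(panel, "reference_panel"))
  m <- panel$scores
  labels <- panel$labels
  if (!is.null(query)) {
    if (inherits(query, "query_profile")) {
      if (is.null(query$scores))
        err_input("query profile has no scores; run project_query() first")
      query_label <- query$label
      query <- query$scores
    }
    if (length(query) != nrow(m))
      err_input("query score dimensionality does not match panel")
    if (query_label %in% labels) query_label <- paste0(query_label, "*")
    m <- cbind(m, as.numeric(query))
    labels <- c(labels, query_label)
  }
  if (ncol(m) < 2L) err_parameter("need at least 2 leaves to build a tree")
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                      method = method)
  hc$labels <- labels
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = labels, method = method, hclust = hc),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("linkage_tree: %d leaves, %s linkage, max height %.4g\n",
              length(x$labels), x$method, max(x$height)))
  invisible(x)
}

# hclust -> ape phylo with leaf depth equal to merge height (ape's
# as.phylo.hclust uses the ultrametric height/2 convention; branch lengths
# are doubled so that a 2-leaf tree at height h reads "(A:h,B:h);").
tree_as_phylo <- function(tree) {
  ph <- ape::as.phylo(tree$hclust)
  ph$edge.length <- ph$edge.length * 2
  ph
}

#' Export a linkage tree as newick and dendrogram image
#'
#' Branch lengths are merge-height differences (leaves sit at depth equal to
#' their first merge height).  The image highlights the query leaf.
#'
#' @param tree a `linkage_tree`.
#' @param highlight leaf label to mark (typically the query), or `NULL`.
#' @param newick_path optional path for the newick file.
#' @param image_path optional path for the dendrogram (`.pdf`, `.svg` or
#'   `.png` by extension).
#' @return the newick string, invisibly if any path was written.
#' @export
export_tree <- function(tree, highlight = NULL, newick_path = NULL,
                        image_path = NULL) {
  stopifnot(inherits(tree, "linkage_tree"))
  if (!is.null(highlight) && !(highlight %in% tree$labels))
    err_parameter(sprintf("unknown highlight label '%s'; valid labels: %s",
                          highlight, paste(tree$labels, collapse = ", ")))
  ph <- tree_as_phylo(tree)
  nwk <- ape::write.tree(ph)
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  if (!is.null(image_path)) {
    ext <- tolower(tools::file_ext(image_path))
    h <- max(4.8, 0.16 * length(tree$labels))
    switch(ext,
           pdf = grDevices::pdf(image_path, width = 8, height = h),
           svg = grDevices::svg(image_path, width = 8, height = h),
           png = grDevices::png(image_path, width = 960, height = 120 * h),
           err_parameter(paste("unsupported image format:", ext)))
    tipcol <- rep("black", length(tree$labels))
    if (!is.null(highlight))
      tipcol[match(highlight, ph$tip.label)] <- "red"
    ape::plot.phylo(ph, tip.color = tipcol, cex = 0.6,
                    main = "complete-linkage placement")
    grDevices::dev.off()
  }
  if (is.null(newick_path) && is.null(image_path)) nwk else invisible(nwk)
}

#' Population the query's first merge assigns it to
#'
#' Walks the merge order and finds the first merge that joins the query's
#' cluster to other leaves; if all those leaves carry the same group tag,
#' that tag is returned, otherwise `NA`.  This operationalises "the query
#' falls inside population P's clade".
#'
#' @param tree a `linkage_tree` containing the query leaf.
#' @param query_label the query's leaf label.
#' @param groups named character vector: panel label -> group tag.
#' @return a group tag or `NA_character_`.
#' @export
assign_population <- function(tree, query_label, groups) {
  qi <- match(query_label, tree$labels)
  if (is.na(qi)) err_parameter(paste("no leaf named", query_label))
  members <- vector("list", nrow(tree$merge))
  leaves_of <- function(id) if (id < 0L) -id else members[[id]]
  for (s in seq_len(nrow(tree$merge))) {
    a <- leaves_of(tree$merge[s, 1]); b <- leaves_of(tree$merge[s, 2])
    members[[s]] <- c(a, b)
    if (qi %in% members[[s]]) {
      others <- setdiff(members[[s]], qi)
      tags <- unique(groups[tree$labels[others]])
      return(if (length(tags) == 1L && !is.na(tags)) tags else NA_character_)
    }
  }
  NA_character_
}
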
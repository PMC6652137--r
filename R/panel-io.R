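# Panel archive layout (plain text, versioned, bit-exact):
#   line 1            magic "#%germplacer-panel <format_version>"
#   @meta             one JSON object: maf_threshold, n_components,
#                     min_call_rate, labels, groups, provenance
#   @sites            TSV chrom/pos/ref/alt, one row per retained site
#   @evr              one "%.17g" explained-variance ratio per line
#   @site_means       one "%.17g" value per line
#   @loadings         n_components rows of tab-separated "%.17g"
#   @scores           n_components rows of tab-separated "%.17g"
#   @end
# "%.17g" round-trips IEEE doubles exactly, so load(save(panel)) is
# bit-identical.

PANEL_FORMAT_VERSION <- 1L

fmt_num <- function(x) sprintf("%.17g", x)
fmt_rows <- function(m) apply(m, 1L, function(r) paste(fmt_num(r), collapse = "\t"))

#' Save a reference panel
#'
#' Writes the versioned plain-text panel archive.  Numeric blocks are stored
#' at full double precision so that [read_panel()] restores the panel
#' bit-exactly.
#'
#' @param panel a `reference_panel` from [fit_panel()].
#' @param path output path (conventionally `*.v2g`).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  m <- panel$model
  meta <- jsonlite::toJSON(list(
    maf_threshold = m$maf_threshold,
    n_components = m$n_components,
    min_call_rate = m$min_call_rate,
    labels = panel$labels,
    groups = panel$groups,
    provenance = panel$provenance
  ), auto_unbox = TRUE, digits = NA, null = "null")
  lines <- c(
    sprintf("#%%germplacer-panel %d", PANEL_FORMAT_VERSION),
    "@meta", as.character(meta),
    "@sites",
    paste(m$sites$chrom, m$sites$pos, m$sites$ref, m$sites$alt, sep = "\t"),
    "@evr", fmt_num(m$evr),
    "@site_means", fmt_num(m$site_means),
    "@loadings", fmt_rows(m$loadings),
    "@scores", fmt_rows(panel$scores),
    "@end")
  writeLines(lines, path)
  invisible(path)
}

#' Load a reference panel
#'
#' Reads an archive written by [write_panel()], checking the format magic and
#' version.
#'
#' @param path panel file path.
#' @return a `reference_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) err_missing(paste("panel file not found:", path))
  lines <- readLines(path)
  magic <- regmatches(lines[1],
                      regexec("^#%germplacer-panel ([0-9]+)$", lines[1]))[[1]]
  if (length(magic) != 2L)
    err_input(paste(path, "is not a germplacer panel archive"))
  version <- as.integer(magic[2])
  if (version > PANEL_FORMAT_VERSION)
    err_version(sprintf(
      "panel format version %d is newer than supported version %d",
      version, PANEL_FORMAT_VERSION))

  marks <- grep("^@", lines)
  names(marks) <- lines[marks]
  section <- function(name) {
    i <- marks[[name]]
    j <- marks[which(marks > i)[1]]
    if (i + 1L > j - 1L) character(0) else lines[(i + 1L):(j - 1L)]
  }
  meta <- jsonlite::fromJSON(paste(section("@meta"), collapse = ""))
  sites_dt <- data.table::fread(text = section("@sites"), header = FALSE,
                                sep = "\t", colClasses = list(character = 1L))
  data.table::setnames(sites_dt, c("chrom", "pos", "ref", "alt"))
  site_means <- as.numeric(section("@site_means"))
  parse_block <- function(name) {
    rows <- strsplit(section(name), "\t", fixed = TRUE)
    do.call(rbind, lapply(rows, as.numeric))
  }
  loadings <- parse_block("@loadings")
  scores <- parse_block("@scores")
  labels <- as.character(meta$labels)
  dimnames(scores) <- list(paste0("PC", seq_len(nrow(scores))), labels)

  model <- structure(
    list(sites = as.data.frame(sites_dt),
         site_means = site_means,
         loadings = loadings,
         evr = as.numeric(section("@evr")),
         maf_threshold = meta$maf_threshold,
         n_components = as.integer(meta$n_components),
         min_call_rate = meta$min_call_rate),
    class = "panel_model")
  structure(
    list(model = model, scores = scores, labels = labels,
         groups = if (is.null(meta$groups)) NULL else as.character(meta$groups),
         provenance = meta$provenance),
    class = "reference_panel")
}
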
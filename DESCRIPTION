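Package: germplacer
Title: Germplasm Identification by PCA Projection of Single-Sample VCFs
Version: 1.0.0
Authors@R: person("Plant Genomics", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compresses a multi-accession crop genotype collection into a
    low-dimensional PCA reference panel, places single-sample variant-only VCF
    queries into the panel through the pre-trained projection, and reports the
    closest accessions with a complete-linkage dendrogram. Supports incremental
    panel growth by projecting new accessions through the frozen parameters,
    plus a seeded simulator of structured germplasm collections for testing.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    ape,
    withr,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
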
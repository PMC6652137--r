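---
title: "Placing resequenced samples in a germplasm collection: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing resequenced samples in a germplasm collection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germplacer)
```

## The model

A germplasm collection of $n$ accessions genotyped at $m_0$ biallelic SNPs
is represented as a dosage matrix $X_0 \in \{0,1,2,\mathrm{NA}\}^{m_0 \times n}$
(alternate-allele counts). Panel construction is a fixed pipeline:

1. **Site filtering.** Sites with undefined or low minor-allele frequency
   ($\mathrm{MAF} < \theta$, default $\theta = 0.2$) or call rate below
   $c_{\min}$ (default 0.5) are removed, leaving $m$ sites. MAF is computed
   from non-missing calls only: $f_i = \sum_j x_{ij} / (2\,n_i)$ with $n_i$
   the non-missing count, $\mathrm{MAF}_i = \min(f_i, 1-f_i)$. The boundary
   is inclusive: $\mathrm{MAF} \ge \theta$ is retained.
2. **Imputation and centering.** Missing calls become the site mean
   $\bar{x}_i$; every site is then centered by $\bar{x}_i$. No
   unit-variance scaling is applied — scaling would up-weight the rarest
   surviving alleles, and the MAF filter already equalises informativeness.
3. **PCA.** With accessions as observations (rows of $X^\top$), a full,
   non-randomized SVD yields loadings $W$ (the top-$k$ right singular
   vectors, $k = 20$ by default) and scores $S = W\tilde{X}$. Explained
   variance ratios are $d_i^2 / \sum_j d_j^2$. The orientation matters:
   it is what lets a collection of $6\times10^4$ sites compress to a
   $20 \times n$ matrix whose columns are accession coordinates.

A query with dosage vector $q$ over the panel's $m$ sites is projected
through the *frozen* parameters, $s_q = W(q - \bar{x})$, then placed by
Euclidean distance in PC space and by complete-linkage clustering of all
panel scores plus the query.

### Why these defaults

| parameter | default | rationale |
|---|---|---|
| MAF threshold $\theta$ | 0.2 | a deliberately strong cutoff keeping only common alleles, which carry the population-structure signal a placement relies on; rarer alleles mostly add noise at this task's scale |
| components $k$ | 20 | enough to separate wild/cultivated material, sub-populations and pedigree groups in collections of a few hundred accessions, while keeping the hosted panel tiny; on a real soybean-scale collection $k=20$ captures roughly half the genotypic variance |
| call-rate floor $c_{\min}$ | 0.5 | a MAF estimated from fewer than half the accessions is unstable and the site's imputed values would be mostly invented |
| report size $k_{\mathrm{nn}}$ | 10 | a human-readable shortlist; the full ranking is available programmatically |
| linkage | complete | merge height = maximum within-cluster distance, giving compact, interpretable clades; single and average linkage are available as a switch |

## The variant-only VCF contract

Standard calling pipelines emit *variant-only* VCFs: a site identical to
the reference genome produces no record. The package therefore scores a
panel site with **no query record as dosage 0** (homozygous reference).
This is the single most consequential interpretation rule in the package:
without it a variant-only file is unreadable against a fixed site index,
and with it the absence of records is data. It is only valid when coverage
is adequate (≥ 10× resequencing); a low fraction of panel sites appearing
as records triggers a warning, not a failure, since panels differ in how
many sites a genuinely reference-like sample should hit.

Everything suspicious is scored *missing*, never silently 0: no-calls
(`./.`), half-calls (`./1`), non-diploid GTs, REF-allele mismatches, and
called alleles that are neither the panel's REF nor its ALT. Missing
dosages are imputed with the stored site means at projection time, which
collapses an all-missing profile to the panel centroid (zero scores) —
conservative by construction. Chromosome names are canonicalised (`Gm01`,
`chr1`, `01`, `1` all match) with a configurable alias table.

## The synthetic collection

`simulate_collection()` generates the world the test suite and acceptance
report run in: $P$ populations diverged at a chosen $F_{ST}$ under the
Balding–Nichols construction (population frequencies
$p_k \sim \mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$ around an
ancestral $p$ drawn uniformly from the configured MAF range), genotypes
$\mathrm{Binomial}(2, p_k)$, plus pedigree offspring (one random allele
per parent per site) and redundant duplicate accessions, with a uniform
per-call missing rate. Defaults — 3 populations, $F_{ST}=0.2$, 5000 sites,
20 accessions each, 2% missing calls — mirror a realistic crop validation
collection: wild and cultivated gene pools of a self-pollinating crop
typically show $F_{ST}$ near 0.2, and genebank collections reliably contain
duplicates and parent–offspring trios. Balding–Nichols was chosen over a
coalescent simulator because divergence is its single interpretable knob
and it needs no external dependency; the missing mask is applied *before*
duplicating redundant accessions so a duplicate is bit-identical to its
source.

What the generator does **not** emulate: linkage disequilibrium (sites are
independent), genotyping error (only missingness), reference bias, or
low-coverage allele dropout. A green identity-recovery test therefore
establishes that the pipeline is internally consistent — encoding, VCF
round-trip, projection and ranking compose to the identity — not that any
particular real collection separates cleanly; the population-assignment
test establishes separability only under independent-site divergence at
the stated $F_{ST}$.

## Numerical and design choices

- **Determinism.** Full SVD (no randomized solver); each component's sign
  is fixed so its largest-magnitude loading is positive, exact ties going
  to the lowest site index. Merge ties in `hclust` and distance ties in the
  ranking (resolved lexicographically by label) are likewise deterministic.
- **Distance metric.** Euclidean in PC space: principal components form a
  Euclidean embedding of the centered genotypes, and it agrees with the
  clustering's geometry. "Closest accession" means smallest PC-space
  distance, not dendrogram adjacency (the two agree for the first merge).
- **Distance table scope.** The ranked table reports the global top-$k$
  accessions rather than only the members of the query's cluster; the
  global list is the stricter, better-defined contract.
- **No refit on integration.** `integrate_accessions()` projects new
  accessions through the frozen loadings and appends score columns;
  existing columns are bit-identical afterwards. Refitting changes every
  coordinate and invalidates saved trees, so it is only available as an
  explicit rebuild. Label collisions get `_2`, `_3`, … suffixes with a
  warning — near-duplicate cultivar names are a documented reality of
  genebank metadata.
- **Serialization.** The panel archive is versioned plain text: a JSON
  metadata header plus `%.17g` numeric blocks, which round-trip IEEE
  doubles exactly, so loading is bit-exact and archives diff cleanly.
- **Newick convention.** Leaves sit at depth equal to their merge height
  (a two-leaf tree at height $h$ is `(A:h,B:h);`); branch lengths are
  merge-height differences.
- **Degenerate inputs.** An all-monomorphic table raises an explicit
  empty-panel error; `n_components` beyond $\min(m, n)$ names both bounds;
  a query VCF with zero panel-site overlap raises a malformed-input error
  pointing at reference-genome or chromosome-naming mismatch rather than
  returning an all-reference profile.

### Open choices resolved here

Two things a description of the published method leaves unstated were
decided as follows. Heterozygotes are scored 1 under the alternate-allele
dosage code — the standard monotone encoding. Features are centered but not
standardized, matching the default of the PCA toolchain the method's scale
(a ~0.5 summed explained-variance ratio at $k=20$) is consistent with; if a
rebuilt real-data panel misses that figure materially, the encoding should
be flagged and investigated rather than silently retuned. Redundant
accessions are *not* deduplicated before fitting — duplicates clustering at
height zero is itself a useful validation signal.

## Limitations

- GT-only: genotype likelihoods (PL/GL) are ignored, so dosage uncertainty
  at low coverage is invisible beyond the missing-call rule.
- Single-sample queries by contract; multi-sample VCFs are rejected with a
  pointer to per-sample splitting.
- Site-mean imputation only; no LD-aware imputation.
- The placement is relative to the panel: a query from material absent
  from the collection will still get a nearest neighbour, just a distant
  one. Distances are reported so that such cases are visible.
- No bootstrap support on dendrogram clades.
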
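# germplacer

Identify the closest accession in a crop germplasm collection from a
single-sample, variant-only VCF.

## The problem

Breeders and genebank curators routinely need to know *which known accession
a resequenced sample is* — to certify commercial seed, resolve mislabelled
genebank entries, recover the pedigree of a breeding line, or place a wild
collection geographically. The raw material is cheap: a standard
mapping-plus-calling pipeline turns reads into a single-sample VCF. The hard
part is comparing that VCF against a collection of hundreds of accessions
genotyped at tens of thousands of SNPs without re-running joint analyses
each time.

`germplacer` solves this by compressing the collection once into a small
**reference panel** and placing each query into it through a frozen
projection:

1. **Dosage encoding.** Diploid genotypes at biallelic SNPs become
   alternate-allele counts $x_{ij} \in \{0, 1, 2\}$ (site $i$, accession
   $j$), with missing calls tracked explicitly.
2. **MAF filtering.** Sites with minor-allele frequency below a strong
   cutoff (default $\mathrm{MAF} \ge 0.2$) or call rate below 50% are
   removed; only common alleles carry clustering signal.
3. **PCA compression.** After per-site mean imputation and centering
   ($\tilde{x}_{ij} = x_{ij} - \bar{x}_i$), a deterministic full-SVD PCA
   with accessions as observations retains $k = 20$ components. The panel
   stores the loadings $W \in \mathbb{R}^{k \times m}$, site means
   $\bar{x} \in [0,2]^m$, explained-variance ratios, and the score matrix
   $S = W\tilde{X} \in \mathbb{R}^{k \times n}$ — e.g. a 222-accession,
   61,875-site collection collapses to a 20 × 222 matrix.
4. **Query projection.** A query's dosage vector $q$ over the panel's site
   index is projected as $s_q = W(q - \bar{x})$ — no refit. Crucially, a
   panel site *absent* from a variant-only VCF is scored 0 (homozygous
   reference); no-calls and allele conflicts are scored missing and imputed
   with $\bar{x}_i$.
5. **Placement.** Accessions are ranked by Euclidean distance
   $\lVert s_q - S_{\cdot j} \rVert_2$ in PC space and the query is drawn
   into a complete-linkage dendrogram of the whole panel.

New accessions from other projects are integrated by projecting them through
the same frozen parameters (`integrate_accessions()` / `update`); refitting
is an explicit rebuild.

## Worked example

A seeded synthetic collection (3 diverged populations at FST 0.2, plus
pedigree offspring and duplicate accessions) stands in for a real
collection; one accession is written out as a variant-only VCF and queried
back:

```r
library(germplacer)

sim <- simulate_collection(sim_config(n_populations = 3, fst = 0.2,
  n_sites = 2000, n_accessions_per_pop = 10, seed = 42))
panel <- fit_panel(sim$table, maf_threshold = 0.2, n_components = 20)
panel
#> reference_panel: 34 accessions x 20 PCs (from 1360 sites, MAF >= 0.2)
#>   summed explained-variance ratio: 0.814

write_query_vcf(sim$table, "POP2_ACC03", "query.vcf")
prof <- read_query_vcf("query.vcf", panel$model)
prof
#> query_profile 'POP2_ACC03': 1360 panel sites (726 variant records,
#>   605 assumed hom-ref, 29 missing) [not projected]

prof <- project_query(panel$model, prof)
rank_distances(panel, prof, k = 5)
#> distance_report for 'POP2_ACC03' (top 5):
#>  rank      label    distance group
#>     1 POP2_ACC03 2.18155e-14  POP2
#>     2 POP2_ACC04 2.00796e+01  POP2
#>     3 POP2_ACC08 2.23752e+01  POP2
#>     4 POP2_ACC09 2.37771e+01  POP2
#>     5 POP2_ACC10 2.44004e+01  POP2
```

The query is recovered as itself at numerically-zero distance, with its
population-mates next — the coverage counters confirm that of 1360 panel
sites, 726 appeared as variant records, 605 were absent (scored homozygous
reference) and 29 were missing. `build_tree(panel, query = prof)` plus
`export_tree()` produce the newick tree and highlighted dendrogram.

The same flow is available from the command line:

```sh
Rscript exec/germplacer simulate --pops 3 --fst 0.2 --sites 2000 --per-pop 10 --seed 42 --out sim
Rscript exec/germplacer build --genotypes sim/genotypes.tsv --maf 0.2 --components 20 --out panel.v2g
Rscript exec/germplacer query --panel panel.v2g --vcf sim/queries/POP2_ACC03.vcf --out report
```

`report/` then contains `distances.tsv`, `placement.nwk` and
`placement.pdf`.

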
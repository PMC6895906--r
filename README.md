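# neurosim

Multi-layer similarity analysis for heritable diseases of the nervous
system. Given disease–mutation catalogs, cell-type marker genes, regional
brain expression, and phenotype-similarity scores, `neurosim` asks on three
layers how alike two diseases are — and whether each layer tracks clinical
phenotype:

1. **Genes.** For each pair of diseases with gene sets $A, B$ in a universe
   $U$, a 2×2 membership table ($a = |A \cap B|$, $b = |A \setminus B|$,
   $c = |B \setminus A|$, $d = |U| - a - b - c$) is tested with the Pearson
   chi-square on 1 df; the effect size is the proportion of shared genes
   $|A \cap B| / \min(|A|, |B|)$.
2. **Cell types.** Each disease gene set is tested for enrichment in every
   cell subtype's marker set by a two-tailed Fisher exact test and scored by
   $N_{overlap} / (N_{G1} \times N_{G2})$; the score vector over all
   subtypes is the disease's enrichment profile.
3. **Brain regions.** Per-region "highly expressed" gene sets are called
   from a gene × sample matrix (region-vs-rest moderated-t contrast; a gene
   qualifies at fold change ≥ 2 with p < 0.05), then treated exactly like
   marker sets in layer 2.

Profiles are compared with the asymmetric binary ("Jaccard-type") distance
— the fraction of discordant positions among positions where at least one
profile is nonzero — and disease pairs are ranked by it. Finally, each
similarity layer is correlated with averaged phenotype-network scores
(Pearson for the shared-gene proportion, Spearman for profile distances),
with a ranked three-group comparison by Welch t-tests.

The package is aimed at researchers assembling disease–gene catalogs who
want a reproducible, tested path from mutation tables to cross-layer
similarity statements, without any network access: a synthetic-cohort
module generates all five input kinds with planted ground truth.

## Worked example

Everything below runs offline from a simulated study-scale bundle
(20 diseases, 424-gene universe, 25 cell-type contexts, 10 brain regions):

```r
library(neurosim)

cfg   <- sim_config(seed = 7)
paths <- simulate_bundle(cfg, "bundle")
res   <- run_pipeline(paths["curated"], paths["clinvar"], paths["markers"],
                      paths["expression"], paths["regions"], paths["phenotype"],
                      out_dir = "out")

res$merged$summary
#> mutations: 679 curated + 350 clinvar - 172 shared = 857 combined (ratio 1.9)
#> genes:     318 curated + 224 clinvar - 200 shared = 342 combined (ratio 1.4)
#>            78 genes linked to >=2 diseases, 264 to exactly 1

res$genetic_gene$n_significant
#> [1] 12

head(res$rank_cell, 3)
#>   disease_a disease_b distance rank
#> 1 disease07 disease09    0.250    1
#> 2 disease10 disease19    0.375    2
#> 3 disease01 disease03    0.400    3

str(res$correlations$gene_pearson[c("estimate", "p_value", "n")])
#> List of 3
#>  $ estimate: num 0.54
#>  $ p_value : num 8.65e-16
#>  $ n       : int 190
```

Reading the output: the merge de-duplicates variants by
`(chrom, pos, ref, alt)` and reports inclusion–exclusion accounting; 12 of
the 190 disease pairs share significantly many genes — exactly the 12 pairs
the simulation planted (four disease triads sharing 8, 7, 6 and 5 genes
pairwise); the closest cell-type profiles belong to planted triad members;
and the shared-gene proportion correlates positively (r = 0.54) with the
planted phenotype scores. `out/` contains every intermediate TSV, a
`summary.json`, and a `log.txt` recording defaulted analysis decisions.

Real inputs go through the same readers: `read_mutation_table()` (TSV),
`read_marker_gmt()` (GMT), `read_expression()` (matrix + region map TSVs),
`read_phenotype_scores()` (TSV, with an optional disease-synonym map).

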
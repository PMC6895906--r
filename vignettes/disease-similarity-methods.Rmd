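---
title: "Methods: multi-layer similarity of nervous-system diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-layer similarity of nervous-system diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurosim)
```

## The problem

Heritable diseases of the nervous system frequently co-occur or present with
overlapping symptoms, and one mechanism behind this is shared genetics: the
same pathogenic gene, sometimes the same variant, implicated in two diseases.
`neurosim` quantifies how similar two diseases are on three layers --

1. **genes**: do two diseases share more mutation-bearing genes than chance?
2. **cell types**: are the two disease gene sets enriched in the same
   cell subtypes of a single-cell marker reference?
3. **brain regions**: are they enriched among the same regions'
   highly-expressed genes?

-- and relates each layer to an external *phenotypic* similarity score per
disease pair (a disease-manifestation network score; higher = more similar
clinical presentation). The package operates downstream of curation: inputs
are disease-mutation tables (coordinates already normalized to one genome
build), marker-gene catalogs (GMT), an expression matrix with a
sample-to-region map, and a phenotype-score table.

## Catalog merge

Two mutation tables (a curated literature catalog and a ClinVar-style
extract) are merged with `merge_catalogs()`. Mutation identity is the
`(chrom, pos, ref, alt)` tuple and deliberately excludes the disease label:
one variant recorded for two diseases counts once in mutation totals but
contributes to both disease gene sets. Gene identity is the symbol,
case-sensitive after whitespace trimming, with no alias resolution. All
counts obey inclusion-exclusion (`union = a + b - shared`), ratios are
rounded half away from zero to one decimal, and conflicting pathogenicity
annotations are kept as separate rows rather than adjudicated. The merged
catalog's gene union is always the exact inclusion-exclusion value of its
inputs; the package never forces it to an externally stated total.

## Layer 1: genetic similarity

For every unordered disease pair, `shared_set_test()` forms the 2x2
membership table over the gene universe
($a$ = shared, $b$/$c$ = private, $d$ = rest) and computes the Pearson
chi-square statistic on 1 df, no continuity correction by default (a Yates
flag exists; the choice is recorded in the pipeline log). The universe
defaults to the union of all disease gene sets in the catalog and may be
replaced by a genome-wide list. Alongside the test, the *proportion of
shared genes* $|A \cap B| / \min(|A|, |B|)$ is the effect-size measure
carried into the phenotype correlation. Mutation-level screening reuses the
same machinery on variant-key sets (`mutation_catalog()`).

Two caveats are part of the method, not the implementation. First, at
catalog scale (20 diseases of ~21 genes on a 424-gene universe) the 2x2
tables are sparse and discrete: by exact hypergeometric enumeration the
chi-square test at nominal $\alpha = 0.05$ has true size 0.078 under
independent sets (the smallest significant overlap is 3 genes). The test
suite verifies the implementation reproduces this *exact* size; users should
read "p < 0.05" at this scale as approximate. Second, the headline
significance call uses raw p-values with a 0.05 cutoff; a
Benjamini-Hochberg column is emitted for users who prefer FDR control
across the 190 pairs.

## Layers 2 and 3: enrichment profiles

Enrichment of a disease gene set in one context (cell subtype or region)
uses the two-tailed Fisher exact test over a background universe, with the
minimum-likelihood two-tail convention: the p-value sums all hypergeometric
overlap outcomes whose probability does not exceed the observed one (a
$1 + 10^{-7}$ relative tolerance absorbs floating-point ties, matching
standard exact-test practice). The background defaults to the union of all
marker genes; disease genes outside it are ignored, and a disease with no
genes in the background yields an all-zero profile with a warning.

Each disease-context cell also gets the enrichment score

$$ \mathrm{score} = \frac{N_{overlap}}{N_{G1} \times N_{G2}}, $$

the overlap count divided by the product of the two set sizes; a disease's
*profile* is its score vector over all contexts in catalog order.

Region "marker" sets are not read from a file but called from expression
data: `region_contrast()` tests each gene region-versus-rest, and a gene is
*highly expressed* in a region when its expression is at least one time
(100%) higher than the average of all other regions -- fold change $\geq 2$,
log2 difference $\geq 1$, boundary inclusive -- with two-sided $p < \alpha$.
"Average of the other regions" is the pooled mean over all non-region
samples; the mean-of-region-means alternative is available by flag.
Two-sided p-values are used because the fold filter supplies the direction.

The contrast t statistic is moderated by default: per-gene pooled variances
$s_g^2$ on $d$ df are shrunk toward a prior, $\tilde{s}_g^2 = (d_0 s_0^2 +
d s_g^2)/(d_0 + d)$, with $(d_0, s_0^2)$ estimated by method of moments on
$\log s_g^2$ under the scaled inverse chi-square hierarchical model, and the
moderated t referred to $d + d_0$ df. Two limits anchor the implementation:
$d_0 \to \infty$ makes all moderated variances equal $s_0^2$, and $d_0 = 0$
recovers the ordinary pooled t (`moderation = "plain"`). The test suite
cross-checks the moderated statistics against an independent
empirical-Bayes implementation on a heterogeneous-variance fixture. The
trigamma inversion in the moment fit uses Newton iteration on
$1/\psi_1$, converging to $10^{-8}$ relative accuracy.

## Profile distance and ranking

Profiles are compared with the asymmetric binary distance: entries are
binarized as nonzero/zero and the distance is the fraction of discordant
positions among positions where at least one profile is nonzero; zero-zero
positions carry no information and are ignored. If neither profile has a
nonzero entry the distance is *undefined* (`NA`), excluded from rankings and
correlations, and reported separately. Binarization is on a nonzero *score*
(any overlap) by default -- the distance is then invariant to any positive
rescaling of the scores -- with `binarize = "significant"` available to
threshold on the Fisher-test flag instead. Pair rankings are ascending by
distance with lexicographic tie-breaks for reproducibility. No p-value is
attached to a distance: the package defines no sampling model for it.

## Phenotype comparison

A disease pair may match several phenotype-network entries; its score is
their arithmetic mean, pooling order-swapped duplicates
(`average_phenotype()`). The genetic layer is compared by Pearson
correlation of the shared-gene proportion with the score; the profile
layers by Spearman correlation of distance with score (exact rank p at
small tie-free n, asymptotic otherwise). Ranked pairs are additionally
split into three groups -- the $k$ lowest-distance pairs, a middle rank
band, the $k$ highest (defaults $k = 20$, middle 21-51, matching a 71-pair
scored set) -- and group means are compared with Welch two-sample t-tests
(the unequal-variance form; the method source says only "t-test", so the
robust default is used and logged). Pairs missing a phenotype score are
dropped with the retained n always reported.

## The synthetic cohort

`sim_config()` fixes the study conditions for all tests; every generator is
driven by a named substream of one root seed, so identical configurations
give byte-identical bundles and each input kind can be regenerated
independently. Defaults:

* **Catalog**: 20 diseases x 21 genes on a 424-gene universe. Four disease
  triads share 8, 7, 6 and 5 genes pairwise (12 overlapping pairs of 190),
  emulating the dense sharing real catalogs show. Allocation is
  constructive -- shared blocks first from a permuted universe, then unique
  fills from globally unused genes -- so realized overlaps equal the planted
  matrix exactly and recovery tests are deterministic given the seed. The
  smallest planted overlap (5 of 21 on 424) has exact chi-square
  $p \approx 4 \times 10^{-5}$, so "every planted pair significant" is not a
  boundary case. `overlaps = NULL` switches to independent uniform sets (the
  null configuration for calibration).
* **Markers**: 25 contexts x 50 genes drawn from a 5000-gene marker
  universe whose first 424 genes are the disease universe. The marker
  universe is deliberately larger than the disease universe: real marker
  catalogs span genome-wide genes, and drawing 1250 marker slots from only
  424 genes would make nearly every disease-context overlap nonzero,
  collapsing all binary distances toward zero. Each triad is planted (half
  of each member's genes) in one common context; every remaining disease in
  a private context.
* **Expression**: 2000 genes x 10 regions x 10 samples; baseline log2
  expression $\mathcal{N}(5, 1)$ per gene, noise sd 0.5 per sample, one
  planted gene per region at log2 fold 3 (estimate se $\approx 0.17$, far
  from the fold-2 boundary).
* **Phenotype**: per pair, each of 2 matchings scores
  $\max(0, 0.05 \cdot \mathrm{proportion~shared} + \mathcal{N}(0, 0.01))$,
  putting averages on the ~0.02-0.03 scale typical of
  disease-manifestation-network scores.

What the generator does *not* emulate: probe-level microarray structure,
batch or covariate effects, realistic single-cell counts, gene-symbol
aliasing, or semantic phenotype matching. Passing recovery tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to those real-data complications.

## Calibration and problem sizes

The test suite checks, at fixed seeds: exact-test equivalence against
exhaustive enumeration (all Fisher tables with background $\leq 40$; all
chi-square tables with cells $\leq 5$; all binary profile pairs of length
$\leq 6$); planted-signal recovery on 100 replicates of the default cohort
(each recovery property must hold in $\geq 95\%$); and null calibration on
400 replicates with no planted signal. Null calibration of the region
contrast uses `moderation = "plain"` (exact finite-sample t null) and
measures the p-value rate: the compound high-expression flag is
intentionally conservative under the null, because the fold filter is an
effect-size gate and the flag is directional while the p-value is
two-sided, so the *test's* calibration is the meaningful check. The genetic
screen's null rate is checked against both the nominal level and the exact
discrete size; at this sparse geometry only the latter can hold (see Layer
1), and the suite records this honestly rather than widening the band.

## Known limitations

* The chi-square screen inherits the small-expected-count behaviour
  discussed above; a Fisher-exact alternative for the gene-sharing layer
  would calibrate exactly but is not what the method prescribes.
* Enrichment significance is sensitive to the background choice; the
  marker-union default is conventional but conservative relative to a
  genome-wide background.
* The binary distance discards all magnitude information by construction;
  two profiles overlapping the same contexts weakly and strongly are
  indistinguishable.
* Disease-name matching across catalogs relies on normalization plus an
  explicit user-supplied synonym map; no semantic matching is attempted.
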
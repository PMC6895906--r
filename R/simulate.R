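# Synthetic cohort generator. Defaults emulate the scale of the real study
# conditions: 20 diseases over a 424-gene universe, 25 cell-type contexts,
# 10 brain regions. Every generator plants known ground truth (exact pairwise
# overlaps, enrichment memberships, region fold changes, a monotone
# phenotype-score link) so each pipeline stage has a recovery test. A single
# root seed drives all sub-generators through named substreams, so any one
# input kind can be regenerated independently.

# four disease triads with within-triad pairwise sharing (12 overlapping
# pairs of 190), emulating the dense sharing structure real catalogs show;
# each disease spends at most 16 of its 21 genes on shared blocks
default_overlaps <- function() {
  triad <- function(d, o) data.frame(i = d[c(1, 1, 2)], j = d[c(2, 3, 3)],
                                     overlap = o)
  rbind(triad(1:3, 8), triad(4:6, 7), triad(7:9, 6), triad(10:12, 5))
}

# all members of one triad are planted in a common context, so cell-type
# profiles co-vary with gene sharing as in the real data; the remaining
# diseases each get a private context
default_planting <- function() {
  data.frame(disease = 1:20,
             context = c(rep(1:4, each = 3), 5:12),
             fraction = 0.5)
}

default_region_effects <- function(n_regions = 10, log2_fold = 3) {
  data.frame(gene = seq_len(n_regions), region = seq_len(n_regions),
             log2_fold = log2_fold)
}

#' Configuration for the synthetic cohort
#'
#' Bundles all generator parameters with their study-condition defaults:
#' 20 diseases of 21 genes each on a 424-gene universe, with four planted
#' disease triads sharing 8, 7, 6 and 5 genes pairwise (12 overlapping pairs
#' out of 190); 25 marker contexts of 50 genes drawn from a 5000-gene
#' expression-wide universe whose head is the disease universe, each triad
#' enriched (half of each member's genes) in a common context and every
#' remaining disease in a private context; 10 regions times 10 samples over 2000
#' expression genes with one planted gene per region at log2 fold 3 and
#' sample noise sd 0.5; phenotype scores generated as
#' `max(0, slope * proportion_shared + noise)` with slope 0.05 and noise sd
#' 0.01, two matchings per pair (matching the ~0.02-0.03 score scale of real
#' phenotype-network averages).
#'
#' @param seed root integer seed; substreams are derived per generator.
#' @param n_diseases,universe_size,genes_per_disease catalog dimensions.
#' @param overlaps data frame `i, j, overlap` of planted pairwise shared-gene
#'   counts (disease indices), or `NULL` for independent sampling with no
#'   planted structure (the null configuration).
#' @param n_contexts,markers_per_context,marker_universe_size marker-catalog
#'   dimensions; the marker universe contains the disease universe as its
#'   first `universe_size` genes.
#' @param planted_enrichment data frame `disease, context, fraction` (indices
#'   and the fraction of that disease's genes placed in that context's
#'   markers), or `NULL` for none.
#' @param n_regions,samples_per_region,n_genes_expr expression dimensions.
#' @param region_effects data frame `gene, region, log2_fold` of planted
#'   region-specific effects (indices into expression genes/regions), or
#'   `NULL` for none.
#' @param noise_sd per-sample expression noise sd on the log2 scale.
#' @param dmn_slope,dmn_noise_sd,dmn_matchings phenotype-score generator:
#'   slope on the planted proportion of shared genes, additive Gaussian noise
#'   sd, and number of matchings recorded per pair.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_diseases = 20, universe_size = 424,
                       genes_per_disease = 21,
                       overlaps = default_overlaps(),
                       n_contexts = 25, markers_per_context = 50,
                       marker_universe_size = 5000,
                       planted_enrichment = default_planting(),
                       n_regions = 10, samples_per_region = 10,
                       n_genes_expr = 2000,
                       region_effects = default_region_effects(n_regions),
                       noise_sd = 0.5,
                       dmn_slope = 0.05, dmn_noise_sd = 0.01,
                       dmn_matchings = 2) {
  cfg <- list(seed = as.integer(seed), n_diseases = n_diseases,
              universe_size = universe_size,
              genes_per_disease = genes_per_disease, overlaps = overlaps,
              n_contexts = n_contexts,
              markers_per_context = markers_per_context,
              marker_universe_size = marker_universe_size,
              planted_enrichment = planted_enrichment,
              n_regions = n_regions, samples_per_region = samples_per_region,
              n_genes_expr = n_genes_expr, region_effects = region_effects,
              noise_sd = noise_sd, dmn_slope = dmn_slope,
              dmn_noise_sd = dmn_noise_sd, dmn_matchings = dmn_matchings)
  counts <- c(cfg$n_diseases, cfg$universe_size, cfg$genes_per_disease,
              cfg$n_contexts, cfg$markers_per_context,
              cfg$marker_universe_size, cfg$n_regions,
              cfg$samples_per_region, cfg$n_genes_expr, cfg$dmn_matchings)
  stopifnot(all(counts >= 1), cfg$noise_sd >= 0, cfg$dmn_noise_sd >= 0,
            is.finite(cfg$dmn_slope),
            cfg$marker_universe_size >= cfg$universe_size)
  if (!is.null(cfg$planted_enrichment))
    stopifnot(all(cfg$planted_enrichment$fraction >= 0),
              all(cfg$planted_enrichment$fraction <= 1))
  structure(cfg, class = "sim_config")
}

sim_gene_names <- function(cfg) sprintf("G%05d", seq_len(cfg$marker_universe_size))
sim_disease_names <- function(cfg) sprintf("disease%02d", seq_len(cfg$n_diseases))

#' Generate a disease catalog with exact planted overlaps
#'
#' Constructive allocation: each planted pair's shared block is assigned
#' first from a permuted universe, then every disease is filled to size with
#' globally unused genes, so realized pairwise overlaps equal the planted
#' matrix *exactly* (unplanted pairs share nothing). With `overlaps = NULL`
#' every disease samples its genes independently and uniformly from the
#' universe (random hypergeometric overlaps; the null configuration).
#'
#' @param cfg a [sim_config()].
#' @return list with `catalog` (a [disease_catalog()]) and `truth` (data
#'   frame of all pairwise realized overlaps and proportions).
#' @export
gen_disease_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, "disease_catalog"))
  universe <- sim_gene_names(cfg)[seq_len(cfg$universe_size)]
  dz <- sim_disease_names(cfg)
  size <- rep(cfg$genes_per_disease, cfg$n_diseases)

  sets <- stats::setNames(rep(list(character(0)), cfg$n_diseases), dz)
  if (is.null(cfg$overlaps)) {
    for (k in seq_len(cfg$n_diseases))
      sets[[k]] <- sample(universe, size[k])
  } else {
    ov <- cfg$overlaps
    stopifnot(all(ov$i != ov$j), all(ov$overlap >= 0))
    for (r in seq_len(nrow(ov)))
      if (ov$overlap[r] > min(size[ov$i[r]], size[ov$j[r]]))
        stop(sprintf("planted overlap for pair (%d,%d) exceeds a set size",
                     ov$i[r], ov$j[r]))
    per_disease <- tapply(c(ov$overlap, ov$overlap), c(ov$i, ov$j), sum)
    over <- as.integer(names(per_disease))[per_disease > size[as.integer(names(per_disease))]]
    if (length(over))
      stop("planted overlaps exceed the gene quota of disease ", over[1])
    need <- sum(size) - sum(ov$overlap)
    if (need > cfg$universe_size)
      stop("universe too small for the requested allocation")
    pool <- sample(universe)
    take <- function(n) {
      if (n == 0) return(character(0))
      g <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; g
    }
    for (r in seq_len(nrow(ov))) {
      block <- take(ov$overlap[r])
      sets[[ov$i[r]]] <- c(sets[[ov$i[r]]], block)
      sets[[ov$j[r]]] <- c(sets[[ov$j[r]]], block)
    }
    for (k in seq_len(cfg$n_diseases))
      sets[[k]] <- c(sets[[k]], take(size[k] - length(sets[[k]])))
  }
  catalog <- disease_catalog(sets, universe = universe)

  pairs <- enumerate_pairs(dz)
  pairs$overlap <- mapply(function(a, b)
    length(intersect(sets[[a]], sets[[b]])),
    pairs$disease_a, pairs$disease_b)
  pairs$proportion <- mapply(function(a, b)
    proportion_shared(sets[[a]], sets[[b]]),
    pairs$disease_a, pairs$disease_b)
  pairs$planted <- FALSE
  if (!is.null(cfg$overlaps)) {
    planted_key <- pair_key(dz[cfg$overlaps$i], dz[cfg$overlaps$j])
    pairs$planted <- pair_key(pairs$disease_a, pairs$disease_b) %in%
      planted_key[cfg$overlaps$overlap > 0]
  }
  list(catalog = catalog, truth = pairs)
}

#' Generate a marker catalog with planted enrichment
#'
#' For each planted `(disease, context, fraction)` row, `ceiling(fraction *
#' set size)` of that disease's genes are placed in the context's marker set;
#' the remainder of each marker set is drawn without replacement from the
#' marker universe (a superset of the disease universe -- marker catalogs
#' span far more genes than any disease catalog, which keeps random
#' disease-context overlaps sparse). Background is the union of all marker
#' sets, as for a catalog read from GMT.
#'
#' @param cfg a [sim_config()].
#' @param catalog the [disease_catalog()] from [gen_disease_catalog()].
#' @return list with `markers` (a [marker_catalog()]) and `truth` (planted
#'   memberships: disease, context, genes planted).
#' @export
gen_marker_catalog <- function(cfg, catalog) {
  stopifnot(inherits(cfg, "sim_config"), inherits(catalog, "disease_catalog"))
  set.seed(substream_seed(cfg$seed, "marker_catalog"))
  muniverse <- sim_gene_names(cfg)
  ctx <- sprintf("celltype%02d", seq_len(cfg$n_contexts))
  planted <- stats::setNames(rep(list(character(0)), cfg$n_contexts), ctx)
  truth <- list()
  pe <- cfg$planted_enrichment
  if (!is.null(pe)) {
    for (r in seq_len(nrow(pe))) {
      dz <- catalog$diseases[pe$disease[r]]
      genes <- catalog$gene_sets[[dz]]
      n_pl <- ceiling(pe$fraction[r] * length(genes))
      pick <- if (n_pl > 0) sample(genes, n_pl) else character(0)
      k <- pe$context[r]
      planted[[k]] <- union(planted[[k]], pick)
      truth[[length(truth) + 1]] <- data.frame(
        disease = dz, context = ctx[k], n_planted = n_pl,
        stringsAsFactors = FALSE)
    }
  }
  over <- which(lengths(planted) > cfg$markers_per_context)
  if (length(over))
    stop("planted genes exceed markers_per_context in context ", ctx[over[1]])
  sets <- lapply(planted, function(p) {
    fill <- sample(setdiff(muniverse, p), cfg$markers_per_context - length(p))
    c(p, fill)
  })
  list(markers = marker_catalog(sets),
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Generate an expression study with planted region effects
#'
#' Per-gene baseline log2 expression ~ Normal(5, 1); planted
#' `(gene, region, log2_fold)` effects are added to the region's samples;
#' i.i.d. Normal(0, `noise_sd`) noise per sample. Gene names are the head of
#' the simulation's gene namespace, so they overlap the disease universe and
#' region highly-expressed sets can be used for disease enrichment.
#'
#' @param cfg a [sim_config()].
#' @return list with `study` (an [expression_study()], log2 scale) and
#'   `truth` (planted effects with gene/region names).
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, "expression"))
  genes <- sim_gene_names(cfg)[seq_len(cfg$n_genes_expr)]
  regions <- sprintf("region%02d", seq_len(cfg$n_regions))
  n_samp <- cfg$n_regions * cfg$samples_per_region
  samples <- sprintf("S%04d", seq_len(n_samp))
  region_of <- stats::setNames(rep(regions, each = cfg$samples_per_region),
                               samples)
  baseline <- stats::rnorm(length(genes), mean = 5, sd = 1)
  mat <- matrix(baseline, nrow = length(genes), ncol = n_samp,
                dimnames = list(genes, samples))
  truth <- NULL
  re <- cfg$region_effects
  if (!is.null(re)) {
    stopifnot(all(re$gene <= cfg$n_genes_expr), all(re$region <= cfg$n_regions))
    for (r in seq_len(nrow(re))) {
      cols <- region_of == regions[re$region[r]]
      mat[re$gene[r], cols] <- mat[re$gene[r], cols] + re$log2_fold[r]
    }
    truth <- data.frame(gene = genes[re$gene], region = regions[re$region],
                        log2_fold = re$log2_fold, stringsAsFactors = FALSE)
  }
  mat <- mat + matrix(stats::rnorm(length(mat), sd = cfg$noise_sd),
                      nrow = nrow(mat))
  list(study = expression_study(mat, region_of, scale = "log2"),
       truth = truth)
}

#' Generate phenotype scores linked to planted genetic similarity
#'
#' For every disease pair, each of `dmn_matchings` recorded scores is
#' `max(0, dmn_slope * proportion_shared + Normal(0, dmn_noise_sd))`, where
#' the proportion is the realized shared-gene proportion of the generated
#' catalog. Multiple matchings exercise the downstream averaging.
#'
#' @param cfg a [sim_config()].
#' @param catalog_truth the `truth` pair table from [gen_disease_catalog()].
#' @return a `phenotype_scores` data frame.
#' @export
gen_phenotype_scores <- function(cfg, catalog_truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, "phenotype"))
  n <- nrow(catalog_truth)
  rows <- do.call(rbind, lapply(seq_len(cfg$dmn_matchings), function(m) {
    data.frame(disease_a = catalog_truth$disease_a,
               disease_b = catalog_truth$disease_b,
               score = pmax(0, cfg$dmn_slope * catalog_truth$proportion +
                              stats::rnorm(n, sd = cfg$dmn_noise_sd)),
               stringsAsFactors = FALSE)
  }))
  class(rows) <- c("phenotype_scores", "data.frame")
  rows
}

#' Generate curated and ClinVar-style mutation tables realizing a catalog
#'
#' Each (disease, gene) association receives `1 + Poisson(1)` distinct
#' variants with random hg19-style coordinates; each variant is assigned to
#' the curated table only, the ClinVar-style table only, or both (so the
#' merge step sees shared and source-specific records). Merging the two
#' tables reproduces the catalog exactly.
#'
#' @param cfg a [sim_config()].
#' @param catalog the [disease_catalog()] to realize.
#' @return list of two mutation-record data frames, `curated` and `clinvar`.
#' @export
gen_mutation_tables <- function(cfg, catalog) {
  stopifnot(inherits(cfg, "sim_config"), inherits(catalog, "disease_catalog"))
  set.seed(substream_seed(cfg$seed, "mutations"))
  assoc <- do.call(rbind, lapply(catalog$diseases, function(dz)
    data.frame(disease = dz, gene = catalog$gene_sets[[dz]],
               stringsAsFactors = FALSE)))
  # one fixed locus per gene so the same gene always maps to one chromosome
  genes <- unique(assoc$gene)
  chrom <- stats::setNames(as.character(sample(1:22, length(genes), TRUE)), genes)
  base <- stats::setNames(sample.int(2e8, length(genes)) + 1e6, genes)
  nt <- c("A", "C", "G", "T")
  rows <- lapply(seq_len(nrow(assoc)), function(i) {
    g <- assoc$gene[i]
    n_mut <- 1 + stats::rpois(1, 1)
    pos <- base[[g]] + sample.int(5000, n_mut)
    ref <- sample(nt, n_mut, TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
    data.frame(disease = assoc$disease[i], gene = g, build = "hg19",
               chrom = chrom[[g]], pos = pos, ref = ref, alt = alt,
               source = "curated",
               pathogenicity = sample(c("pathogenic", "likely_pathogenic"),
                                      n_mut, TRUE, prob = c(0.8, 0.2)),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  dest <- sample(c("curated", "clinvar", "both"), nrow(all), TRUE,
                 prob = c(0.6, 0.2, 0.2))
  # every disease-gene link must survive in the union; it does, since each
  # record lands in at least one table
  curated <- all[dest != "clinvar", , drop = FALSE]
  clinvar <- all[dest != "curated", , drop = FALSE]
  clinvar$source <- "clinvar"
  rownames(curated) <- rownames(clinvar) <- NULL
  list(curated = curated, clinvar = clinvar)
}

#' Write the full five-file synthetic input bundle
#'
#' Generates all input kinds from one configuration and writes them in the
#' formats the readers expect: `curated.tsv` and `clinvar.tsv` (mutation
#' tables), `markers.gmt`, `expression.tsv` plus `regions.tsv` (sample-to-
#' region map), `phenotype.tsv`, and `truth.json` (planted ground truth).
#' Identical configurations (including the seed) produce byte-identical
#' bundles.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
simulate_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dz <- gen_disease_catalog(cfg)
  mk <- gen_marker_catalog(cfg, dz$catalog)
  ex <- gen_expression(cfg)
  ph <- gen_phenotype_scores(cfg, dz$truth)
  mt <- gen_mutation_tables(cfg, dz$catalog)

  paths <- c(
    curated = file.path(dir, "curated.tsv"),
    clinvar = file.path(dir, "clinvar.tsv"),
    markers = file.path(dir, "markers.gmt"),
    expression = file.path(dir, "expression.tsv"),
    regions = file.path(dir, "regions.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_mutation_table(mt$curated, paths["curated"])
  write_mutation_table(mt$clinvar, paths["clinvar"])
  write_marker_gmt(mk$markers, paths["markers"])
  expr_df <- data.frame(gene = rownames(ex$study$values),
                        ex$study$values, check.names = FALSE)
  write_tsv(expr_df, paths["expression"])
  write_tsv(data.frame(sample = names(ex$study$region_of),
                       region = unname(ex$study$region_of)),
            paths["regions"])
  write_tsv(ph, paths["phenotype"])
  truth <- list(
    pairs = dz$truth,
    planted_enrichment = mk$truth,
    region_effects = ex$truth,
    config = unclass(cfg)
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(paths)
}

#' Construct synthetic mutation tables with prescribed marginal counts
#'
#' Builds a deterministic pair of curated/ClinVar-style tables realizing
#' given per-source mutation and gene counts and shared-mutation /
#' shared-gene counts, so the merge accounting can be exercised at any
#' published scale without the underlying data. Variants are laid out on
#' sequential coordinates; genes are assigned round-robin so every gene
#' appears at least once; the shared variants carry the same gene and
#' coordinates in both tables. Defaults are the scale of the real study:
#' 1607 mutations / 365 genes curated, 837 / 114 ClinVar, 10 shared
#' mutations, 54 shared genes, 20 diseases.
#'
#' @param n_mut_curated,n_gene_curated curated table dimensions.
#' @param n_mut_clinvar,n_gene_clinvar ClinVar-style table dimensions.
#' @param n_mut_shared,n_gene_shared counts common to the two tables.
#' @param n_diseases number of disease labels to cycle over.
#' @return list of two mutation-record data frames, `curated` and `clinvar`.
#' @export
gen_sized_mutation_tables <- function(n_mut_curated = 1607,
                                      n_gene_curated = 365,
                                      n_mut_clinvar = 837,
                                      n_gene_clinvar = 114,
                                      n_mut_shared = 10,
                                      n_gene_shared = 54,
                                      n_diseases = 20) {
  stopifnot(n_mut_shared <= min(n_mut_curated, n_mut_clinvar),
            n_gene_shared <= min(n_gene_curated, n_gene_clinvar),
            n_mut_curated >= n_gene_curated,
            n_mut_clinvar >= n_gene_clinvar,
            n_mut_shared >= 0, n_mut_shared <= n_gene_shared)
  genes_cur <- sprintf("GC%04d", seq_len(n_gene_curated))
  genes_clv <- c(genes_cur[seq_len(n_gene_shared)],
                 sprintf("GV%04d", seq_len(n_gene_clinvar - n_gene_shared)))
  dz <- sprintf("disease%02d", seq_len(n_diseases))
  cycle <- function(x, n) x[((seq_len(n) - 1) %% length(x)) + 1]
  mk <- function(pos, gene, disease, source) data.frame(
    disease = disease, gene = gene, build = "hg19", chrom = "1", pos = pos,
    ref = "A", alt = "G", source = source, pathogenicity = "pathogenic",
    stringsAsFactors = FALSE)
  # curated variants occupy positions 1..n_mut_curated; the first
  # n_mut_shared also appear in the clinvar table with identical fields
  curated <- mk(seq_len(n_mut_curated), cycle(genes_cur, n_mut_curated),
                cycle(dz, n_mut_curated), "curated")
  n_new <- n_mut_clinvar - n_mut_shared
  clinvar <- rbind(
    mk(seq_len(n_mut_shared), curated$gene[seq_len(n_mut_shared)],
       curated$disease[seq_len(n_mut_shared)], "clinvar"),
    mk(n_mut_curated + seq_len(n_new), cycle(genes_clv, n_new),
       cycle(dz, n_new), "clinvar")
  )
  list(curated = curated, clinvar = clinvar)
}
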
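test_that("planted overlaps are realized exactly by construction", {
  cfg <- sim_config(seed = 3, n_diseases = 3, universe_size = 60,
                    genes_per_disease = 10,
                    overlaps = data.frame(i = 1, j = 2, overlap = 5),
                    planted_enrichment = NULL, region_effects = NULL)
  dz <- gen_disease_catalog(cfg)
  g <- dz$catalog$gene_sets
  expect_equal(length(intersect(g$disease01, g$disease02)), 5)
  expect_equal(length(intersect(g$disease01, g$disease03)), 0)
  expect_equal(length(intersect(g$disease02, g$disease03)), 0)
  expect_equal(dz$truth$overlap[dz$truth$planted], 5)

  # all-zero / absent overlap rows give mutually disjoint sets
  cfg0 <- sim_config(seed = 3, n_diseases = 4, universe_size = 100,
                     genes_per_disease = 10,
                     overlaps = data.frame(i = 1, j = 2, overlap = 0),
                     planted_enrichment = NULL, region_effects = NULL)
  t0 <- gen_disease_catalog(cfg0)$truth
  expect_true(all(t0$overlap == 0))

  # infeasible allocations are rejected with the offending pair named
  bad <- sim_config(seed = 3, n_diseases = 3, universe_size = 60,
                    genes_per_disease = 4,
                    overlaps = data.frame(i = 1, j = 2, overlap = 5),
                    planted_enrichment = NULL, region_effects = NULL)
  expect_error(gen_disease_catalog(bad), "\\(1,2\\)")
  cramped <- sim_config(seed = 3, n_diseases = 5, universe_size = 20,
                        genes_per_disease = 10, overlaps = NULL,
                        planted_enrichment = NULL, region_effects = NULL)
  expect_silent(gen_disease_catalog(cramped))  # independent mode may reuse genes
  packed <- sim_config(seed = 3, n_diseases = 5, universe_size = 20,
                       genes_per_disease = 10,
                       overlaps = data.frame(i = 1, j = 2, overlap = 2),
                       planted_enrichment = NULL, region_effects = NULL)
  expect_error(gen_disease_catalog(packed), "universe too small")
})

test_that("identical configurations reproduce byte-identical bundles", {
  cfg <- sim_config(seed = 11, n_diseases = 6, universe_size = 80,
                    genes_per_disease = 8,
                    overlaps = data.frame(i = 1, j = 2, overlap = 4),
                    n_contexts = 5, markers_per_context = 10,
                    marker_universe_size = 300, n_genes_expr = 50,
                    planted_enrichment = data.frame(disease = 1, context = 1,
                                                    fraction = 0.5),
                    region_effects = default_region_effects(10, 3))
  d1 <- file.path(tempdir(), "b1"); d2 <- file.path(tempdir(), "b2")
  p1 <- simulate_bundle(cfg, d1); p2 <- simulate_bundle(cfg, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  # substreams are independent: the catalog regenerates identically alone
  expect_identical(gen_disease_catalog(cfg)$catalog$gene_sets,
                   gen_disease_catalog(cfg)$catalog$gene_sets)
})

test_that("marker planting places the promised disease-gene fraction", {
  cfg <- sim_config(seed = 5, n_diseases = 4, universe_size = 60,
                    genes_per_disease = 8, overlaps = NULL,
                    n_contexts = 4, markers_per_context = 12,
                    marker_universe_size = 500,
                    planted_enrichment = data.frame(disease = 2, context = 3,
                                                    fraction = 1))
  dz <- gen_disease_catalog(cfg)
  mk <- gen_marker_catalog(cfg, dz$catalog)
  # fraction 1: the whole disease set is inside the context's markers
  expect_true(all(dz$catalog$gene_sets$disease02 %in%
                    mk$markers$marker_sets$celltype03))
  expect_equal(mk$truth$n_planted, 8)
  expect_true(all(lengths(mk$markers$marker_sets) == 12))

  # infeasible planting (more planted genes than marker slots)
  tight <- sim_config(seed = 5, n_diseases = 4, universe_size = 60,
                      genes_per_disease = 8, overlaps = NULL,
                      n_contexts = 4, markers_per_context = 5,
                      marker_universe_size = 500,
                      planted_enrichment = data.frame(disease = 2, context = 3,
                                                      fraction = 1))
  expect_error(gen_marker_catalog(tight, dz$catalog), "exceed")
})

test_that("expression effects respect the fold threshold by construction", {
  # noiseless, no planted effect: nothing flagged
  cfg0 <- sim_config(seed = 2, n_genes_expr = 40, noise_sd = 0,
                     region_effects = NULL, overlaps = NULL,
                     planted_enrichment = NULL)
  st0 <- gen_expression(cfg0)$study
  sets0 <- region_high_sets(st0, moderation = "plain")
  expect_true(all(lengths(sets0$marker_sets) == 0))

  # planted log2 fold 0.5 sits below the fold-2 threshold: never flagged
  cfg1 <- sim_config(seed = 2, n_genes_expr = 40, noise_sd = 0.01,
                     region_effects = data.frame(gene = 1, region = 1,
                                                 log2_fold = 0.5),
                     overlaps = NULL, planted_enrichment = NULL)
  st1 <- gen_expression(cfg1)
  res <- region_contrast(st1$study, "region01", moderation = "plain")
  expect_false(res$high_flag[res$gene == st1$truth$gene])
  expect_lt(res$p_value[res$gene == st1$truth$gene], 0.05)  # real but small
})

test_that("phenotype scores follow the planted similarity link", {
  cfg <- sim_config(seed = 13, n_diseases = 4, universe_size = 60,
                    genes_per_disease = 6,
                    overlaps = data.frame(i = 1, j = 2, overlap = 3),
                    planted_enrichment = NULL, region_effects = NULL,
                    dmn_slope = 1, dmn_noise_sd = 0, dmn_matchings = 2)
  dz <- gen_disease_catalog(cfg)
  ph <- gen_phenotype_scores(cfg, dz$truth)
  avg <- average_phenotype(ph)
  expect_equal(nrow(ph), 2 * nrow(dz$truth))  # two matchings per pair
  key <- paste(avg$disease_a, avg$disease_b)
  tkey <- paste(dz$truth$disease_a, dz$truth$disease_b)
  expect_equal(avg$dmn_score[match(tkey, key)], dz$truth$proportion)

  # zero slope: scores carry no similarity signal (Monte-Carlo mean near 0)
  ests <- vapply(1:40, function(r) {
    c0 <- sim_config(seed = 100 + r, n_diseases = 10, universe_size = 200,
                     genes_per_disease = 10, overlaps = NULL,
                     planted_enrichment = NULL, region_effects = NULL,
                     dmn_slope = 0, dmn_noise_sd = 0.02, dmn_matchings = 1)
    d0 <- gen_disease_catalog(c0)
    p0 <- gen_phenotype_scores(c0, d0$truth)
    a0 <- average_phenotype(p0)
    k <- paste(a0$disease_a, a0$disease_b)
    tk <- paste(d0$truth$disease_a, d0$truth$disease_b)
    suppressWarnings(stats::cor(d0$truth$proportion, a0$dmn_score[match(tk, k)]))
  }, numeric(1))
  expect_lt(abs(mean(ests, na.rm = TRUE)), 3 * stats::sd(ests) / sqrt(sum(!is.na(ests))) + 0.05)
})

test_that("generated mutation tables merge back into the catalog", {
  cfg <- sim_config(seed = 19, n_diseases = 5, universe_size = 80,
                    genes_per_disease = 8, overlaps = NULL,
                    planted_enrichment = NULL, region_effects = NULL)
  dz <- gen_disease_catalog(cfg)
  mt <- gen_mutation_tables(cfg, dz$catalog)
  m <- merge_catalogs(mt$curated, mt$clinvar)
  expect_setequal(m$catalog$diseases, dz$catalog$diseases)
  for (d in dz$catalog$diseases)
    expect_setequal(m$catalog$gene_sets[[d]], dz$catalog$gene_sets[[d]])
})

test_that("bundles read back through the package readers faithfully", {
  cfg <- sim_config(seed = 29, n_diseases = 5, universe_size = 80,
                    genes_per_disease = 8,
                    overlaps = data.frame(i = 1, j = 2, overlap = 4),
                    n_contexts = 5, markers_per_context = 10,
                    marker_universe_size = 300, n_genes_expr = 60,
                    planted_enrichment = NULL,
                    region_effects = default_region_effects(10, 3))
  dir <- file.path(tempdir(), "bundle_rt")
  paths <- simulate_bundle(cfg, dir)
  expect_true(all(file.exists(paths)))

  cur <- read_mutation_table(paths[["curated"]], "curated")
  clv <- read_mutation_table(paths[["clinvar"]], "clinvar")
  cat <- merge_catalogs(cur, clv)$catalog
  truth_cat <- gen_disease_catalog(cfg)$catalog
  for (d in truth_cat$diseases)
    expect_setequal(cat$gene_sets[[d]], truth_cat$gene_sets[[d]])

  mk <- read_marker_gmt(paths[["markers"]])
  expect_equal(length(mk$contexts), 5)
  st <- read_expression(paths[["expression"]], paths[["regions"]])
  expect_equal(length(st$regions), 10)
  ph <- read_phenotype_scores(paths[["phenotype"]])
  expect_equal(nrow(ph), cfg$dmn_matchings * choose(5, 2))
})
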
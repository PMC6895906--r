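test_that("pair enumeration is complete, ordered and self-pair free", {
  d5 <- paste0("d", 1:5)
  p <- enumerate_pairs(d5)
  # brute-force double-loop oracle
  oracle <- list()
  for (i in seq_along(d5)) for (j in seq_along(d5))
    if (i < j) oracle[[length(oracle) + 1]] <- c(d5[i], d5[j])
  expect_equal(nrow(p), length(oracle))  # 10
  expect_true(all(mapply(function(r, o) all(c(p$disease_a[r], p$disease_b[r]) == o),
                         seq_len(nrow(p)), oracle)))
  expect_equal(nrow(enumerate_pairs(c("a", "b"))), 1)
  expect_error(enumerate_pairs("only_one"), "at least 2")
})

test_that("chi-square matches the hand formula on exhaustive small tables", {
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
    s <- sets_from_table(a, b, cc, d)
    ht <- shared_set_test(s$A, s$B, s$universe)
    if (ht$degenerate) next
    expect_equal(ht$statistic, chi2_hand(a, b, cc, d), tolerance = 1e-12)
    expect_equal(ht$p_value, stats::pchisq(chi2_hand(a, b, cc, d), 1,
                                           lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("chi-square handles balanced and degenerate tables", {
  s <- sets_from_table(1, 1, 1, 1)  # observed equals expected
  ht <- shared_set_test(s$A, s$B, s$universe)
  expect_equal(ht$statistic, 0)
  expect_equal(ht$p_value, 1)

  # both sets equal to the whole universe: zero margin, degenerate
  u <- paste0("g", 1:5)
  ht2 <- shared_set_test(u, u, u)
  expect_true(ht2$degenerate)
  expect_equal(ht2$p_value, 1)
  expect_equal(ht2$statistic, 0)

  expect_error(shared_set_test("x", "y", c("y", "z")),
               "subsets of the universe")
})

test_that("chi-square is symmetric and monotone in the overlap", {
  # symmetry in the two sets
  s <- sets_from_table(3, 5, 2, 30)
  expect_equal(shared_set_test(s$A, s$B, s$universe)$statistic,
               shared_set_test(s$B, s$A, s$universe)$statistic)

  # fixed sizes: statistic non-decreasing in the overlap above independence
  for (N in c(30, 60)) for (K in c(6, 10)) {
    expectation <- K * K / N
    stats_above <- sapply(ceiling(expectation):K, function(a)
      chi2_hand(a, K - a, K - a, N - 2 * K + a))
    expect_true(all(diff(stats_above) >= -1e-9))
  }
})

test_that("proportion of shared genes uses the smaller set size", {
  expect_equal(proportion_shared(c("A", "B"), c("A", "B", "C")), 1)  # A subset B
  expect_equal(proportion_shared(c("A", "B"), c("C", "D")), 0)
  expect_equal(proportion_shared(paste0("g", 1:4), paste0("g", 3:8)), 2 / 4)
  expect_error(proportion_shared(character(0), "A"), "non-empty")
})

test_that("similarity screen flags exactly the planted pair", {
  u <- sprintf("u%03d", 1:300)
  cat <- disease_catalog(list(
    d1 = u[1:10], d2 = u[c(1:8, 11, 12)],  # 8 shared of 10: massive excess
    d3 = u[21:30], d4 = u[31:40]
  ), universe = u)
  sc <- similarity_screen(cat)
  hit <- sc$pairs[sc$pairs$significant, ]
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$disease_a, hit$disease_b), c("d1", "d2"))
  expect_lt(hit$chi2_p, 1e-6)
  # hand-computed table for the planted pair agrees
  expect_equal(hit$chi2_stat, chi2_hand(8, 2, 2, 288), tolerance = 1e-9)

  # mutually disjoint small sets: nothing significant
  cat2 <- disease_catalog(list(d1 = u[1:5], d2 = u[6:10], d3 = u[11:15]),
                          universe = u)
  expect_equal(similarity_screen(cat2)$n_significant, 0)

  # alpha = 1 marks every pair (all p-values are < 1 here)
  expect_equal(similarity_screen(cat, alpha = 1)$n_significant, 6)
})

test_that("screen output is invariant under disease relabeling (symmetry)", {
  u <- sprintf("u%03d", 1:100)
  set.seed(1)
  sets <- list(x = sample(u, 12), y = sample(u, 9), z = sample(u, 15))
  s1 <- similarity_screen(disease_catalog(sets, universe = u))$pairs
  s2 <- similarity_screen(disease_catalog(rev(sets), universe = u))$pairs
  key <- function(df) paste(df$disease_a, df$disease_b)
  s2 <- s2[match(key(s1), key(s2)), ]
  expect_equal(s1$chi2_stat, s2$chi2_stat)
  expect_equal(s1$n_overlap, s2$n_overlap)
})

test_that("mutation-level screening runs on variant-key catalogs", {
  rec <- rbind(
    mutation_fixture(10, disease = "ataxia", gene = "SACS"),
    transform(mutation_fixture(10, disease = "als", gene = "SOD1"), pos = pos + 5),
    transform(mutation_fixture(4, disease = "ftd", gene = "MAPT"), pos = pos + 100)
  )
  mc <- mutation_catalog(rec)
  sc <- similarity_screen(mc, level = "mutation")
  ov <- sc$pairs$n_overlap[sc$pairs$disease_a == "als" &
                           sc$pairs$disease_b == "ataxia"]
  expect_equal(ov, 5)  # positions 6..10 coincide
  expect_equal(sc$level, "mutation")
})

test_that("null screen rejection matches the exact discrete test size", {
  # independent gene sets: the chi-square on sparse 2x2 tables is discrete,
  # so its true size differs from the nominal level; the implementation must
  # match the size computed by exact hypergeometric enumeration
  cfg0 <- sim_config(seed = 99, overlaps = NULL, planted_enrichment = NULL,
                     region_effects = NULL)
  N <- cfg0$universe_size; K <- cfg0$genes_per_disease
  k <- 0:K
  stat <- vapply(k, function(a) chi2_hand(a, K - a, K - a, N - 2 * K + a),
                 numeric(1))
  exact_size <- sum(stats::dhyper(k, K, N - K, K)[stat >= stats::qchisq(0.95, 1)])

  n_rep <- 150
  rates <- vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(seed = 1000 + r, overlaps = NULL,
                      planted_enrichment = NULL, region_effects = NULL)
    sc <- similarity_screen(gen_disease_catalog(cfg)$catalog)
    mean(sc$pairs$significant)
  }, numeric(1))
  # replicate-level CI (pairs within a catalog are dependent)
  half <- 3 * stats::sd(rates) / sqrt(n_rep)
  expect_lt(abs(mean(rates) - exact_size), half)
})
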
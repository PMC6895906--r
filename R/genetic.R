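#' Enumerate all unordered disease pairs
#'
#' @param diseases character vector of at least two disease names.
#' @return data frame with columns `disease_a`, `disease_b`: all `C(n, 2)`
#'   unordered pairs, lexicographically ordered, no self-pairs.
#' @export
#' @examples
#' nrow(enumerate_pairs(paste0("d", 1:20)))  # 190
enumerate_pairs <- function(diseases) {
  diseases <- unique(as.character(diseases))
  if (length(diseases) < 2) stop("need at least 2 diseases")
  diseases <- sort(diseases)
  idx <- utils::combn(length(diseases), 2)
  data.frame(disease_a = diseases[idx[1, ]], disease_b = diseases[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Chi-square test for excess gene sharing between two diseases
#'
#' Builds the 2x2 membership table over the gene universe
#' (`a = |A and B|`, `b = |A only|`, `c = |B only|`, `d = rest`) and returns
#' the Pearson chi-square statistic with its upper-tail p-value on 1 df.
#' No continuity correction by default. A degenerate table (a zero row or
#' column margin, e.g. both sets equal to the universe) returns statistic 0,
#' p = 1, and `degenerate = TRUE`.
#'
#' @param set_a,set_b character vectors of gene symbols, subsets of
#'   `universe`.
#' @param universe the reference gene universe (length >= 2).
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return list with `statistic`, `p_value`, `n_overlap`, `table` (2x2
#'   matrix), and `degenerate`.
#' @export
shared_set_test <- function(set_a, set_b, universe, correct = FALSE) {
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  if (length(universe) < 2) stop("universe must contain at least 2 genes")
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe)))
    stop("sets must be subsets of the universe")
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  cc <- length(set_b) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), nrow = 2,
                dimnames = list(in_a = c("yes", "no"), in_b = c("yes", "no")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = 0, p_value = 1, n_overlap = a, table = tab,
                degenerate = TRUE))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       n_overlap = a, table = tab, degenerate = FALSE)
}

#' Proportion of shared genes between two diseases
#'
#' The overlap count divided by the size of the smaller gene set, the
#' normalized genetic-similarity measure used against phenotype scores.
#'
#' @param set_a,set_b non-empty character vectors of gene symbols.
#' @return a number in `[0, 1]`.
#' @export
proportion_shared <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  if (length(set_a) == 0 || length(set_b) == 0)
    stop("gene sets must be non-empty")
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}

#' Screen all disease pairs for significant gene (or mutation) sharing
#'
#' Runs [shared_set_test()] on every unordered pair of diseases in the
#' catalog. For mutation-level screening pass a catalog built with
#' [mutation_catalog()], whose "genes" are `(chrom, pos, ref, alt)` keys.
#' The universe defaults to the catalog's own universe (the combined gene
#' list); a genome-wide list may be supplied instead. Raw p-values are
#' compared against `alpha` as the headline call; a Benjamini-Hochberg
#' adjusted column is emitted alongside for users who want it.
#'
#' @param catalog a [disease_catalog()] with at least 2 diseases.
#' @param alpha significance cutoff on the raw p-value (default 0.05).
#' @param level label recorded in the output, `"gene"` or `"mutation"`.
#' @param universe optional overriding universe.
#' @param correct Yates correction flag, passed to [shared_set_test()].
#' @return list with `pairs` (one row per pair: sizes, overlap, statistic,
#'   p-value, BH-adjusted p, proportion shared, significance flag),
#'   `n_significant`, `alpha`, `level`, and `universe_size`.
#' @export
similarity_screen <- function(catalog, alpha = 0.05,
                              level = c("gene", "mutation"),
                              universe = NULL, correct = FALSE) {
  stopifnot(inherits(catalog, "disease_catalog"))
  level <- match.arg(level)
  universe <- unique(as.character(universe %||% catalog$universe))
  pairs <- enumerate_pairs(catalog$diseases)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    A <- catalog$gene_sets[[pairs$disease_a[i]]]
    B <- catalog$gene_sets[[pairs$disease_b[i]]]
    ht <- shared_set_test(A, B, universe, correct = correct)
    data.frame(
      disease_a = pairs$disease_a[i], disease_b = pairs$disease_b[i],
      n_a = length(A), n_b = length(B), n_overlap = ht$n_overlap,
      chi2_stat = ht$statistic, chi2_p = ht$p_value,
      degenerate = ht$degenerate,
      proportion_shared = proportion_shared(A, B),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, res)
  tab$p_bh <- stats::p.adjust(tab$chi2_p, method = "BH")
  tab$significant <- tab$chi2_p < alpha
  list(pairs = tab, n_significant = sum(tab$significant), alpha = alpha,
       level = level, universe_size = length(universe))
}
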
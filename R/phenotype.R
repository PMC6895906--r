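#' Average phenotype scores per disease pair
#'
#' One disease pair may match multiple entries in the phenotype network; its
#' phenotypic similarity is the arithmetic mean of all recorded scores, with
#' order-swapped duplicates pooled before averaging.
#'
#' @param scores a `phenotype_scores` data frame from
#'   [read_phenotype_scores()] (or any data frame with `disease_a`,
#'   `disease_b`, `score`).
#' @return data frame with one row per unordered pair: `disease_a`,
#'   `disease_b` (canonical order), `dmn_score` (mean), `n_matchings`.
#' @export
average_phenotype <- function(scores) {
  stopifnot(nrow(scores) >= 1)
  p <- canonical_pair(scores$disease_a, scores$disease_b)
  key <- paste(p$a, p$b, sep = "\r")
  agg <- tapply(scores$score, key, mean)
  n <- tapply(scores$score, key, length)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(
    disease_a = vapply(parts, `[[`, character(1), 1),
    disease_b = vapply(parts, `[[`, character(1), 2),
    dmn_score = unname(as.numeric(agg)),
    n_matchings = unname(as.integer(n)),
    stringsAsFactors = FALSE
  )
  out[order(out$disease_a, out$disease_b), , drop = FALSE]
}

#' Join a similarity table with averaged phenotype scores
#'
#' Inner join on the unordered disease pair: pairs absent from the phenotype
#' table, or with an undefined similarity value, are dropped and counted, and
#' the retained n is always reported downstream.
#'
#' @param similarity data frame with `disease_a`, `disease_b` and the column
#'   named by `value`.
#' @param value name of the similarity column (e.g. `"proportion_shared"` or
#'   `"distance"`).
#' @param phenotype averaged phenotype table from [average_phenotype()].
#' @return data frame `disease_a`, `disease_b`, `similarity`, `dmn_score`;
#'   attributes `n_dropped_no_score` and `n_dropped_undefined`.
#' @export
paired_scores <- function(similarity, value, phenotype) {
  stopifnot(value %in% names(similarity))
  key_s <- pair_key(similarity$disease_a, similarity$disease_b)
  key_p <- pair_key(phenotype$disease_a, phenotype$disease_b)
  hit <- match(key_s, key_p)
  sim <- similarity[[value]]
  keep <- !is.na(hit) & !is.na(sim)
  out <- data.frame(
    disease_a = canonical_pair(similarity$disease_a, similarity$disease_b)$a[keep],
    disease_b = canonical_pair(similarity$disease_a, similarity$disease_b)$b[keep],
    similarity = sim[keep],
    dmn_score = phenotype$dmn_score[hit[keep]],
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped_no_score") <- sum(is.na(hit) & !is.na(sim))
  attr(out, "n_dropped_undefined") <- sum(is.na(sim))
  out
}

#' Correlate a similarity layer with phenotype scores
#'
#' Pearson or Spearman correlation with a two-sided p-value (the t transform
#' for Pearson; the exact rank null at small n without ties, asymptotic
#' otherwise, for Spearman).
#'
#' @param paired data frame from [paired_scores()] (columns `similarity`,
#'   `dmn_score`), or a numeric vector (then `y` must be given).
#' @param y optional second numeric vector when `paired` is a vector.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `method`, `estimate`, `p_value`, `n`.
#' @export
correlate_similarity <- function(paired, y = NULL,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.data.frame(paired)) {
    x <- paired$similarity
    y <- paired$dmn_score
  } else {
    x <- paired
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the vectors")
  exact <- if (method == "spearman")
    !(anyDuplicated(x) || anyDuplicated(y)) && length(x) < 1290
  else NULL
  ht <- suppressWarnings(stats::cor.test(x, y, method = method, exact = exact))
  list(method = method, estimate = unname(ht$estimate),
       p_value = unname(ht$p.value), n = length(x))
}

#' Compare phenotype scores across ranked distance groups
#'
#' Splits distance-ranked disease pairs into three groups -- the `k` pairs
#' with the lowest distances, a middle rank range, and the `k` pairs with the
#' highest distances -- and compares their mean phenotype scores with Welch
#' two-sample t-tests between each pair of groups.
#'
#' @param ranked data frame of ranked pairs (from [rank_pairs()], joined with
#'   phenotype scores) ordered ascending by distance, with the score column
#'   named by `score_col`.
#' @param k size of the lowest- and highest-distance groups (default 20).
#' @param mid integer vector of length 2: first and last rank of the middle
#'   group (default `c(21, 51)`); must not overlap the outer groups.
#' @param score_col name of the phenotype-score column.
#' @return object of class `group_comparison`: `group_defs`, `group_sizes`,
#'   `group_means`, and `t_p_values` (Welch p-values for low-mid, low-high,
#'   mid-high).
#' @export
group_compare <- function(ranked, k = 20, mid = c(21, 51),
                          score_col = "dmn_score") {
  stopifnot(score_col %in% names(ranked), length(mid) == 2, mid[1] <= mid[2])
  n <- nrow(ranked)
  if (n < mid[2] + k || mid[1] <= k)
    stop("overlapping or infeasible group definitions for n = ", n)
  idx <- list(
    lowest = seq_len(k),
    middle = seq(mid[1], mid[2]),
    highest = seq(n - k + 1, n)
  )
  if (mid[2] > n - k) stop("middle group overlaps the highest group")
  s <- ranked[[score_col]]
  groups <- lapply(idx, function(i) s[i])
  means <- vapply(groups, mean, numeric(1))
  welch <- function(a, b) stats::t.test(a, b)$p.value
  structure(list(
    group_defs = list(k = k, mid = mid, n = n),
    group_sizes = lengths(idx),
    group_means = means,
    t_p_values = c(
      lowest_vs_middle = welch(groups$lowest, groups$middle),
      lowest_vs_highest = welch(groups$lowest, groups$highest),
      middle_vs_highest = welch(groups$middle, groups$highest)
    )
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("groups (n=%d): lowest %d | ranks %d-%d | highest %d\n",
              x$group_defs$n, x$group_defs$k, x$group_defs$mid[1],
              x$group_defs$mid[2], x$group_defs$k))
  cat("mean scores:", sprintf("%.4g", x$group_means), "\n")
  cat("Welch t p-values:",
      paste(names(x$t_p_values), sprintf("%.3g", x$t_p_values), sep = "="),
      "\n")
  invisible(x)
}
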
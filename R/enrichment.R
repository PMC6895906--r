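#' Two-tailed Fisher exact test for gene-set enrichment
#'
#' Tests whether a disease gene set overlaps a context's marker set more than
#' expected by chance over a background universe. The 2x2 table is
#' (in disease set) x (in marker set) over the background; the two-tailed
#' p-value sums all hypergeometric outcomes whose probability does not exceed
#' the observed outcome's (the minimum-likelihood rule, the standard exact
#' two-tail convention). An empty marker set is degenerate: p = 1 with the
#' `degenerate` attribute set.
#'
#' @param disease_genes non-empty character vector, subset of `background`.
#' @param marker_genes character vector, subset of `background`.
#' @param background character vector, the enrichment universe.
#' @return the p-value, with attributes `n_over` (overlap count) and
#'   `degenerate`.
#' @export
fisher_enrichment <- function(disease_genes, marker_genes, background) {
  disease_genes <- unique(as.character(disease_genes))
  marker_genes <- unique(as.character(marker_genes))
  background <- unique(as.character(background))
  if (length(disease_genes) == 0) stop("disease gene set is empty")
  if (length(setdiff(disease_genes, background)) ||
      length(setdiff(marker_genes, background)))
    stop("gene sets must be subsets of the background")
  k <- length(intersect(disease_genes, marker_genes))
  if (length(marker_genes) == 0)
    return(structure(1, n_over = 0L, degenerate = TRUE))
  fet_two_tail(k, length(disease_genes), length(marker_genes),
               length(background))
}

#' Two-tailed Fisher exact p-value from overlap counts
#'
#' Count-level core of [fisher_enrichment()]: the probability, under the
#' hypergeometric null, of any overlap whose likelihood does not exceed the
#' observed one (minimum-likelihood two-tail rule).
#'
#' @param n_over observed overlap count.
#' @param n_g1,n_g2 the two set sizes.
#' @param n_background the universe size.
#' @return the p-value, with attributes `n_over` and `degenerate` (single-
#'   point support, e.g. a set spanning the whole background).
#' @export
fet_two_tail <- function(n_over, n_g1, n_g2, n_background) {
  stopifnot(n_g1 >= 1, n_g2 >= 1, n_background >= max(n_g1, n_g2),
            n_over >= max(0, n_g1 + n_g2 - n_background),
            n_over <= min(n_g1, n_g2))
  support <- max(0, n_g1 + n_g2 - n_background):min(n_g1, n_g2)
  d <- stats::dhyper(support, n_g2, n_background - n_g2, n_g1)
  # relative tolerance guards against ties broken by floating-point noise
  p <- min(1, sum(d[d <= d[support == n_over] * (1 + 1e-7)]))
  structure(p, n_over = as.integer(n_over),
            degenerate = length(support) == 1)
}

#' Gene-set enrichment score
#'
#' The overlap count divided by the product of the two set sizes:
#' `n_over / (n_g1 * n_g2)`. Symmetric in the two sizes and strictly
#' increasing in the overlap.
#'
#' @param n_over overlap count, at most `min(n_g1, n_g2)`.
#' @param n_g1,n_g2 positive gene-set sizes.
#' @return the score.
#' @export
#' @examples
#' enrichment_score(2, 4, 5)  # 0.1
enrichment_score <- function(n_over, n_g1, n_g2) {
  stopifnot(n_g1 >= 1, n_g2 >= 1, n_over >= 0)
  if (n_over > min(n_g1, n_g2))
    stop("n_over exceeds the smaller set size")
  n_over / (n_g1 * n_g2)
}

#' Build per-disease enrichment profiles over a marker catalog
#'
#' For every disease and every context, counts the overlap between the
#' disease genes (restricted to the marker background) and the context's
#' marker set, computes the enrichment score and the two-tailed Fisher exact
#' p-value, and flags significance at `alpha`. The profile of one disease is
#' its vector of enrichment scores over all contexts, in the catalog's
#' context order; the disease-by-context significance matrix is the "star
#' matrix" view of the same result. A disease with no genes in the background
#' yields an all-zero profile with a warning.
#'
#' @param catalog a [disease_catalog()].
#' @param markers a [marker_catalog()] (cell-type markers, or region
#'   highly-expressed sets from [region_high_sets()]).
#' @param alpha significance cutoff for the flags (default 0.05).
#' @return object of class `enrichment_profiles`: `diseases`, `contexts`,
#'   `records` (long data frame of per disease-context results), and
#'   disease-by-context matrices `score`, `p_value`, `significant`.
#' @export
build_profiles <- function(catalog, markers, alpha = 0.05) {
  stopifnot(inherits(catalog, "disease_catalog"),
            inherits(markers, "marker_catalog"))
  bg <- markers$background
  diseases <- catalog$diseases
  contexts <- markers$contexts

  rows <- vector("list", length(diseases) * length(contexts))
  i <- 0L
  for (dz in diseases) {
    genes <- intersect(catalog$gene_sets[[dz]], bg)
    if (length(genes) == 0)
      warning("disease '", dz, "' has no genes in the marker background; ",
              "profile is all zero")
    for (ctx in contexts) {
      mk <- intersect(markers$marker_sets[[ctx]], bg)
      n_over <- length(intersect(genes, mk))
      score <- if (length(genes) == 0 || length(mk) == 0) 0 else
        enrichment_score(n_over, length(genes), length(mk))
      p <- if (length(genes) == 0) 1 else
        as.numeric(fisher_enrichment(genes, mk, bg))
      i <- i + 1L
      rows[[i]] <- data.frame(
        disease = dz, context = ctx, n_over = n_over,
        n_g1 = length(genes), n_g2 = length(mk),
        score = score, fet_p = p, significant = p < alpha,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, rows)

  to_mat <- function(col) {
    m <- matrix(records[[col]], nrow = length(diseases),
                ncol = length(contexts), byrow = TRUE,
                dimnames = list(diseases, contexts))
    m
  }
  structure(
    list(diseases = diseases, contexts = contexts, records = records,
         score = to_mat("score"), p_value = to_mat("fet_p"),
         significant = to_mat("significant"), alpha = alpha),
    class = "enrichment_profiles"
  )
}

#' @export
print.enrichment_profiles <- function(x, ...) {
  cat("enrichment_profiles:", length(x$diseases), "diseases x",
      length(x$contexts), "contexts;", sum(x$significant),
      "significant at alpha =", x$alpha, "\n")
  invisible(x)
}
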
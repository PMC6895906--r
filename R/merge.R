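#' Merge curated and ClinVar-style mutation catalogs
#'
#' Combines two mutation tables into one de-duplicated dataset and computes
#' the inclusion-exclusion accounting. Mutation identity is the
#' `(chrom, pos, ref, alt)` tuple -- the disease label is *not* part of the
#' key, so a variant recorded for two diseases counts once in the mutation
#' totals while still contributing to both disease gene sets. Gene identity is
#' the symbol. A variant present in both sources keeps one record per
#' (disease, variant) with `source = "both"`; conflicting pathogenicity calls
#' are kept as separate rows rather than resolved.
#'
#' @param curated,clinvar mutation-record data frames (see
#'   [read_mutation_table()]); all records must share one genome build.
#' @return list with elements
#'   \describe{
#'     \item{records}{merged, de-duplicated mutation records;}
#'     \item{summary}{a `merge_summary` list: per-source, shared and union
#'       mutation and gene counts, curated/clinvar count ratios (rounded half
#'       up to 1 decimal), and the multi-/single-disease gene split;}
#'     \item{catalog}{the combined [disease_catalog()].}
#'   }
#' @export
#' @examples
#' cur <- data.frame(disease = "ataxia", gene = "SACS", build = "hg19",
#'                   chrom = "13", pos = 1:3, ref = "A", alt = "G",
#'                   source = "curated", pathogenicity = "pathogenic")
#' clv <- transform(cur, pos = 3:5, source = "clinvar")
#' merge_catalogs(cur, clv)$summary$n_mut_union  # 5
merge_catalogs <- function(curated, clinvar) {
  builds <- unique(c(curated$build, clinvar$build))
  if (length(builds) != 1)
    stop("mixed genome builds: ", paste(builds, collapse = ", "),
         "; normalize coordinates upstream")

  key_cur <- unique(mutation_key(curated))
  key_clv <- unique(mutation_key(clinvar))
  gene_cur <- unique(curated$gene)
  gene_clv <- unique(clinvar$gene)

  shared_keys <- intersect(key_cur, key_clv)

  all <- rbind(curated, clinvar)
  all$source[mutation_key(all) %in% shared_keys] <- "both"
  dedup_key <- paste(all$disease, mutation_key(all), all$pathogenicity,
                     sep = "\r")
  records <- all[!duplicated(dedup_key), , drop = FALSE]
  rownames(records) <- NULL

  catalog <- catalog_from_records(records)
  split <- single_multi_gene_split(catalog)

  summary <- structure(list(
    n_mut_curated = length(key_cur),
    n_mut_clinvar = length(key_clv),
    n_mut_shared = length(shared_keys),
    n_mut_union = length(union(key_cur, key_clv)),
    n_gene_curated = length(gene_cur),
    n_gene_clinvar = length(gene_clv),
    n_gene_shared = length(intersect(gene_cur, gene_clv)),
    n_gene_union = length(union(gene_cur, gene_clv)),
    ratio_mut = round_half_up(length(key_cur) / length(key_clv), 1),
    ratio_gene = round_half_up(length(gene_cur) / length(gene_clv), 1),
    n_gene_multi = length(split$multi),
    n_gene_single = length(split$single)
  ), class = "merge_summary")

  list(records = records, summary = summary, catalog = catalog)
}

#' @export
print.merge_summary <- function(x, ...) {
  cat(sprintf(
    "mutations: %d curated + %d clinvar - %d shared = %d combined (ratio %.1f)\n",
    x$n_mut_curated, x$n_mut_clinvar, x$n_mut_shared, x$n_mut_union, x$ratio_mut))
  cat(sprintf(
    "genes:     %d curated + %d clinvar - %d shared = %d combined (ratio %.1f)\n",
    x$n_gene_curated, x$n_gene_clinvar, x$n_gene_shared, x$n_gene_union,
    x$ratio_gene))
  cat(sprintf("           %d genes linked to >=2 diseases, %d to exactly 1\n",
              x$n_gene_multi, x$n_gene_single))
  invisible(x)
}

#' Split catalog genes into multi-disease and single-disease sets
#'
#' @param catalog a [disease_catalog()].
#' @return list with character vectors `multi` (genes appearing in at least
#'   two disease gene sets) and `single` (genes in exactly one); together they
#'   partition the genes that appear in at least one set.
#' @export
single_multi_gene_split <- function(catalog) {
  stopifnot(inherits(catalog, "disease_catalog"))
  counts <- table(unlist(lapply(catalog$gene_sets, unique), use.names = FALSE))
  list(multi = sort(names(counts)[counts >= 2]),
       single = sort(names(counts)[counts == 1]))
}
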
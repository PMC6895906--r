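#' Run the full disease-similarity pipeline
#'
#' Orchestrates every stage on file inputs: merge the two mutation catalogs,
#' screen all disease pairs for gene- and mutation-level sharing, call
#' per-region highly-expressed gene sets from the expression study, build
#' cell-type and brain-region enrichment profiles, compute binary profile
#' distances and rankings, and -- when a phenotype table is supplied --
#' average its scores and correlate each similarity layer with them
#' (Pearson on the proportion of shared genes, Spearman on the profile
#' distances), plus the ranked three-group comparison where enough scored
#' pairs exist. Every intermediate table is written as TSV into `out_dir`
#' together with a machine-readable `summary.json` and a `log.txt` recording
#' the defaulted analysis decisions.
#'
#' @param curated,clinvar paths to the two mutation TSVs.
#' @param markers path to the cell-type marker GMT.
#' @param expression,region_map paths to the expression matrix TSV and its
#'   sample-to-region map.
#' @param phenotype optional path to the phenotype-score TSV; when missing,
#'   stages up to the distance rankings still complete and the correlation
#'   stage is skipped with a warning.
#' @param out_dir output directory (created if needed).
#' @param alpha significance cutoff used in every stage (default 0.05).
#' @param moderation variance moderation for the region contrasts
#'   (`"eb"` or `"plain"`).
#' @param binarize profile binarization rule for distances (`"score"` or
#'   `"significant"`).
#' @param group_k,group_mid three-group comparison layout (sizes of the outer
#'   groups and rank bounds of the middle group).
#' @param expression_scale `"log2"` or `"linear"`, see [expression_study()].
#' @param synonyms optional disease synonym map, see [normalize_disease()].
#' @return (invisibly) a list with all stage results and the summary list.
#' @export
run_pipeline <- function(curated, clinvar, markers, expression, region_map,
                         phenotype = NULL, out_dir,
                         alpha = 0.05, moderation = c("eb", "plain"),
                         binarize = c("score", "significant"),
                         group_k = 20, group_mid = c(21, 51),
                         expression_scale = c("log2", "linear"),
                         synonyms = NULL) {
  moderation <- match.arg(moderation)
  binarize <- match.arg(binarize)
  expression_scale <- match.arg(expression_scale)
  inputs <- c(curated = curated, clinvar = clinvar, markers = markers,
              expression = expression, region_map = region_map)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  note("alpha = ", alpha)
  note("chi-square universe = combined catalog genes; no continuity correction")
  note("region contrast moderation = ", moderation,
       "; fold threshold 2 (boundary inclusive); other-regions mean pooled")
  note("profile binarization = ", binarize)
  note("group comparison: Welch t-test; k = ", group_k,
       ", middle ranks ", group_mid[1], "-", group_mid[2])

  merged <- stage("merge", {
    merge_catalogs(
      read_mutation_table(curated, "curated", synonyms = synonyms),
      read_mutation_table(clinvar, "clinvar", synonyms = synonyms)
    )
  })
  write_mutation_table(merged$records, file.path(out_dir, "merged.tsv"))
  write_tsv(data.frame(field = names(unclass(merged$summary)),
                       value = unlist(merged$summary)),
            file.path(out_dir, "merge_summary.tsv"))

  gen <- stage("genetic_similarity",
               similarity_screen(merged$catalog, alpha = alpha))
  write_tsv(gen$pairs, file.path(out_dir, "genetic_similarity_gene.tsv"))
  mut <- stage("genetic_similarity", similarity_screen(
    mutation_catalog(merged$records), alpha = alpha, level = "mutation"))
  write_tsv(mut$pairs, file.path(out_dir, "genetic_similarity_mutation.tsv"))

  study <- stage("region_expression",
                 read_expression(expression, region_map,
                                 scale = expression_scale))
  region_sets <- stage("region_expression",
                       region_high_sets(study, alpha = alpha,
                                        moderation = moderation))
  write_tsv(attr(region_sets, "contrasts"),
            file.path(out_dir, "region_contrasts.tsv"))
  write_marker_gmt(region_sets, file.path(out_dir, "region_high_sets.gmt"))

  cells <- stage("context_enrichment", read_marker_gmt(markers))
  prof_cell <- stage("context_enrichment",
                     build_profiles(merged$catalog, cells, alpha = alpha))
  prof_region <- stage("context_enrichment", suppressWarnings(
    build_profiles(merged$catalog, region_sets, alpha = alpha)))
  write_tsv(prof_cell$records, file.path(out_dir, "cell_enrichment.tsv"))
  write_tsv(prof_region$records, file.path(out_dir, "region_enrichment.tsv"))

  dist_cell <- profile_distance_matrix(prof_cell, binarize = binarize)
  dist_region <- profile_distance_matrix(prof_region, binarize = binarize)
  rank_cell <- stage("profile_distance", rank_pairs(dist_cell))
  rank_region <- stage("profile_distance", rank_pairs(dist_region))
  write_tsv(rank_cell, file.path(out_dir, "rank_cell.tsv"))
  write_tsv(rank_region, file.path(out_dir, "rank_region.tsv"))

  summary <- list(
    alpha = alpha,
    merge = unclass(merged$summary),
    n_pairs = nrow(gen$pairs),
    n_significant_gene = gen$n_significant,
    n_significant_mutation = mut$n_significant,
    n_cell_enrichments = sum(prof_cell$significant),
    n_region_enrichments = sum(prof_region$significant),
    n_undefined_cell_distances = attr(rank_cell, "n_undefined"),
    n_undefined_region_distances = attr(rank_region, "n_undefined")
  )

  correlations <- NULL; groups <- NULL; phen <- NULL
  if (is.null(phenotype) || !file.exists(phenotype %||% "")) {
    warning("no phenotype table supplied; correlation stage skipped")
    note("phenotype stage skipped: no input file")
  } else {
    phen <- stage("phenotype_similarity", average_phenotype(
      read_phenotype_scores(phenotype, synonyms = synonyms)))
    write_tsv(phen, file.path(out_dir, "phenotype_averaged.tsv"))
    cor_one <- function(sim, value, method) {
      p <- paired_scores(sim, value, phen)
      ct <- correlate_similarity(p, method = method)
      c(ct, list(n_dropped_no_score = attr(p, "n_dropped_no_score")))
    }
    correlations <- stage("phenotype_similarity", list(
      gene_pearson = cor_one(gen$pairs, "proportion_shared", "pearson"),
      cell_spearman = cor_one(rank_cell, "distance", "spearman"),
      region_spearman = cor_one(rank_region, "distance", "spearman")
    ))
    groups <- lapply(list(cell = rank_cell, region = rank_region),
                     function(rk) {
      scored <- paired_scores(rk, "distance", phen)
      scored <- scored[order(scored$similarity, scored$disease_a,
                             scored$disease_b), ]
      n <- nrow(scored)
      if (n >= group_mid[2] + group_k && group_mid[1] > group_k)
        group_compare(scored, k = group_k, mid = group_mid)
      else {
        note("group comparison skipped: only ", n, " scored pairs")
        NULL
      }
    })
    summary$correlations <- lapply(correlations, function(x)
      x[c("method", "estimate", "p_value", "n")])
    summary$group_means <- lapply(groups, function(g)
      if (is.null(g)) NULL else as.list(g$group_means))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(log, file.path(out_dir, "log.txt"))

  invisible(list(
    merged = merged, genetic_gene = gen, genetic_mutation = mut,
    study = study, region_sets = region_sets,
    profiles_cell = prof_cell, profiles_region = prof_region,
    dist_cell = dist_cell, dist_region = dist_region,
    rank_cell = rank_cell, rank_region = rank_region,
    phenotype = phen, correlations = correlations, groups = groups,
    summary = summary
  ))
}
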
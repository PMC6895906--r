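#' Disease gene-set catalog
#'
#' Container mapping each disease to its set of mutation-bearing genes,
#' together with the gene universe used as the reference for overlap tests.
#'
#' @param gene_sets named list of character vectors; names are disease names
#'   (normalized with [normalize_disease()]), values are gene symbols. Gene
#'   symbols are compared case-sensitively after whitespace trimming; no alias
#'   resolution is attempted.
#' @param universe optional character vector of all gene symbols in scope;
#'   defaults to the union of the gene sets. Every gene in a set must belong
#'   to the universe.
#' @return an object of class `disease_catalog` with elements `diseases`
#'   (ordered names), `gene_sets`, and `universe`.
#' @export
#' @examples
#' disease_catalog(list(ataxia = c("SACS", "SETX"), dystonia = c("GCH1", "SETX")))
disease_catalog <- function(gene_sets, universe = NULL) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 1)
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets))))
    stop("gene_sets must be a named list keyed by disease")
  gene_sets <- lapply(gene_sets, function(g) unique(trimws(as.character(g))))
  if (any(lengths(gene_sets) == 0))
    stop("gene_sets values must be non-empty for included diseases")
  universe <- unique(trimws(as.character(universe %||% unlist(gene_sets, use.names = FALSE))))
  missing <- setdiff(unlist(gene_sets, use.names = FALSE), universe)
  if (length(missing))
    stop("genes outside the universe: ", paste(utils::head(missing, 5), collapse = ", "))
  structure(
    list(diseases = names(gene_sets), gene_sets = gene_sets, universe = universe),
    class = "disease_catalog"
  )
}

#' @export
print.disease_catalog <- function(x, ...) {
  cat("disease_catalog:", length(x$diseases), "diseases,",
      length(x$universe), "genes in universe\n")
  sizes <- lengths(x$gene_sets)
  cat("  set sizes:", min(sizes), "-", max(sizes), "\n")
  invisible(x)
}

#' Marker-gene catalog for cell types or brain regions
#'
#' @param marker_sets named list of character vectors; names are contexts
#'   (cell subtypes or brain regions), values are marker gene symbols.
#' @param background optional enrichment universe; defaults to the union of
#'   all marker sets. Every marker must belong to the background.
#' @return object of class `marker_catalog` with `contexts`, `marker_sets`,
#'   `background`.
#' @export
marker_catalog <- function(marker_sets, background = NULL) {
  stopifnot(is.list(marker_sets), length(marker_sets) >= 1)
  if (is.null(names(marker_sets)) || any(!nzchar(names(marker_sets))))
    stop("marker_sets must be a named list keyed by context")
  if (anyDuplicated(names(marker_sets)))
    stop("context names must be unique")
  marker_sets <- lapply(marker_sets, function(g) unique(trimws(as.character(g))))
  background <- unique(trimws(as.character(
    background %||% unlist(marker_sets, use.names = FALSE))))
  missing <- setdiff(unlist(marker_sets, use.names = FALSE), background)
  if (length(missing))
    stop("marker genes outside the background: ",
         paste(utils::head(missing, 5), collapse = ", "))
  structure(
    list(contexts = names(marker_sets), marker_sets = marker_sets,
         background = background),
    class = "marker_catalog"
  )
}

#' @export
print.marker_catalog <- function(x, ...) {
  cat("marker_catalog:", length(x$contexts), "contexts,",
      length(x$background), "background genes\n")
  invisible(x)
}

#' Gene-by-sample expression study with a sample-to-region map
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample IDs).
#' @param region_of named character vector mapping every sample ID to one
#'   region name.
#' @param scale `"log2"` if values are already log2 intensities (the default
#'   for preprocessed microarray data), `"linear"` otherwise; linear values
#'   are log2-transformed (after adding `pseudocount`) before contrasts.
#' @return object of class `expression_study` with `genes`, `samples`,
#'   `values`, `region_of`, `regions`, `scale`.
#' @export
expression_study <- function(values, region_of, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  region_of <- vapply(region_of, as.character, character(1))
  missing <- setdiff(colnames(values), names(region_of))
  if (length(missing))
    stop("samples missing from the region map: ",
         paste(utils::head(missing, 5), collapse = ", "))
  extra <- setdiff(names(region_of), colnames(values))
  if (length(extra)) {
    warning("region map entries absent from the matrix dropped: ",
            paste(utils::head(extra, 5), collapse = ", "))
    region_of <- region_of[colnames(values)]
  }
  region_of <- region_of[colnames(values)]
  structure(
    list(genes = rownames(values), samples = colnames(values), values = values,
         region_of = region_of, regions = unique(unname(region_of)),
         scale = scale),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", length(x$genes), "genes x", length(x$samples),
      "samples,", length(x$regions), "regions (", x$scale, "scale )\n")
  invisible(x)
}

mutation_record_columns <- c("disease", "gene", "build", "chrom", "pos",
                             "ref", "alt", "source", "pathogenicity")

mutation_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

validate_mutation_records <- function(records) {
  ok <- !is.na(records$pos) & records$pos >= 1 &
    !is.na(records$ref) & !is.na(records$alt) & records$ref != records$alt &
    nzchar(records$disease) & !is.na(records$disease) &
    nzchar(records$gene) & !is.na(records$gene) &
    records$source %in% c("curated", "clinvar", "both") &
    records$pathogenicity %in% c("pathogenic", "likely_pathogenic")
  ok & !is.na(ok)
}

#' Build a disease gene-set catalog from mutation records
#'
#' @param records mutation-record data frame as returned by
#'   [read_mutation_table()] or [merge_catalogs()].
#' @param universe optional gene universe; defaults to all genes in `records`.
#' @return a [disease_catalog()].
#' @export
catalog_from_records <- function(records, universe = NULL) {
  sets <- split(records$gene, records$disease)
  disease_catalog(lapply(sets, unique), universe = universe)
}

#' Build a mutation-level catalog (disease to variant-key sets)
#'
#' Variant identity is the `(chrom, pos, ref, alt)` tuple; the disease label is
#' not part of the key, so one variant recorded for two diseases appears in
#' both sets. Feed the result to [similarity_screen()] with
#' `level = "mutation"`.
#'
#' @inheritParams catalog_from_records
#' @return a [disease_catalog()] whose "genes" are variant keys.
#' @export
mutation_catalog <- function(records, universe = NULL) {
  sets <- split(mutation_key(records), records$disease)
  disease_catalog(lapply(sets, unique), universe = universe)
}
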
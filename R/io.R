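#' Read a disease-mutation table
#'
#' Reads a tab-separated table with one pathogenic variant per row. Required
#' columns: `disease`, `gene`, `build`, `chrom`, `pos`, `ref`, `alt`,
#' `pathogenicity` (`pathogenic` or `likely_pathogenic`). Coordinates are
#' 1-based, fully closed (VCF convention) and are assumed to be pre-normalized
#' to one genome build; no lift-over is performed. Disease names are
#' normalized (case-fold, whitespace collapse). Rows violating the record
#' invariants (`pos >= 1`, `ref != alt`, non-empty disease/gene, known
#' pathogenicity) are dropped with a warning naming their line numbers;
#' duplicate rows are kept (de-duplication is [merge_catalogs()]'s job).
#'
#' @param path path to a TSV file with a header line.
#' @param source_tag provenance of the table, `"curated"` or `"clinvar"`;
#'   stored in the `source` column of every record.
#' @param synonyms optional disease synonym map, see [normalize_disease()].
#' @return data frame of mutation records.
#' @export
read_mutation_table <- function(path, source_tag = c("curated", "clinvar"),
                                synonyms = NULL) {
  source_tag <- match.arg(source_tag)
  df <- read_tsv(path, colClasses = "character")
  required <- setdiff(mutation_record_columns, "source")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  df$pos <- suppressWarnings(as.numeric(df$pos))
  df$disease <- normalize_disease(df$disease, synonyms)
  df$gene <- trimws(df$gene)
  df$source <- source_tag
  df <- df[mutation_record_columns]
  ok <- validate_mutation_records(df)
  if (any(!ok)) {
    # +1: header occupies line 1 of the file
    warning("dropped ", sum(!ok), " invalid row(s) at line(s): ",
            paste(which(!ok) + 1L, collapse = ", "))
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid mutation records in ", path)
  rownames(df) <- NULL
  df
}

#' Write a disease-mutation table
#'
#' Inverse of [read_mutation_table()]: emits UTF-8, tab-separated output with
#' a header; reading it back reproduces the field content exactly.
#'
#' @param records mutation-record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  write_tsv(records[mutation_record_columns], path)
  invisible(path)
}

#' Read a GMT marker-gene catalog
#'
#' One gene set per line: `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Context order follows file order.
#'
#' @param path path to a GMT file.
#' @param background optional enrichment universe; defaults to the union of
#'   all marker sets.
#' @return a [marker_catalog()].
#' @export
read_marker_gmt <- function(path, background = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  marker_catalog(sets, background = background)
}

#' Write a marker catalog as GMT
#'
#' @param catalog a [marker_catalog()].
#' @param path output path.
#' @param descriptions optional character vector of per-context descriptions
#'   (defaults to the context name).
#' @return `path`, invisibly.
#' @export
write_marker_gmt <- function(catalog, path, descriptions = NULL) {
  descriptions <- descriptions %||% catalog$contexts
  lines <- mapply(function(ctx, desc) {
    paste(c(ctx, desc, catalog$marker_sets[[ctx]]), collapse = "\t")
  }, catalog$contexts, descriptions)
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read an expression matrix and its sample-to-region map
#'
#' The matrix TSV has genes as rows (first column = gene symbol, header names
#' the samples); the region map TSV has columns `sample` and `region`. Samples
#' present in the matrix but absent from the map are a hard error; map entries
#' absent from the matrix are dropped with a warning.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param region_map_path path to the sample-to-region TSV.
#' @param scale `"log2"` or `"linear"`, see [expression_study()].
#' @return an [expression_study()].
#' @export
read_expression <- function(matrix_path, region_map_path,
                            scale = c("log2", "linear")) {
  raw <- read_tsv(matrix_path, colClasses = "character")
  genes <- raw[[1]]
  vals <- as.matrix(raw[-1])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals) & nzchar(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  if (anyNA(num)) {
    na <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("missing expression value at gene '%s', sample '%s'",
                 genes[na[1, 1]], colnames(num)[na[1, 2]]))
  }
  map <- read_tsv(region_map_path, colClasses = "character")
  if (!all(c("sample", "region") %in% names(map)))
    stop("region map must have columns 'sample' and 'region'")
  region_of <- stats::setNames(map$region, map$sample)
  expression_study(num, region_of, scale = match.arg(scale))
}

#' Read a phenotype-similarity score table
#'
#' TSV with columns `disease_a`, `disease_b`, `score` (non-negative). The pair
#' key is order-insensitive and duplicate pairs are retained: one disease pair
#' may have multiple matches in the phenotype network, and the average of the
#' scores is taken downstream by [average_phenotype()].
#'
#' @param path path to a TSV file.
#' @param synonyms optional disease synonym map applied to both name columns,
#'   see [normalize_disease()].
#' @return data frame of class `phenotype_scores` with normalized, canonically
#'   ordered pair columns and a `score` column; all input rows retained.
#' @export
read_phenotype_scores <- function(path, synonyms = NULL) {
  df <- read_tsv(path)
  required <- c("disease_a", "disease_b", "score")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df$score <- as.numeric(df$score)
  if (anyNA(df$score) || any(df$score < 0))
    stop("phenotype scores must be non-negative numbers")
  a <- normalize_disease(df$disease_a, synonyms)
  b <- normalize_disease(df$disease_b, synonyms)
  p <- canonical_pair(a, b)
  out <- data.frame(disease_a = p$a, disease_b = p$b, score = df$score,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_scores", "data.frame")
  out
}

#' Look up all scores recorded for one disease pair
#'
#' Order-insensitive: `phenotype_lookup(x, a, b)` equals
#' `phenotype_lookup(x, b, a)`.
#'
#' @param scores a `phenotype_scores` data frame.
#' @param a,b disease names (normalized internally).
#' @return numeric vector of scores (possibly length 0).
#' @export
phenotype_lookup <- function(scores, a, b) {
  key <- pair_key(normalize_disease(a), normalize_disease(b))
  scores$score[pair_key(scores$disease_a, scores$disease_b) == key]
}
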